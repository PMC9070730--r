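## Stack discovery, the standardized output tree, exact-round-trip
## checkpoints, YAML configuration and plain-text logging.

.pipeline_stages <- c("alignment", "registrations", "segmentation",
                      "cells", "tables", "figures", "logs")

#' Order image paths by their embedded z index
#'
#' Microscope export names embed the plane number in flexible,
#' user-defined ways; \code{imSort} extracts it with a single regular
#' expression containing one numeric capture group and orders the paths
#' by the captured number (natural sort, not lexicographic, so
#' \code{Z10} follows \code{Z2}).
#'
#' @param paths character vector of image file paths.
#' @param zPattern regular expression with exactly one capture group
#'   matching the z index digits. The default matches \code{Z<digits>}
#'   or \code{_<digits>} immediately before the file extension.
#' @param zStepUm,pixelSizeUm physical calibration recorded in the
#'   manifest (micrometers).
#' @param channelTag free-text channel label.
#' @return a [StackManifest-class] with paths in ascending z order.
#' @examples
#' imSort(c("a_Z10.tif", "a_Z2.tif"), zStepUm = 2.5, pixelSizeUm = 5)
#' @export
imSort <- function(paths, zPattern = "[Zz_](\\d+)\\.[^.]+$",
                   zStepUm = 2.5, pixelSizeUm = 5,
                   channelTag = "signal") {
  if (!length(paths)) stop("no image paths supplied")
  idx <- vapply(paths, function(p) {
    base <- basename(p)
    hits <- gregexpr(zPattern, base, perl = TRUE)[[1]]
    nhit <- if (hits[1] == -1L) 0L else length(hits)
    if (nhit == 0L)
      stop(sprintf("path does not match z pattern '%s': %s", zPattern, p),
           call. = FALSE)
    if (nhit > 1L)
      stop(sprintf("path matches z pattern more than once: %s", p),
           call. = FALSE)
    m <- regexec(zPattern, base, perl = TRUE)[[1]]
    if (length(m) < 2L)
      stop(sprintf("z pattern '%s' has no capture group", zPattern),
           call. = FALSE)
    grp <- regmatches(base, list(m))[[1]][2]
    as.numeric(grp)
  }, numeric(1), USE.NAMES = FALSE)
  if (anyDuplicated(idx)) {
    dup <- paths[duplicated(idx) | duplicated(idx, fromLast = TRUE)]
    stop(sprintf("duplicate z indices among: %s",
                 paste(basename(dup), collapse = ", ")))
  }
  new("StackManifest", imagePaths = paths[order(idx)], zStepUm = zStepUm,
      pixelSizeUm = pixelSizeUm, channelTag = channelTag)
}

#' Create the standardized output directory tree
#'
#' Idempotently creates one subdirectory per pipeline stage under
#' \code{outputRoot} and returns their paths. Every writer in the
#' package targets this layout, so intermediate results are organized
#' identically across datasets.
#'
#' @param outputRoot writable directory (created if absent).
#' @return named list of the seven stage directories: alignment,
#'   registrations, segmentation, cells, tables, figures, logs.
#' @export
getSavepaths <- function(outputRoot) {
  dir.create(outputRoot, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outputRoot) || file.access(outputRoot, 2L) != 0L)
    stop(sprintf("output root is not writable: %s", outputRoot))
  out <- lapply(.pipeline_stages, function(s) {
    d <- file.path(outputRoot, s)
    dir.create(d, showWarnings = FALSE)
    d
  })
  names(out) <- .pipeline_stages
  out
}

## Exact-round-trip tabular serialization: doubles are written with 17
## significant digits, which R's reader parses back to the identical
## bit pattern.
.writeTableExact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

.readTableExact <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df
}

.checkpoint_file <- function(paths, stage) {
  switch(stage,
    alignment = file.path(paths$alignment, "anchors.csv"),
    segmentation = file.path(paths$segmentation, "detections.csv"),
    cells = file.path(paths$cells, "cells.csv"),
    tables = file.path(paths$tables, "region_counts.csv"),
    registrations = paths$registrations,
    stop(sprintf("unknown pipeline stage '%s' (known: %s)", stage,
                 paste(c("alignment", "registrations", "segmentation",
                         "cells", "tables"), collapse = ", ")))
  )
}

#' Save / load a pipeline checkpoint
#'
#' Intermediate results are saved as human-readable text under the
#' standardized output tree so an analysis can be resumed, inspected or
#' shared at any stage. Round trips are exact: doubles survive
#' bit-identically and alignment maps reload with identical anchors.
#'
#' Supported stages and payloads: \code{alignment} (an
#' [AlignmentMap-class]), \code{segmentation} / \code{cells} /
#' \code{tables} (data.frames), \code{registrations} (a named list of
#' [Warp-class] objects, one file per plate).
#'
#' @param stage one of the stage names above.
#' @param payload the object to save.
#' @param paths output tree from [getSavepaths()], or an output root
#'   directory.
#' @return \code{saveCheckpoint}: the file (or directory) written,
#'   invisibly. \code{loadCheckpoint}: the reloaded payload.
#' @export
saveCheckpoint <- function(stage, payload, paths) {
  if (is.character(paths)) paths <- getSavepaths(paths)
  target <- .checkpoint_file(paths, stage)
  if (stage == "alignment") {
    stopifnot(is(payload, "AlignmentMap"))
    .writeTableExact(payload@anchors, target)
    yaml::write_yaml(list(n_planes = payload@nPlanes,
                          z_step_um = payload@zStepUm),
                     file.path(paths$alignment, "map_meta.yaml"))
  } else if (stage == "registrations") {
    stopifnot(is.list(payload), all(vapply(payload, is, logical(1), "Warp")))
    for (nm in names(payload)) saveWarp(payload[[nm]], target, nm)
  } else {
    stopifnot(is.data.frame(payload))
    .writeTableExact(payload, target)
  }
  invisible(target)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(stage, paths) {
  if (is.character(paths)) paths <- getSavepaths(paths)
  target <- .checkpoint_file(paths, stage)
  if (stage == "registrations") {
    warps <- loadWarps(target)
    if (!length(warps))
      stop(sprintf("checkpoint for stage '%s' was never run (no warp files in %s)",
                   stage, target))
    return(warps)
  }
  if (!file.exists(target))
    stop(sprintf("checkpoint for stage '%s' was never run (missing %s)",
                 stage, target))
  if (stage == "alignment") {
    meta_f <- file.path(paths$alignment, "map_meta.yaml")
    if (!file.exists(meta_f))
      stop("alignment checkpoint is corrupt: anchors present but map_meta.yaml missing")
    a <- tryCatch(.readTableExact(target),
                  error = function(e) stop(sprintf(
                    "alignment checkpoint is corrupt: %s", conditionMessage(e))))
    meta <- yaml::read_yaml(meta_f)
    m <- tryCatch(
      alignmentMap(a$z_index, a$ap_mm, meta$n_planes, meta$z_step_um,
                   source = a$source),
      error = function(e) stop(sprintf("alignment checkpoint is corrupt: %s",
                                       conditionMessage(e))))
    return(m)
  }
  tryCatch(.readTableExact(target),
           error = function(e) stop(sprintf("checkpoint for stage '%s' is corrupt: %s",
                                            stage, conditionMessage(e))))
}

#' Write / read a pipeline configuration
#'
#' Configurations are a single YAML document holding every analysis
#' parameter: the stack definition, output root, alignment, segmentation
#' and cleanup settings, and the random seed. All parameters are plain
#' scalars or lists so the file is hand-editable.
#'
#' @param config a configuration list, e.g. from [pipelineConfig()].
#' @param path YAML file path.
#' @return \code{readPipelineConfig}: the validated configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
  cfg <- yaml::read_yaml(path)
  validatePipelineConfig(cfg)
}

#' Assemble a pipeline configuration list
#'
#' @param imageDir directory containing the stack's TIFF planes.
#' @param outputRoot output directory for the standardized tree.
#' @param zPattern z-index extraction pattern (see [imSort()]).
#' @param zStepUm,pixelSizeUm physical calibration (um).
#' @param stepSchedule,referenceAps choice-game settings.
#' @param seg named list of [segmentationFilter()] arguments.
#' @param cleanup named list of [cleanupParams()] arguments.
#' @param seed integer seed used by any stochastic step.
#' @param atlasDir atlas bundle directory (see [loadAtlas()]), or NULL.
#' @param endpointAps c(AP of plane 0, AP of the last plane), the two
#'   manually assigned endpoint anchors; NULL until known.
#' @return a validated configuration list.
#' @export
pipelineConfig <- function(imageDir, outputRoot,
                           zPattern = "[Zz_](\\d+)\\.[^.]+$",
                           zStepUm = 2.5, pixelSizeUm = 5,
                           stepSchedule = c(200, 100, 30, 10),
                           referenceAps = defaultReferencePlates()$ap_mm,
                           seg = list(), cleanup = list(), seed = 1L,
                           atlasDir = NULL, endpointAps = NULL) {
  cfg <- list(
    stack = list(dir = imageDir, z_pattern = zPattern,
                 z_step_um = zStepUm, pixel_size_um = pixelSizeUm),
    output_root = outputRoot,
    align = list(step_schedule = as.numeric(stepSchedule),
                 reference_aps = as.numeric(referenceAps),
                 endpoint_aps = if (!is.null(endpointAps)) as.numeric(endpointAps)),
    atlas_dir = atlasDir,
    seg = seg, cleanup = cleanup, seed = as.integer(seed))
  validatePipelineConfig(cfg)
}

#' @rdname pipelineConfig
#' @param config a configuration list to validate.
#' @export
validatePipelineConfig <- function(config) {
  need <- c("stack", "output_root", "align", "seg", "cleanup", "seed")
  if (!is.null(config$align$endpoint_aps) &&
      (length(config$align$endpoint_aps) != 2 ||
       diff(config$align$endpoint_aps) >= 0))
    stop("align$endpoint_aps must be two strictly decreasing AP coordinates")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop(sprintf("config is missing fields: %s", paste(miss, collapse = ", ")))
  if (config$stack$z_step_um <= 0 || config$stack$pixel_size_um <= 0)
    stop("stack z_step_um and pixel_size_um must be positive")
  ## constructing the parameter objects runs their validity methods
  do.call(choiceGameConfig, list(stepSchedule = config$align$step_schedule,
                                 referenceAps = config$align$reference_aps))
  do.call(segmentationFilter, config$seg)
  do.call(cleanupParams, config$cleanup)
  config
}

#' Append a timestamped line to a run log
#'
#' @param logDir the \code{logs} directory of the output tree.
#' @param stage pipeline stage name.
#' @param message free-text message (parameters, counts, durations).
#' @export
logMessage <- function(logDir, stage, message) {
  line <- sprintf("%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%OS2"), stage, message)
  cat(line, "\n", sep = "", file = file.path(logDir, "run.log"),
      append = TRUE)
  invisible(line)
}
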