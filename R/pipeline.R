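## Stage orchestration: canonical order, prerequisite checking via
## checkpoints, and run logging.

.stage_order <- c("align", "register", "segment", "clean", "warp", "count")

.stageDone <- function(paths, stage) {
  switch(stage,
    align = file.exists(file.path(paths$alignment, "anchors.csv")),
    register = length(list.files(paths$registrations,
                                 pattern = "\\.warp$")) > 0,
    segment = file.exists(file.path(paths$segmentation, "detections.csv")),
    clean = file.exists(file.path(paths$cells, "cells.csv")),
    warp = file.exists(file.path(paths$tables, "cells_mapped.csv")),
    count = file.exists(file.path(paths$tables, "region_counts.csv")))
}

.stage_prereq <- list(align = character(), register = "align",
                      segment = character(), clean = "segment",
                      warp = c("clean", "align", "register"),
                      count = "warp")

#' Run pipeline stages in canonical order
#'
#' Executes the requested stages — align, register, segment, clean,
#' warp, count — against the checkpointed output tree, enforcing the
#' canonical order: a stage runs only if each prerequisite stage is
#' either checkpointed from an earlier run or requested before it in
#' the same call. Whole, partial or plate-restricted runs are all
#' expressed through the config's reference AP list: only plates within
#' the aligned range are registered and used.
#'
#' @param config configuration list (see [pipelineConfig()]) or a path
#'   to a YAML config file. Must carry \code{align$endpoint_aps} (the
#'   manually assigned endpoint anchors) for the align stage and
#'   \code{atlas_dir} for register/warp/count.
#' @param stages subset of the canonical stages to run.
#' @param chooser chooser for the align stage ([oracleChooser()] or
#'   [consoleChooser()]); lists with an \code{accept} element also get
#'   a midpoint check.
#' @param corrector registration corrector (see [regiLoop()]).
#' @param atlas optional pre-loaded [AtlasBundle-class]; otherwise read
#'   from \code{config$atlas_dir}.
#' @param verbose log stage messages to the console as well as the run
#'   log.
#' @return invisibly, the output tree paths.
#' @export
runPipeline <- function(config, stages = .stage_order, chooser = NULL,
                        corrector = autoCorrector(), atlas = NULL,
                        verbose = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  validatePipelineConfig(config)
  stages <- match.arg(stages, .stage_order, several.ok = TRUE)
  if (is.unsorted(match(stages, .stage_order)))
    stop(sprintf("stages out of canonical order; expected an ordered subset of: %s",
                 paste(.stage_order, collapse = " -> ")))
  paths <- getSavepaths(config$output_root)
  for (s in stages) {
    missing <- .stage_prereq[[s]]
    missing <- missing[!vapply(missing, .stageDone, logical(1), paths = paths) &
                       !(missing %in% stages[seq_len(match(s, stages) - 1L)])]
    if (length(missing))
      stop(sprintf("stage '%s' requires stage '%s' to run first", s, missing[1]))
  }
  needs_atlas <- any(c("register", "warp", "count") %in% stages)
  if (needs_atlas && is.null(atlas)) {
    if (is.null(config$atlas_dir))
      stop("config$atlas_dir (or an atlas object) is required for the requested stages")
    atlas <- loadAtlas(config$atlas_dir)
  }
  manifest <- NULL
  getManifest <- function() {
    if (is.null(manifest)) {
      files <- list.files(config$stack$dir, pattern = "\\.tiff?$",
                          full.names = TRUE)
      manifest <<- imSort(files, config$stack$z_pattern,
                          zStepUm = config$stack$z_step_um,
                          pixelSizeUm = config$stack$pixel_size_um)
    }
    manifest
  }
  cfgGame <- choiceGameConfig(config$align$step_schedule,
                              config$align$reference_aps)
  note <- function(stage, msg) {
    logMessage(paths$logs, stage, msg)
    if (verbose) message(sprintf("[%s] %s", stage, msg))
  }
  for (s in stages) {
    t0 <- Sys.time()
    switch(s,
      align = {
        ep <- config$align$endpoint_aps
        if (is.null(ep))
          stop("align stage needs config$align$endpoint_aps (manually assigned endpoint anchors)")
        if (is.null(chooser))
          stop("align stage needs a chooser (consoleChooser() or oracleChooser())")
        mf <- getManifest()
        map <- alignmentMap(c(0L, nPlanes(mf) - 1L), ep, nPlanes(mf),
                            zStepUm(mf))
        map <- alignReferencePlates(map, chooser, cfgGame)
        if (is.list(chooser) && !is.null(chooser$accept))
          map <- midpointCheck(map, chooser, cfgGame, atlas)
        saveCheckpoint("alignment", map, paths)
        note(s, sprintf("%d anchors", nrow(anchors(map))))
      },
      register = {
        map <- loadCheckpoint("alignment", paths)
        rng <- range(anchors(map)$ap_mm)
        aps <- vapply(plates(atlas), apCoordinate, numeric(1))
        aps <- aps[aps <= rng[2] & aps >= rng[1]]
        if (!length(aps))
          stop("no atlas plates fall inside the aligned AP range")
        warps <- regiLoop(getManifest(), map, atlas, aps, corrector,
                          registrationsDir = paths$registrations)
        note(s, sprintf("%d plates registered", length(warps)))
      },
      segment = {
        filt <- do.call(segmentationFilter, config$seg)
        dets <- segmentLoop(getManifest(), filt,
                            checkpointDir = paths$segmentation)
        note(s, sprintf("%d detections", nrow(dets)))
      },
      clean = {
        dets <- loadCheckpoint("segmentation", paths)
        p <- do.call(cleanupParams, config$cleanup)
        cells <- cleanDuplicates(dets, p, config$stack$z_step_um)
        saveCheckpoint("cells", cells, paths)
        note(s, sprintf("%d detections -> %d cells", nrow(dets), nrow(cells)))
      },
      warp = {
        cells <- loadCheckpoint("cells", paths)
        map <- loadCheckpoint("alignment", paths)
        warps <- loadCheckpoint("registrations", paths)
        cells <- forwardWarpCells(cells, warps, map,
                                  config$stack$pixel_size_um)
        cells <- assignRegions(cells, atlas)
        .writeTableExact(cells, file.path(paths$tables, "cells_mapped.csv"))
        note(s, sprintf("%d cells mapped (%d unmapped)", sum(cells$mapped),
                        sum(!cells$mapped)))
      },
      count = {
        cells <- .readTableExact(file.path(paths$tables, "cells_mapped.csv"))
        tab <- getTable(cells, atlas)
        saveCheckpoint("tables", tab, paths)
        sunburstData(tab, atlas, file.path(paths$figures, "sunburst.json"))
        note(s, sprintf("root rolled count %d",
                        max(tab$rolled_count[tab$acronym != "unassigned"])))
      })
    note(s, sprintf("completed in %.2f s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  invisible(paths)
}
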