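## Atlas data model: labeled coronal plates with AP coordinates, the
## region ontology tree, and the bundled default reference-plate table.

.default_reference_plates <- data.frame(
  ap_mm = c(1.91, 1.10, -0.42, -0.93, -1.94, -2.95, -3.96),
  plate_number = c(35L, 43L, 58L, 63L, 73L, 83L, 93L),
  landmark = c(
    "PIR/ORB folds span ~half a hemisphere; teardrop aco; no ACB yet",
    "fa wings about to touch; NDB extends halfway to corpus callosum",
    "fx and sm just separated; och in one piece below hypothalamus",
    "CA3so appearing in fimbria; fx below top of V3; opt near HY/amygdala border",
    "DG spans ~2/3 of hippocampal wing; fr, mtt, fx evenly spaced; ME visible",
    "MM receded on thinned tissue; pc and aqueduct below V3 behind SCig-c/b",
    "TRN and PG split by cst and ml; bic protrudes beyond mcp"),
  stringsAsFactors = FALSE)

#' The seven default reference plate coordinates
#'
#' The suggested internal reference plates used by the choice game when
#' the user does not pick their own: seven coronal atlas plates spread
#' across the AP axis, each identified by its AP coordinate (mm from
#' bregma), its plate number in the reference plate set, and a short
#' summary of the anatomical landmarks used to recognize it.
#'
#' @return data.frame with columns \code{ap_mm}, \code{plate_number},
#'   \code{landmark}, ordered anterior to posterior: +1.91/35, +1.10/43,
#'   -0.42/58, -0.93/63, -1.94/73, -2.95/83, -3.96/93.
#' @examples
#' defaultReferencePlates()[, 1:2]
#' @export
defaultReferencePlates <- function() .default_reference_plates

#' Construct an AtlasPlate
#'
#' @param apMm plate AP coordinate (mm from bregma).
#' @param labelMask 2D integer matrix of region ids (0 = outside tissue).
#' @param outline optional n x 2 (x, y) closed boundary polygon; traced
#'   from the mask if omitted.
#' @param plateNumber integer plate number.
#' @return an [AtlasPlate-class].
#' @export
atlasPlate <- function(apMm, labelMask, outline = NULL, plateNumber = NA_integer_) {
  if (is.null(outline)) outline <- .traceOutline(labelMask > 0)
  new("AtlasPlate", apMm = apMm, plateNumber = as.integer(plateNumber),
      labelMask = labelMask, outline = outline)
}

## Trace the outer boundary of the largest foreground component,
## oriented clockwise (screen sense, y down) starting dorsal-most.
.traceOutline <- function(fg) {
  lb <- EBImage::bwlabel(fg)
  if (max(lb) == 0) stop("no foreground component to trace")
  if (max(lb) > 1) {
    sizes <- tabulate(as.vector(lb), nbins = max(lb))
    keep <- which.max(sizes)
    lb[lb != keep] <- 0L
    lb[lb == keep] <- 1L
  }
  oc <- EBImage::ocontour(lb)[[1]]
  ## EBImage uses (x, y) 0-based with x along matrix rows; our plate
  ## convention is x = column, y = row, so swap.
  pts <- cbind(x = oc[, 2], y = oc[, 1])
  .orientContour(pts)
}

## Rotate a closed polygon to start at its dorsal-most (min y, then min
## x) vertex and orient it with positive shoelace area (clockwise on
## screen for y-down coordinates).
.orientContour <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("contour has fewer than 3 points")
  x <- pts[, 1]; y <- pts[, 2]
  a2 <- sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
  if (a2 < 0) pts <- pts[n:1, , drop = FALSE]
  start <- which(pts[, 2] == min(pts[, 2]))
  start <- start[which.min(pts[start, 1])]
  if (start > 1) pts <- pts[c(start:n, 1:(start - 1)), , drop = FALSE]
  colnames(pts) <- c("x", "y")
  pts
}

#' Construct an AtlasBundle
#'
#' @param plates list of [AtlasPlate-class] in strictly decreasing AP
#'   order.
#' @param ontology region ontology data.frame (\code{region_id},
#'   \code{acronym}, \code{name}, \code{parent_id}, \code{color_hex}).
#' @param referenceTable reference plate table; defaults to
#'   [defaultReferencePlates()].
#' @return an [AtlasBundle-class].
#' @export
atlasBundle <- function(plates, ontology,
                        referenceTable = defaultReferencePlates()) {
  new("AtlasBundle", plates = plates, ontology = ontology,
      referenceTable = referenceTable)
}

#' Save / load an atlas bundle directory
#'
#' The on-disk bundle is a directory with \code{ontology.csv} (id,
#' acronym, name, parent_id, color), \code{plates.csv} (plate_number,
#' ap_mm, mask_filename) and one 16-bit integer TIFF label mask per
#' plate. Loading validates every invariant: plates strictly decreasing
#' in AP and every nonzero mask value present in the ontology.
#'
#' @param atlas an [AtlasBundle-class].
#' @param bundleDir bundle directory path.
#' @return \code{loadAtlas}: a validated [AtlasBundle-class].
#' @export
saveAtlas <- function(atlas, bundleDir) {
  dir.create(bundleDir, recursive = TRUE, showWarnings = FALSE)
  .writeTableExact(atlas@ontology, file.path(bundleDir, "ontology.csv"))
  idx <- data.frame(
    plate_number = vapply(atlas@plates, function(p) p@plateNumber, integer(1)),
    ap_mm = vapply(atlas@plates, function(p) p@apMm, numeric(1)))
  idx$mask_filename <- sprintf("plate_%03d.tif", seq_len(nrow(idx)))
  .writeTableExact(idx, file.path(bundleDir, "plates.csv"))
  for (i in seq_along(atlas@plates)) {
    m <- atlas@plates[[i]]@labelMask
    if (max(m) > 65535) stop("region ids exceed 16-bit mask range")
    tiff::writeTIFF(m / 65535, file.path(bundleDir, idx$mask_filename[i]),
                    bits.per.sample = 16L)
  }
  .writeTableExact(atlas@referenceTable,
                   file.path(bundleDir, "reference_plates.csv"))
  invisible(bundleDir)
}

#' @rdname saveAtlas
#' @export
loadAtlas <- function(bundleDir) {
  need <- file.path(bundleDir, c("ontology.csv", "plates.csv"))
  if (!all(file.exists(need)))
    stop(sprintf("not an atlas bundle (missing %s)",
                 paste(basename(need[!file.exists(need)]), collapse = ", ")))
  ont <- .readTableExact(file.path(bundleDir, "ontology.csv"))
  idx <- .readTableExact(file.path(bundleDir, "plates.csv"))
  if (nrow(idx) > 1 && any(diff(idx$ap_mm) >= 0))
    stop("plate index is not in strictly decreasing AP order")
  plates <- lapply(seq_len(nrow(idx)), function(i) {
    f <- file.path(bundleDir, idx$mask_filename[i])
    if (!file.exists(f)) stop(sprintf("missing mask image: %s", f))
    m <- tiff::readTIFF(f, as.is = TRUE)
    storage.mode(m) <- "integer"
    orphan <- setdiff(unique(as.vector(m)), c(0L, ont$region_id))
    if (length(orphan))
      stop(sprintf("mask %s contains ids absent from ontology: %s",
                   idx$mask_filename[i], paste(sort(orphan), collapse = ", ")))
    atlasPlate(idx$ap_mm[i], m, plateNumber = idx$plate_number[i])
  })
  ref_f <- file.path(bundleDir, "reference_plates.csv")
  ref <- if (file.exists(ref_f)) .readTableExact(ref_f)
         else defaultReferencePlates()
  atlasBundle(plates, ont, ref)
}

#' Nearest atlas plate to an AP coordinate
#'
#' Queries beyond the atlas range clamp to the terminal plates; exact
#' midpoints between two plates break toward the more anterior one.
#'
#' @param atlas an [AtlasBundle-class].
#' @param apMm query AP coordinate (mm).
#' @return the [AtlasPlate-class] minimizing |plate AP - query|.
#' @export
nearestPlate <- function(atlas, apMm) {
  atlas@plates[[nearestPlateIndex(atlas, apMm)]]
}

#' @rdname nearestPlate
#' @return \code{nearestPlateIndex}: integer index into \code{plates(atlas)}.
#' @export
nearestPlateIndex <- function(atlas, apMm) {
  aps <- vapply(atlas@plates, function(p) p@apMm, numeric(1))
  if (!length(aps)) stop("atlas has no plates")
  d <- abs(aps - apMm)
  ## plates are ordered anterior (index 1) to posterior; the first
  ## near-minimum is the more anterior plate on (floating-point) ties
  which(d <= min(d) + 1e-9)[1]
}

#' Region ids of an acronym and all its descendants
#'
#' @param ontology ontology data.frame (see [AtlasBundle-class]) or an
#'   [AtlasBundle-class].
#' @param acronym region acronym.
#' @return integer vector: the region's id plus all transitive children.
#' @export
descendants <- function(ontology, acronym) {
  if (is(ontology, "AtlasBundle")) ontology <- ontology@ontology
  hit <- match(acronym, ontology$acronym)
  if (is.na(hit)) {
    near <- agrep(acronym, ontology$acronym, max.distance = 0.3,
                  value = TRUE, ignore.case = TRUE)
    stop(sprintf("unknown region acronym '%s'%s", acronym,
                 if (length(near)) sprintf(" (did you mean: %s?)",
                                           paste(near, collapse = ", "))
                 else ""))
  }
  ids <- ontology$region_id[hit]
  repeat {
    kids <- ontology$region_id[!is.na(ontology$parent_id) &
                               ontology$parent_id %in% ids &
                               !(ontology$region_id %in% ids)]
    if (!length(kids)) break
    ids <- c(ids, kids)
  }
  sort(ids)
}

.rootId <- function(ontology) ontology$region_id[is.na(ontology$parent_id)]
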