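#' @import methods
NULL

## Central S4 containers for the pipeline. Validity methods enforce the
## structural invariants every downstream stage relies on, so objects that
## reach alignment / registration / mapping code are known-good.

#' StackManifest: an ordered coronal image stack
#'
#' Describes a single-channel stack of 2D coronal planes on disk, ordered
#' anterior to posterior, together with its physical calibration.
#'
#' @slot imagePaths character vector of file paths, strictly ordered by the
#'   z index extracted from the file names (no duplicates).
#' @slot zStepUm physical spacing between consecutive planes in micrometers.
#' @slot pixelSizeUm in-plane pixel edge length in micrometers.
#' @slot channelTag free-text label for the imaging channel.
#'
#' @seealso [imSort()] which constructs validated manifests.
#' @export
setClass("StackManifest",
  representation(
    imagePaths = "character",
    zStepUm = "numeric",
    pixelSizeUm = "numeric",
    channelTag = "character"
  ),
  prototype(channelTag = "signal")
)

setValidity("StackManifest", function(object) {
  msg <- character()
  if (length(object@zStepUm) != 1 || !is.finite(object@zStepUm) ||
      object@zStepUm <= 0)
    msg <- c(msg, "zStepUm must be a single positive number")
  if (length(object@pixelSizeUm) != 1 || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (anyDuplicated(object@imagePaths))
    msg <- c(msg, "imagePaths contains duplicated paths")
  if (length(msg)) msg else TRUE
})

#' AlignmentMap: piecewise z to AP mapping
#'
#' An ordered set of anchors, each tying a plane index to an
#' anterior-posterior (AP) coordinate in mm from bregma. AP coordinates
#' decrease with increasing plane index because stacks are acquired
#' anterior first.
#'
#' @slot anchors data.frame with columns \code{z_index} (0-based plane
#'   index, integer), \code{ap_mm} (mm from bregma, positive anterior) and
#'   \code{source} (one of \code{endpoint}, \code{choice_game},
#'   \code{midpoint_check}).
#' @slot nPlanes total number of planes in the stack.
#' @slot zStepUm plane spacing in micrometers.
#'
#' @seealso [alignmentMap()], [interpolateAP()], [choiceGame()]
#' @export
setClass("AlignmentMap",
  representation(
    anchors = "data.frame",
    nPlanes = "integer",
    zStepUm = "numeric"
  )
)

.anchor_sources <- c("endpoint", "choice_game", "midpoint_check")

setValidity("AlignmentMap", function(object) {
  a <- object@anchors
  msg <- character()
  need <- c("z_index", "ap_mm", "source")
  if (!all(need %in% names(a)))
    return(sprintf("anchors must have columns %s", paste(need, collapse = ", ")))
  if (length(object@nPlanes) != 1 || object@nPlanes < 1)
    msg <- c(msg, "nPlanes must be a single positive integer")
  if (length(object@zStepUm) != 1 || object@zStepUm <= 0)
    msg <- c(msg, "zStepUm must be positive")
  if (nrow(a)) {
    if (any(a$z_index < 0) || any(a$z_index >= object@nPlanes))
      msg <- c(msg, "anchor z_index out of [0, nPlanes - 1]")
    if (is.unsorted(a$z_index, strictly = TRUE))
      msg <- c(msg, "anchors must be strictly ordered by z_index")
    if (nrow(a) > 1 && any(diff(a$ap_mm) >= 0))
      msg <- c(msg, "anchor ap_mm must be strictly decreasing in z_index")
    if (!all(a$source %in% .anchor_sources))
      msg <- c(msg, sprintf("anchor source must be one of: %s",
                            paste(.anchor_sources, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' ChoiceGameConfig: coarse-to-fine alignment search settings
#'
#' @slot stepSchedule strictly decreasing positive plane offsets presented
#'   at successive refinement levels. Default \code{c(200, 100, 30, 10)}.
#' @slot referenceAps strictly decreasing AP coordinates (mm) of the
#'   internal reference plates to align. Defaults to the seven suggested
#'   plate coordinates of [defaultReferencePlates()].
#' @export
setClass("ChoiceGameConfig",
  representation(
    stepSchedule = "numeric",
    referenceAps = "numeric"
  )
)

setValidity("ChoiceGameConfig", function(object) {
  msg <- character()
  s <- object@stepSchedule
  if (!length(s) || any(s <= 0) || any(s != round(s)))
    msg <- c(msg, "stepSchedule must be positive integers")
  if (length(s) > 1 && any(diff(s) >= 0))
    msg <- c(msg, "stepSchedule must be strictly decreasing")
  r <- object@referenceAps
  if (length(r) > 1 && any(diff(r) >= 0))
    msg <- c(msg, "referenceAps must be strictly decreasing")
  if (length(msg)) msg else TRUE
})

#' MorphProfile: normalized local z-per-AP ratios
#'
#' One interval per consecutive anchor pair of an [AlignmentMap-class].
#' The ratio in each interval is the local planes-per-mm divided by the
#' whole-stack planes-per-mm, so a perfectly linear morph gives 1
#' everywhere and the |dAP|-weighted mean is exactly 1.
#'
#' @slot intervals data.frame with columns \code{ap_start_mm},
#'   \code{ap_end_mm}, \code{dz_planes}, \code{morph_ratio}.
#' @export
setClass("MorphProfile",
  representation(intervals = "data.frame")
)

setValidity("MorphProfile", function(object) {
  iv <- object@intervals
  need <- c("ap_start_mm", "ap_end_mm", "dz_planes", "morph_ratio")
  if (!all(need %in% names(iv)))
    return(sprintf("intervals must have columns %s", paste(need, collapse = ", ")))
  if (nrow(iv) && any(iv$morph_ratio <= 0))
    return("morph ratios must be positive")
  TRUE
})

#' AtlasPlate: one labeled coronal reference plate
#'
#' @slot apMm AP coordinate of the plate in mm from bregma.
#' @slot plateNumber integer plate number within its atlas set.
#' @slot labelMask 2D integer matrix of region ids; 0 means outside tissue.
#'   Pixel (x, y) is 0-based with y increasing downward (matrix row y + 1,
#'   column x + 1).
#' @slot outline n x 2 matrix (columns x, y) of the closed tissue boundary
#'   polygon in plate pixel coordinates, ordered clockwise from the
#'   dorsal-most point.
#' @export
setClass("AtlasPlate",
  representation(
    apMm = "numeric",
    plateNumber = "integer",
    labelMask = "matrix",
    outline = "matrix"
  )
)

setValidity("AtlasPlate", function(object) {
  msg <- character()
  if (length(object@apMm) != 1 || !is.finite(object@apMm))
    msg <- c(msg, "apMm must be a single finite number")
  if (!is.numeric(object@labelMask))
    msg <- c(msg, "labelMask must be numeric (integer region ids)")
  if (any(object@labelMask < 0))
    msg <- c(msg, "labelMask values must be >= 0")
  if (ncol(object@outline) != 2)
    msg <- c(msg, "outline must be an n x 2 matrix of (x, y)")
  if (length(msg)) msg else TRUE
})

#' AtlasBundle: plates plus region ontology
#'
#' @slot plates list of [AtlasPlate-class], ordered by strictly decreasing
#'   AP (anterior to posterior).
#' @slot ontology data.frame with columns \code{region_id},
#'   \code{acronym}, \code{name}, \code{parent_id} (NA for the single
#'   root) and \code{color_hex}; parent links form a tree.
#' @slot referenceTable data.frame of the default reference plates
#'   (\code{ap_mm}, \code{plate_number}, \code{landmark}); for a full
#'   atlas this is the seven-row suggested-plate table.
#' @export
setClass("AtlasBundle",
  representation(
    plates = "list",
    ontology = "data.frame",
    referenceTable = "data.frame"
  )
)

.validOntology <- function(ont) {
  msg <- character()
  need <- c("region_id", "acronym", "name", "parent_id", "color_hex")
  if (!all(need %in% names(ont)))
    return(sprintf("ontology must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(ont$region_id))
    msg <- c(msg, "ontology region_id values must be unique")
  if (anyDuplicated(ont$acronym))
    msg <- c(msg, "ontology acronyms must be unique")
  roots <- which(is.na(ont$parent_id))
  if (length(roots) != 1)
    msg <- c(msg, "ontology must have exactly one root (parent_id NA)")
  bad <- !is.na(ont$parent_id) & !(ont$parent_id %in% ont$region_id)
  if (any(bad))
    msg <- c(msg, sprintf("parent_id not in ontology: %s",
                          paste(ont$parent_id[bad], collapse = ", ")))
  ## cycle check: walk each node to the root
  if (!length(msg)) {
    parent <- stats::setNames(ont$parent_id, as.character(ont$region_id))
    for (id in ont$region_id) {
      seen <- character()
      cur <- as.character(id)
      while (!is.na(parent[[cur]])) {
        if (cur %in% seen) return("ontology parent links contain a cycle")
        seen <- c(seen, cur)
        cur <- as.character(parent[[cur]])
      }
    }
  }
  msg
}

setValidity("AtlasBundle", function(object) {
  msg <- .validOntology(object@ontology)
  if (!all(vapply(object@plates, is, logical(1), "AtlasPlate")))
    msg <- c(msg, "plates must all be AtlasPlate objects")
  aps <- vapply(object@plates, function(p) p@apMm, numeric(1))
  if (length(aps) > 1 && any(diff(aps) >= 0))
    msg <- c(msg, "plate AP coordinates must be strictly decreasing")
  ids <- object@ontology$region_id
  for (p in object@plates) {
    orphan <- setdiff(unique(as.vector(p@labelMask)), c(0, ids))
    if (length(orphan))
      msg <- c(msg, sprintf("plate at AP %g has mask ids absent from ontology: %s",
                            p@apMm, paste(sort(orphan), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' CorrespondencePointSet: paired atlas/image landmarks with undo history
#'
#' @slot pairs data.frame with columns \code{atlas_x}, \code{atlas_y},
#'   \code{image_x}, \code{image_y} (pixel coordinates).
#' @slot history list of previous \code{pairs} data.frames; every non-undo
#'   edit pushes the prior list, undo pops it.
#' @export
setClass("CorrespondencePointSet",
  representation(pairs = "data.frame", history = "list"),
  prototype(history = list())
)

setValidity("CorrespondencePointSet", function(object) {
  need <- c("atlas_x", "atlas_y", "image_x", "image_y")
  if (!all(need %in% names(object@pairs)))
    return(sprintf("pairs must have columns %s", paste(need, collapse = ", ")))
  TRUE
})

#' Warp: a fitted 2D thin-plate-spline plate registration
#'
#' Forward (image to atlas) and inverse (atlas to image) mappings are
#' fitted independently from the same control pairs by swapping source
#' and target roles.
#'
#' @slot controlPairs the pairs the warp was fitted from.
#' @slot lambda regularization weight (0 = interpolating spline).
#' @slot forward,inverse lists with elements \code{src} (n x 2 control
#'   sources) and \code{coef} ((n + 3) x 2 spline/affine coefficients).
#' @export
setClass("Warp",
  representation(
    controlPairs = "data.frame",
    lambda = "numeric",
    forward = "list",
    inverse = "list"
  )
)

setValidity("Warp", function(object) {
  if (length(object@lambda) != 1 || object@lambda < 0)
    return("lambda must be a single number >= 0")
  for (d in c("forward", "inverse")) {
    co <- slot(object, d)
    if (!all(c("src", "coef") %in% names(co)))
      return(sprintf("%s must have elements src and coef", d))
    if (nrow(co$coef) != nrow(co$src) + 3L)
      return(sprintf("%s coef must have n + 3 rows", d))
  }
  TRUE
})

#' SegmentationFilter: blob segmentation parameters
#'
#' Difference-of-Gaussians band-pass followed by thresholding and
#' connected-component area filtering.
#'
#' @slot sigmaSmallUm,sigmaLargeUm band-pass scales in micrometers
#'   (small < large).
#' @slot threshold threshold on the filtered response; interpreted per
#'   \code{thresholdType}.
#' @slot thresholdType \code{"absolute"} (threshold is a response value)
#'   or \code{"quantile"} (threshold is a quantile in (0, 1) of the
#'   response distribution).
#' @slot minAreaUm2,maxAreaUm2 accepted object area bounds in square
#'   micrometers.
#' @export
setClass("SegmentationFilter",
  representation(
    sigmaSmallUm = "numeric",
    sigmaLargeUm = "numeric",
    threshold = "numeric",
    thresholdType = "character",
    minAreaUm2 = "numeric",
    maxAreaUm2 = "numeric"
  ),
  prototype(thresholdType = "absolute")
)

setValidity("SegmentationFilter", function(object) {
  msg <- character()
  if (object@sigmaSmallUm <= 0 || object@sigmaLargeUm <= object@sigmaSmallUm)
    msg <- c(msg, "need 0 < sigmaSmallUm < sigmaLargeUm")
  if (!object@thresholdType %in% c("absolute", "quantile"))
    msg <- c(msg, "thresholdType must be 'absolute' or 'quantile'")
  if (object@thresholdType == "quantile" &&
      (object@threshold <= 0 || object@threshold >= 1))
    msg <- c(msg, "quantile threshold must be in (0, 1)")
  if (object@minAreaUm2 >= object@maxAreaUm2 || object@minAreaUm2 < 0)
    msg <- c(msg, "need 0 <= minAreaUm2 < maxAreaUm2")
  if (length(msg)) msg else TRUE
})

#' CleanupParams: duplicate-detection grouping thresholds
#'
#' @slot xyThreshUm maximum in-plane centroid distance (um) for two
#'   detections to be considered the same cell.
#' @slot zThreshUm maximum axial separation (um) for grouping.
#' @export
setClass("CleanupParams",
  representation(xyThreshUm = "numeric", zThreshUm = "numeric")
)

setValidity("CleanupParams", function(object) {
  if (object@xyThreshUm <= 0 || object@zThreshUm < 0)
    return("xyThreshUm must be > 0 and zThreshUm >= 0")
  TRUE
})

#' PhantomSpec: synthetic ground-truth dataset parameters
#'
#' Defines a synthetic coronal stack: a monotone nonlinear z-to-AP morph,
#' a miniature nested-region atlas, cells rendered as 3D Gaussian blobs
#' spanning several adjacent planes (the duplicate-generation mechanism),
#' and Gaussian background noise.
#'
#' @slot nPlanes number of planes (default 300).
#' @slot planeShape integer c(height, width) in pixels (default 256 x 256).
#' @slot pixelSizeUm in-plane pixel size (default 5 um).
#' @slot zStepUm plane spacing (default 2.5 um, matching high z-resolution
#'   light-sheet acquisition).
#' @slot apStartMm,apEndMm AP coordinates of the first and last plane;
#'   the span defaults to nPlanes * zStepUm so plane spacing and AP are
#'   physically consistent.
#' @slot morphAmplitudeMm peak deviation of the true z-AP map from the
#'   straight line between endpoints (mm).
#' @slot morphPeak relative stack position in [0.45, 0.55] where the
#'   deviation peaks; monotonicity is guaranteed for amplitudes up to
#'   0.4 x span.
#' @slot nCells number of cells to plant.
#' @slot cellSigmaXyUm,cellSigmaZUm in-plane and axial Gaussian spread of
#'   a rendered cell (um).
#' @slot noiseSd standard deviation of additive Gaussian background noise
#'   (image intensities are in [0, 1]).
#' @slot seed integer random seed making the phantom fully deterministic.
#' @export
setClass("PhantomSpec",
  representation(
    nPlanes = "integer",
    planeShape = "integer",
    pixelSizeUm = "numeric",
    zStepUm = "numeric",
    apStartMm = "numeric",
    apEndMm = "numeric",
    morphAmplitudeMm = "numeric",
    morphPeak = "numeric",
    nCells = "integer",
    cellSigmaXyUm = "numeric",
    cellSigmaZUm = "numeric",
    noiseSd = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@nPlanes < 2) msg <- c(msg, "nPlanes must be >= 2")
  if (length(object@planeShape) != 2 || any(object@planeShape < 16))
    msg <- c(msg, "planeShape must be two integers >= 16")
  if (object@pixelSizeUm <= 0 || object@zStepUm <= 0)
    msg <- c(msg, "pixelSizeUm and zStepUm must be positive")
  if (object@apStartMm <= object@apEndMm)
    msg <- c(msg, "apStartMm must exceed apEndMm (anterior first)")
  if (object@morphAmplitudeMm < 0)
    msg <- c(msg, "morphAmplitudeMm must be >= 0")
  if (object@morphPeak < 0.45 || object@morphPeak > 0.55)
    msg <- c(msg, "morphPeak must lie in [0.45, 0.55]")
  span <- object@apStartMm - object@apEndMm
  if (object@morphAmplitudeMm > 0.4 * span)
    msg <- c(msg, "morphAmplitudeMm too large for a monotone morph (limit 0.4 x AP span)")
  if (object@nCells < 0) msg <- c(msg, "nCells must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})
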