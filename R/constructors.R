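#' Construct an AlignmentMap
#'
#' Typically started with just the two manually assigned endpoint anchors;
#' [choiceGame()] and [midpointCheck()] add internal anchors.
#'
#' @param z_index integer vector of 0-based plane indices.
#' @param ap_mm AP coordinates (mm from bregma) of those planes; must be
#'   strictly decreasing in z.
#' @param nPlanes total number of planes in the stack.
#' @param zStepUm plane spacing in micrometers.
#' @param source anchor provenance labels, recycled; one of
#'   \code{"endpoint"}, \code{"choice_game"}, \code{"midpoint_check"}.
#' @return an [AlignmentMap-class] object.
#' @examples
#' m <- alignmentMap(c(0, 299), c(0.375, -0.375), nPlanes = 300, zStepUm = 2.5)
#' interpolateAP(m, 150)
#' @export
alignmentMap <- function(z_index, ap_mm, nPlanes, zStepUm,
                         source = "endpoint") {
  ord <- order(z_index)
  a <- data.frame(z_index = as.integer(z_index[ord]), ap_mm = ap_mm[ord],
                  source = rep_len(as.character(source), length(z_index))[ord],
                  stringsAsFactors = FALSE)
  new("AlignmentMap", anchors = a, nPlanes = as.integer(nPlanes),
      zStepUm = zStepUm)
}

#' Construct a ChoiceGameConfig
#'
#' @param stepSchedule plane offsets per refinement level; the default
#'   progression of z-step choices is 200, 100, 30, 10 planes.
#' @param referenceAps internal reference plate AP coordinates (mm);
#'   defaults to the seven suggested plates of [defaultReferencePlates()].
#' @return a [ChoiceGameConfig-class] object.
#' @export
choiceGameConfig <- function(stepSchedule = c(200, 100, 30, 10),
                             referenceAps = defaultReferencePlates()$ap_mm) {
  new("ChoiceGameConfig", stepSchedule = as.numeric(stepSchedule),
      referenceAps = as.numeric(referenceAps))
}

#' Construct a SegmentationFilter
#'
#' Defaults suit small immunolabeled somata imaged at ~5 um/pixel: a
#' 5/20 um difference-of-Gaussians band-pass and a 100-2000 um2 area
#' gate (a 10-um-diameter disc is ~79 um2).
#'
#' @param sigmaSmallUm,sigmaLargeUm band-pass scales (um), small < large.
#' @param threshold threshold on the band-pass response.
#' @param thresholdType \code{"absolute"} or \code{"quantile"}.
#' @param minAreaUm2,maxAreaUm2 accepted object area range (um2).
#' @return a [SegmentationFilter-class] object.
#' @export
segmentationFilter <- function(sigmaSmallUm = 5, sigmaLargeUm = 20,
                               threshold = 0.05,
                               thresholdType = "absolute",
                               minAreaUm2 = 100, maxAreaUm2 = 2000) {
  new("SegmentationFilter", sigmaSmallUm = sigmaSmallUm,
      sigmaLargeUm = sigmaLargeUm, threshold = threshold,
      thresholdType = thresholdType, minAreaUm2 = minAreaUm2,
      maxAreaUm2 = maxAreaUm2)
}

#' Construct CleanupParams
#'
#' Defaults: 10 um in-plane and 7.5 um axial (three planes at a 2.5 um
#' z-step), matching the axial footprint of a small soma.
#'
#' @param xyThreshUm max in-plane centroid distance (um).
#' @param zThreshUm max axial separation (um).
#' @return a [CleanupParams-class] object.
#' @export
cleanupParams <- function(xyThreshUm = 10, zThreshUm = 7.5) {
  new("CleanupParams", xyThreshUm = xyThreshUm, zThreshUm = zThreshUm)
}

#' Construct a PhantomSpec
#'
#' The default phantom is a 300-plane, 256 x 256 pixel partial-brain
#' stack at 2.5 um z-step and 5 um pixels, whose AP span
#' (nPlanes x zStep = 0.75 mm) is physically consistent with the plane
#' spacing. Cells are 3D Gaussian blobs whose axial spread makes each
#' appear on several adjacent planes.
#'
#' @param nPlanes,planeShape stack geometry.
#' @param pixelSizeUm,zStepUm physical calibration (um).
#' @param apStartMm AP of plane 0 (mm from bregma).
#' @param apEndMm AP of the last plane; default places the span at
#'   nPlanes x zStepUm below apStartMm.
#' @param morphAmplitudeMm peak nonlinear deviation of the z-AP map (mm).
#' @param morphPeak relative position of the deviation peak, in
#'   [0.45, 0.55].
#' @param nCells number of planted cells.
#' @param cellSigmaXyUm,cellSigmaZUm blob spread (um).
#' @param noiseSd background Gaussian noise sd (intensity units, [0, 1]).
#' @param seed integer seed; phantoms are bit-reproducible.
#' @return a [PhantomSpec-class] object.
#' @export
phantomSpec <- function(nPlanes = 300, planeShape = c(256, 256),
                        pixelSizeUm = 5, zStepUm = 2.5,
                        apStartMm = 0.5,
                        apEndMm = apStartMm - nPlanes * zStepUm / 1000,
                        morphAmplitudeMm = 0.2, morphPeak = 0.5,
                        nCells = 25, cellSigmaXyUm = 10,
                        cellSigmaZUm = 3.5, noiseSd = 0.01, seed = 1) {
  new("PhantomSpec", nPlanes = as.integer(nPlanes),
      planeShape = as.integer(planeShape), pixelSizeUm = pixelSizeUm,
      zStepUm = zStepUm, apStartMm = apStartMm, apEndMm = apEndMm,
      morphAmplitudeMm = morphAmplitudeMm, morphPeak = morphPeak,
      nCells = as.integer(nCells), cellSigmaXyUm = cellSigmaXyUm,
      cellSigmaZUm = cellSigmaZUm, noiseSd = noiseSd,
      seed = as.integer(seed))
}
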