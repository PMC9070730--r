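## Anchor-based AP alignment: piecewise interpolation, the coarse-to-fine
## "choice game", the midpoint check, morph-ratio profiling and the
## linear-prediction error analysis.

.requireEndpoints <- function(map) {
  a <- map@anchors
  if (nrow(a) < 2 || a$z_index[1] != 0L || a$z_index[nrow(a)] != map@nPlanes - 1L)
    stop("alignment map must anchor both endpoints (plane 0 and the last plane) before interpolation")
}

#' Interpolate the AP coordinate of a plane
#'
#' Piecewise-linear interpolation between the bracketing anchors of the
#' map. Exact at every anchor and strictly decreasing in z.
#'
#' @param map an [AlignmentMap-class] with both endpoints anchored.
#' @param zIndex plane index (0-based); may be a vector, and need not be
#'   integral (half-planes arise in midpoint computations).
#' @return AP coordinate(s) in mm from bregma.
#' @export
interpolateAP <- function(map, zIndex) {
  .requireEndpoints(map)
  if (any(zIndex < 0 | zIndex > map@nPlanes - 1L))
    stop(sprintf("z index out of range [0, %d]", map@nPlanes - 1L))
  a <- map@anchors
  stats::approx(a$z_index, a$ap_mm, xout = zIndex, method = "linear",
                rule = 2)$y
}

## Insert one anchor, re-validating monotonicity (validity method runs
## in the constructor).
.insertAnchor <- function(map, zIndex, apMm, source) {
  a <- map@anchors
  if (zIndex %in% a$z_index) {
    at <- a$ap_mm[match(zIndex, a$z_index)]
    if (at == apMm) return(map)  # already anchored identically
    stop(sprintf("plane %d is already anchored at AP %+.4f; cannot re-anchor at %+.4f",
                 zIndex, at, apMm))
  }
  tryCatch(
    alignmentMap(c(a$z_index, zIndex), c(a$ap_mm, apMm), map@nPlanes,
                 map@zStepUm, source = c(a$source, source)),
    error = function(e) stop(sprintf(
      "inserting anchor (z = %d, AP = %+.4f) violates AP monotonicity: %s",
      zIndex, apMm, conditionMessage(e))))
}

## Would assigning apMm to plane zIndex keep the anchor set monotone?
.anchorCompatible <- function(map, zIndex, apMm) {
  a <- map@anchors
  before <- a$ap_mm[a$z_index < zIndex]
  after <- a$ap_mm[a$z_index > zIndex]
  at <- a$ap_mm[a$z_index == zIndex]
  (!length(before) || all(before > apMm)) &&
    (!length(after) || all(after < apMm)) &&
    (!length(at) || all(at == apMm))
}

#' Align one reference plate with the choice game
#'
#' Coarse-to-fine search for the image plane corresponding to a
#' reference atlas plate. The initial middle plane is the one whose
#' interpolated AP (from the current map) is closest to the reference
#' AP. Each cycle presents three candidates spaced by the current step
#' of the schedule; choosing left or right recenters the middle there
#' (step unchanged), choosing the middle advances to the next smaller
#' step, and choosing the middle at the finest step terminates. The
#' matched plane is then defined to lie at the reference AP and is
#' inserted into the map as a new anchor.
#'
#' @param map an [AlignmentMap-class] with endpoints anchored.
#' @param referenceAp AP (mm) of the reference plate, strictly between
#'   the endpoint APs.
#' @param chooser a chooser callback
#'   \code{function(left, middle, right, referenceAp, context)} returning
#'   \code{"left"}, \code{"middle"} or \code{"right"}; or a list with a
#'   \code{choose} element of that form (see [oracleChooser()]). A
#'   choice that would break AP monotonicity against existing anchors is
#'   rejected and the chooser re-prompted.
#' @param cfg a [ChoiceGameConfig-class].
#' @param source provenance label for the inserted anchor.
#' @param insert if \code{FALSE}, return the anchor without inserting.
#' @return list with \code{map} (updated), \code{anchor} (data.frame
#'   row: z_index, ap_mm, source) and \code{nCalls} (chooser calls).
#' @export
choiceGame <- function(map, referenceAp, chooser, cfg = choiceGameConfig(),
                       source = "choice_game", insert = TRUE) {
  .requireEndpoints(map)
  a <- map@anchors
  if (referenceAp >= a$ap_mm[1] || referenceAp <= a$ap_mm[nrow(a)])
    stop(sprintf("reference AP %+.4f not strictly inside the anchored range (%+.4f, %+.4f)",
                 referenceAp, a$ap_mm[nrow(a)], a$ap_mm[1]))
  choose <- if (is.list(chooser)) chooser$choose else chooser
  zmax <- map@nPlanes - 1L
  ## the matched plane must lie strictly between the anchors whose APs
  ## bracket the reference AP; candidates are clamped into that window
  ## (like the stack bounds), so no impossible plane is ever presented
  z_lo <- max(c(-1L, a$z_index[a$ap_mm > referenceAp])) + 1L
  z_hi <- min(c(map@nPlanes, a$z_index[a$ap_mm < referenceAp])) - 1L
  if (z_lo > z_hi)
    stop(sprintf("no free plane between the anchors bracketing AP %+.4f",
                 referenceAp))
  ## initial middle: plane whose interpolated AP is nearest the reference
  all_ap <- interpolateAP(map, z_lo:z_hi)
  middle <- z_lo + which.min(abs(all_ap - referenceAp)) - 1L
  schedule <- as.integer(cfg@stepSchedule)
  level <- 1L
  ncalls <- 0L
  max_calls <- map@nPlanes + 10L * length(schedule) + 10L
  while (TRUE) {
    s <- schedule[level]
    left <- max(z_lo, middle - s)
    right <- min(z_hi, middle + s)
    rejected <- 0L
    repeat {
      pick <- choose(left, middle, right, referenceAp,
                     list(map = map, step = s, level = level))
      ncalls <- ncalls + 1L
      if (ncalls > max_calls)
        stop("choice game did not converge (chooser call limit exceeded)")
      if (!pick %in% c("left", "middle", "right"))
        stop(sprintf("chooser returned '%s'; expected left/middle/right", pick))
      cand <- switch(pick, left = left, middle = middle, right = right)
      if (.anchorCompatible(map, cand, referenceAp)) break
      rejected <- rejected + 1L
      message(sprintf(
        "choice '%s' (plane %d) would violate AP monotonicity against existing anchors; choose again",
        pick, cand))
      if (rejected >= 3L)
        stop("chooser repeatedly proposed planes incompatible with existing anchors")
    }
    if (pick == "middle") {
      if (level == length(schedule)) break
      level <- level + 1L
    } else {
      middle <- cand
    }
  }
  anchor <- data.frame(z_index = as.integer(middle), ap_mm = referenceAp,
                       source = source, stringsAsFactors = FALSE)
  out_map <- if (insert) .insertAnchor(map, anchor$z_index, anchor$ap_mm, source)
             else map
  list(map = out_map, anchor = anchor, nCalls = ncalls)
}

#' Play the choice game for every reference plate
#'
#' Convenience loop running [choiceGame()] at each AP of the config's
#' reference list that falls strictly inside the map's anchored range
#' (reference plates outside a partial stack are skipped with a
#' message).
#'
#' @inheritParams choiceGame
#' @return the updated [AlignmentMap-class].
#' @export
alignReferencePlates <- function(map, chooser, cfg = choiceGameConfig()) {
  for (ap in cfg@referenceAps) {
    a <- map@anchors
    if (ap >= a$ap_mm[1] || ap <= a$ap_mm[nrow(a)]) {
      message(sprintf("reference AP %+.2f outside the stack range; skipped", ap))
      next
    }
    map <- choiceGame(map, ap, chooser, cfg)$map
  }
  map
}

#' Verify interval midpoints and re-anchor where rejected
#'
#' For each consecutive anchor pair of the incoming map, the midpoint
#' plane and its interpolated AP are presented to the chooser's
#' \code{accept} callback. Accepted midpoints leave the map unchanged;
#' a rejected midpoint triggers a new round of the choice game at that
#' interpolated AP, and the matched plane becomes an additional anchor
#' (source \code{midpoint_check}).
#'
#' @param map an [AlignmentMap-class] with at least two anchors.
#' @param chooser a list with elements \code{choose} (as in
#'   [choiceGame()]) and \code{accept}
#'   (\code{function(zIndex, apInterp, context)} returning TRUE/FALSE).
#' @param cfg a [ChoiceGameConfig-class].
#' @param atlas optional [AtlasBundle-class] passed to the chooser
#'   context (used by interactive choosers to display the plate).
#' @return the updated [AlignmentMap-class].
#' @export
midpointCheck <- function(map, chooser, cfg = choiceGameConfig(),
                          atlas = NULL) {
  if (nrow(map@anchors) < 2) stop("midpoint check needs at least 2 anchors")
  if (!is.list(chooser) || is.null(chooser$accept) || is.null(chooser$choose))
    stop("midpointCheck needs a chooser list with 'choose' and 'accept' callbacks")
  pairs0 <- map@anchors$z_index  # pairs existing at entry; one pass
  for (i in seq_len(length(pairs0) - 1L)) {
    z1 <- pairs0[i]; z2 <- pairs0[i + 1L]
    if (z2 - z1 < 2L) next
    zmid <- as.integer(round((z1 + z2) / 2))
    apmid <- interpolateAP(map, zmid)
    ok <- isTRUE(chooser$accept(zmid, apmid,
                                list(map = map, atlas = atlas)))
    if (ok) next
    res <- choiceGame(map, apmid, chooser, cfg, source = "midpoint_check")
    map <- res$map
  }
  map
}

#' Morph-ratio profile of an alignment map
#'
#' For each interval between consecutive anchors the morph ratio is the
#' local planes-per-mm divided by the endpoint-to-endpoint planes-per-mm:
#' \deqn{r_i = (\Delta z_i / |\Delta AP_i|) / (Z_{tot} / |AP_{tot}|).}
#' A perfectly linear morph gives 1 everywhere; ratios above 1 mark AP
#' stretches covered by disproportionately many planes (local expansion
#' of the tissue relative to the atlas). The |dAP|-weighted mean of the
#' ratios is exactly 1 by construction.
#'
#' @param map an [AlignmentMap-class] with >= 2 anchors.
#' @return a [MorphProfile-class].
#' @export
morphProfile <- function(map) {
  a <- map@anchors
  if (nrow(a) < 2) stop("morph profile needs at least 2 anchors")
  dz <- diff(a$z_index)
  dap <- abs(diff(a$ap_mm))
  if (any(dap == 0)) stop("zero-length AP interval between anchors")
  ztot <- a$z_index[nrow(a)] - a$z_index[1]
  aptot <- abs(a$ap_mm[nrow(a)] - a$ap_mm[1])
  ratio <- (dz / dap) / (ztot / aptot)
  new("MorphProfile", intervals = data.frame(
    ap_start_mm = a$ap_mm[-nrow(a)], ap_end_mm = a$ap_mm[-1],
    dz_planes = dz, morph_ratio = ratio))
}

#' Deviation of the aligned map from linear interpolation
#'
#' Recomputes every plane's AP twice: once from all anchors
#' (\code{ap_actual}) and once from the two endpoint anchors alone
#' (\code{ap_linear}, the prediction a linear model would make), and
#' reports their difference in micrometers. Planes lying more posterior
#' than their linear prediction get negative errors.
#'
#' @param map an [AlignmentMap-class] with endpoints anchored.
#' @return data.frame with one row per plane: \code{z_index},
#'   \code{ap_actual}, \code{ap_linear}, \code{error_um}, and
#'   \code{is_anchor}.
#' @export
linearPredictionError <- function(map) {
  .requireEndpoints(map)
  a <- map@anchors
  z <- 0:(map@nPlanes - 1L)
  lin_map <- alignmentMap(c(a$z_index[1], a$z_index[nrow(a)]),
                          c(a$ap_mm[1], a$ap_mm[nrow(a)]),
                          map@nPlanes, map@zStepUm)
  data.frame(z_index = z,
             ap_actual = interpolateAP(map, z),
             ap_linear = interpolateAP(lin_map, z),
             error_um = (interpolateAP(map, z) - interpolateAP(lin_map, z)) * 1000,
             is_anchor = z %in% a$z_index)
}

#' Interactive console chooser
#'
#' A chooser for [choiceGame()] and [midpointCheck()] that prompts on
#' the R console. For each decision the candidate plane images (when a
#' manifest is supplied) are written side by side as a PNG preview into
#' \code{figuresDir} so they can be inspected in any image viewer.
#'
#' @param manifest optional [StackManifest-class] used to render
#'   previews.
#' @param figuresDir directory for preview images.
#' @return a chooser list with \code{choose} and \code{accept}
#'   callbacks.
#' @export
consoleChooser <- function(manifest = NULL, figuresDir = tempdir()) {
  preview <- function(zs, tag) {
    if (is.null(manifest)) return(invisible(NULL))
    zs <- unique(zs)
    imgs <- lapply(imagePaths(manifest)[zs + 1L], tiff::readTIFF)
    f <- file.path(figuresDir, sprintf("preview_%s.png", tag))
    grDevices::png(f, width = 320 * length(imgs), height = 320)
    graphics::par(mfrow = c(1, length(imgs)), mar = c(0.5, 0.5, 1.5, 0.5))
    for (i in seq_along(imgs)) {
      graphics::plot.new()
      graphics::rasterImage(imgs[[i]], 0, 0, 1, 1)
      graphics::title(sprintf("plane %d", zs[i]))
    }
    grDevices::dev.off()
    message(sprintf("preview written: %s", f))
  }
  list(
    choose = function(left, middle, right, referenceAp, context) {
      preview(c(left, middle, right),
              sprintf("choice_ap%+.2f_step%d", referenceAp, context$step))
      repeat {
        ans <- tolower(trimws(readline(sprintf(
          "reference AP %+.3f | [l]eft %d  [m]iddle %d  [r]ight %d ? ",
          referenceAp, left, middle, right))))
        if (ans %in% c("l", "left")) return("left")
        if (ans %in% c("m", "middle")) return("middle")
        if (ans %in% c("r", "right")) return("right")
        message("please answer l, m or r")
      }
    },
    accept = function(zIndex, apInterp, context) {
      preview(zIndex, sprintf("midpoint_z%d", zIndex))
      repeat {
        ans <- tolower(trimws(readline(sprintf(
          "midpoint plane %d at interpolated AP %+.3f: accept? [y/n] ",
          zIndex, apInterp))))
        if (ans %in% c("y", "yes")) return(TRUE)
        if (ans %in% c("n", "no")) return(FALSE)
        message("please answer y or n")
      }
    })
}
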