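## Per-plane blob segmentation (difference-of-Gaussians band-pass,
## threshold, connected components, area gate) and consolidation of
## per-plane detections into 3D cells.

#' Segment blobs in one coronal plane
#'
#' Band-pass filters the plane with a difference of Gaussians at the
#' filter's two scales, thresholds the response, labels connected
#' components, discards components outside the area bounds, and reports
#' each surviving object's intensity-weighted centroid (in physical
#' micrometers), area and peak raw intensity.
#'
#' @param image 2D numeric matrix, intensities in [0, 1].
#' @param filt a [SegmentationFilter-class].
#' @param pixelSizeUm in-plane pixel size (um); both filter scales must
#'   be at least one pixel after conversion.
#' @return data.frame with columns \code{x_um}, \code{y_um},
#'   \code{peak_intensity}, \code{area_um2} (one row per detection;
#'   zero rows when nothing passes). Coordinates are 0-based pixel
#'   centers scaled by the pixel size.
#' @export
segmentPlane <- function(image, filt, pixelSizeUm) {
  if (pixelSizeUm <= 0) stop("pixelSizeUm must be positive")
  s1 <- filt@sigmaSmallUm / pixelSizeUm
  s2 <- filt@sigmaLargeUm / pixelSizeUm
  if (s1 < 1)
    stop(sprintf("sigmaSmallUm = %g um is below one pixel (%g um) after conversion",
                 filt@sigmaSmallUm, pixelSizeUm))
  dog <- EBImage::gblur(image, sigma = s1) - EBImage::gblur(image, sigma = s2)
  thr <- if (filt@thresholdType == "quantile")
    stats::quantile(dog, filt@threshold, names = FALSE) else filt@threshold
  lb <- EBImage::bwlabel(dog > thr)
  nlab <- max(lb)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      peak_intensity = numeric(0), area_um2 = numeric(0))
  if (nlab == 0) return(empty)
  px_area <- pixelSizeUm^2
  idx <- which(lb > 0)
  lab <- lb[idx]
  wt <- image[idx]
  row0 <- (idx - 1L) %% nrow(image)       # 0-based y
  col0 <- (idx - 1L) %/% nrow(image)      # 0-based x
  area <- tabulate(lab, nbins = nlab) * px_area
  wsum <- vapply(split(wt, lab), sum, numeric(1))
  xw <- vapply(split(wt * col0, lab), sum, numeric(1)) / wsum
  yw <- vapply(split(wt * row0, lab), sum, numeric(1)) / wsum
  peak <- vapply(split(wt, lab), max, numeric(1))
  keep <- area >= filt@minAreaUm2 & area <= filt@maxAreaUm2
  if (!any(keep)) return(empty)
  data.frame(x_um = xw[keep] * pixelSizeUm, y_um = yw[keep] * pixelSizeUm,
             peak_intensity = peak[keep], area_um2 = area[keep],
             row.names = NULL)
}

#' Segment every plane of a stack
#'
#' Loops [segmentPlane()] over the manifest in z order and concatenates
#' the per-plane detections with their plane index attached. With a
#' checkpoint directory the detections found so far are saved after
#' every plane, so a failed run preserves prior planes and a rerun
#' resumes after the last completed plane.
#'
#' @param manifest a [StackManifest-class].
#' @param filt a [SegmentationFilter-class].
#' @param checkpointDir optional \code{segmentation} directory for
#'   incremental saves and resume.
#' @param verbose log per-plane counts via [message()].
#' @return data.frame of detections: \code{x_um}, \code{y_um},
#'   \code{z_index}, \code{peak_intensity}, \code{area_um2}.
#' @export
segmentLoop <- function(manifest, filt, checkpointDir = NULL, verbose = FALSE) {
  paths <- imagePaths(manifest)
  cols <- c("x_um", "y_um", "z_index", "peak_intensity", "area_um2")
  done <- data.frame(x_um = numeric(0), y_um = numeric(0),
                     z_index = integer(0), peak_intensity = numeric(0),
                     area_um2 = numeric(0))
  start_z <- 0L
  ckpt <- if (!is.null(checkpointDir))
    file.path(checkpointDir, "detections.csv") else NULL
  progress_f <- if (!is.null(checkpointDir))
    file.path(checkpointDir, "progress.yaml") else NULL
  if (!is.null(ckpt) && file.exists(ckpt) && file.exists(progress_f)) {
    done <- .readTableExact(ckpt)[, cols]
    start_z <- yaml::read_yaml(progress_f)$next_z
  }
  out <- list(done)
  z <- start_z
  while (z < length(paths)) {
    img <- tryCatch(tiff::readTIFF(paths[z + 1L]), error = function(e) {
      if (!is.null(ckpt)) {
        .writeTableExact(do.call(rbind, out), ckpt)
        yaml::write_yaml(list(next_z = z), progress_f)
      }
      stop(sprintf("cannot read plane %d (%s): %s", z, paths[z + 1L],
                   conditionMessage(e)), call. = FALSE)
    })
    det <- segmentPlane(img, filt, pixelSizeUm(manifest))
    det$z_index <- rep(z, nrow(det))
    det <- det[, cols]
    out[[length(out) + 1L]] <- det
    if (verbose) message(sprintf("plane %d: %d detections", z, nrow(det)))
    if (!is.null(ckpt)) {
      .writeTableExact(do.call(rbind, out), ckpt)
      yaml::write_yaml(list(next_z = z + 1L), progress_f)
    }
    z <- z + 1L
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Union-find with path halving.
.ufFind <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Consolidate per-plane detections into 3D cells
#'
#' A cell imaged at a fine z-step appears on several adjacent planes and
#' is detected once per plane. Detections are linked whenever their
#' in-plane centroid distance is within \code{xyThreshUm} AND their
#' axial separation (plane difference times the z-step) is within
#' \code{zThreshUm}; each connected component of this graph becomes one
#' cell, positioned at its maximum-intensity member (ties broken toward
#' the lower plane), with the remaining members erased. Grouping is
#' transitive: a chain of near detections merges even when its extremes
#' are far apart, which is what a cell smeared across many planes
#' produces.
#'
#' Candidate neighbors are found by spatial grid binning, not all-pairs
#' comparison, but the result is identical to the brute-force graph.
#'
#' @param dets detections data.frame from [segmentLoop()].
#' @param p a [CleanupParams-class].
#' @param zStepUm plane spacing (um).
#' @return data.frame of cells: \code{x_um}, \code{y_um},
#'   \code{z_index}, \code{peak_intensity}, \code{n_merged}.
#' @export
cleanDuplicates <- function(dets, p, zStepUm) {
  n <- nrow(dets)
  if (!n)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_index = integer(0), peak_intensity = numeric(0),
                      n_merged = integer(0)))
  xy_t <- p@xyThreshUm
  z_win <- floor(p@zThreshUm / zStepUm + 1e-9)  # max |dz| in planes
  gx <- floor(dets$x_um / xy_t)
  gy <- floor(dets$y_um / xy_t)
  key <- paste(gx, gy, sep = ",")
  bins <- split(seq_len(n), key)
  bin_of <- function(a, b) paste(a, b, sep = ",")
  parent <- seq_len(n)
  for (b in names(bins)) {
    ij <- as.integer(strsplit(b, ",", fixed = TRUE)[[1]])
    members <- bins[[b]]
    ## neighbors: own bin plus the 8 surrounding bins; to avoid double
    ## work only look at bins lexicographically >= own, plus within-bin
    for (d in list(c(0, 0), c(1, 0), c(-1, 1), c(0, 1), c(1, 1))) {
      nb <- bins[[bin_of(ij[1] + d[1], ij[2] + d[2])]]
      if (is.null(nb)) next
      if (d[1] == 0 && d[2] == 0) {
        if (length(members) < 2) next
        cand <- utils::combn(members, 2)
        ii <- cand[1, ]; jj <- cand[2, ]
      } else {
        g <- expand.grid(members, nb)
        ii <- g[[1]]; jj <- g[[2]]
      }
      dz_ok <- abs(dets$z_index[ii] - dets$z_index[jj]) <= z_win
      if (!any(dz_ok)) next
      ii <- ii[dz_ok]; jj <- jj[dz_ok]
      d2 <- (dets$x_um[ii] - dets$x_um[jj])^2 +
            (dets$y_um[ii] - dets$y_um[jj])^2
      hit <- d2 <= xy_t^2
      for (k in which(hit)) {
        ri <- .ufFind(parent, ii[k]); rj <- .ufFind(parent, jj[k])
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), function(i) .ufFind(parent, i), integer(1))
  comp <- split(seq_len(n), root)
  rows <- vapply(comp, function(m) {
    best <- m[order(-dets$peak_intensity[m], dets$z_index[m])][1]
    best
  }, integer(1))
  cells <- data.frame(x_um = dets$x_um[rows], y_um = dets$y_um[rows],
                      z_index = dets$z_index[rows],
                      peak_intensity = dets$peak_intensity[rows],
                      n_merged = lengths(comp))
  cells <- cells[order(cells$z_index, cells$x_um, cells$y_um), ]
  rownames(cells) <- NULL
  cells
}
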