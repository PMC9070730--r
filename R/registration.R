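## Per-plate nonrigid registration from correspondence points: contour
## initialization, point editing with undo, warp fitting, persistence
## and the batch registration loop.

## Resample a closed polygon at n equal arc-length positions, starting
## at its first vertex.
.resamplePolygon <- function(pts, n) {
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  at <- (seq_len(n) - 1) / n * total
  cbind(x = stats::approx(s, closed[, 1], xout = at)$y,
        y = stats::approx(s, closed[, 2], xout = at)$y)
}

#' Initialize correspondence points from tissue contours
#'
#' Builds the starting point set for plate registration: the tissue
#' mask is found by an automatic Otsu threshold on log intensity, the
#' outer contour of its largest connected component is traced, and
#' \code{nPoints} samples at equal arc length are paired with equal
#' arc-length samples of the plate outline. Both contours start at
#' their dorsal-most point and run clockwise, so pairing is
#' deterministic and respects the bilateral symmetry of coronal
#' sections.
#'
#' @param image 2D numeric matrix (intensities in [0, 1]).
#' @param plate the [AtlasPlate-class] being registered.
#' @param nPoints number of correspondence pairs (>= 8).
#' @return a [CorrespondencePointSet-class] with \code{nPoints} pairs.
#' @export
initCorrespondence <- function(image, plate, nPoints = 32) {
  if (nPoints < 8) stop("nPoints must be >= 8")
  if (!length(image) || all(image == image[1]))
    stop("image is empty or constant; no foreground to contour")
  li <- log1p(image)
  li <- (li - min(li)) / (max(li) - min(li))
  thr <- EBImage::otsu(li, range = c(0, 1))
  fg <- li > thr
  if (!any(fg)) stop("no foreground component found above the automatic threshold")
  ic <- .traceOutline(fg)
  if (nrow(ic) < nPoints)
    stop(sprintf("tissue contour has %d pixels; need >= nPoints = %d",
                 nrow(ic), nPoints))
  img_pts <- .resamplePolygon(ic, nPoints)
  atlas_pts <- .resamplePolygon(.orientContour(plate@outline), nPoints)
  new("CorrespondencePointSet",
      pairs = data.frame(atlas_x = atlas_pts[, 1], atlas_y = atlas_pts[, 2],
                         image_x = img_pts[, 1], image_y = img_pts[, 2]),
      history = list())
}

#' Edit a correspondence point set
#'
#' Every non-undo edit pushes the previous pair list onto the history
#' stack; \code{undo} pops it, restoring the exact prior state.
#'
#' @param ps a [CorrespondencePointSet-class].
#' @param action one of \code{"add"}, \code{"remove"}, \code{"move"},
#'   \code{"undo"}.
#' @param payload for \code{add}: list with \code{atlas} and
#'   \code{image} (each \code{c(x, y)}); for \code{remove}: a 1-based
#'   pair index; for \code{move}: list with \code{index}, \code{side}
#'   (\code{"atlas"} or \code{"image"}) and \code{xy}.
#' @return the edited [CorrespondencePointSet-class].
#' @export
editPoints <- function(ps, action, payload = NULL) {
  cur <- ps@pairs
  push <- function(new_pairs)
    new("CorrespondencePointSet", pairs = new_pairs,
        history = c(ps@history, list(cur)))
  switch(action,
    add = {
      stopifnot(is.list(payload), !is.null(payload$atlas), !is.null(payload$image))
      push(rbind(cur, data.frame(
        atlas_x = payload$atlas[1], atlas_y = payload$atlas[2],
        image_x = payload$image[1], image_y = payload$image[2])))
    },
    remove = {
      i <- payload
      if (!is.numeric(i) || i < 1 || i > nrow(cur))
        stop(sprintf("no pair with index %s (have %d pairs)",
                     deparse(payload), nrow(cur)))
      push(cur[-i, , drop = FALSE])
    },
    move = {
      stopifnot(is.list(payload))
      i <- payload$index
      if (!is.numeric(i) || i < 1 || i > nrow(cur))
        stop(sprintf("no pair with index %s (have %d pairs)",
                     deparse(payload$index), nrow(cur)))
      if (!payload$side %in% c("atlas", "image"))
        stop("move payload$side must be 'atlas' or 'image'")
      nxt <- cur
      nxt[i, paste0(payload$side, c("_x", "_y"))] <- payload$xy
      push(nxt)
    },
    undo = {
      h <- ps@history
      if (!length(h)) stop("nothing to undo: history is empty")
      new("CorrespondencePointSet", pairs = h[[length(h)]],
          history = h[-length(h)])
    },
    stop(sprintf("unknown edit action '%s'", action))
  )
}

#' Fit a thin-plate-spline warp from correspondence points
#'
#' Forward (image to atlas) and inverse (atlas to image) splines are
#' fitted independently by swapping source and target roles. With
#' \code{lambda = 0} the spline interpolates: every control point maps
#' exactly (to numerical precision); \code{lambda > 0} trades control
#' fidelity for smoothness.
#'
#' @param ps a [CorrespondencePointSet-class] with >= 4 non-collinear
#'   pairs.
#' @param lambda regularization weight (>= 0).
#' @return a [Warp-class].
#' @export
fitWarp <- function(ps, lambda = 0) {
  p <- ps@pairs
  if (nrow(p) < 4) stop("warp fitting needs at least 4 correspondence pairs")
  img <- as.matrix(p[, c("image_x", "image_y")])
  atl <- as.matrix(p[, c("atlas_x", "atlas_y")])
  dimnames(img) <- dimnames(atl) <- NULL
  new("Warp", controlPairs = p, lambda = lambda,
      forward = .tpsFit(img, atl, lambda),
      inverse = .tpsFit(atl, img, lambda))
}

#' Apply a fitted warp to points
#'
#' @param w a [Warp-class].
#' @param points n x 2 matrix (or data.frame) of (x, y) coordinates.
#' @param direction \code{"forward"} (image to atlas pixels) or
#'   \code{"inverse"} (atlas to image pixels).
#' @return n x 2 matrix of transformed coordinates.
#' @export
applyWarp <- function(w, points, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  pts <- as.matrix(points)
  if (!nrow(pts)) return(pts[, 1:2, drop = FALSE])
  out <- .tpsEval(slot(w, direction), pts[, 1:2, drop = FALSE])
  colnames(out) <- c("x", "y")
  out
}

#' Total bending energy of a warp
#'
#' Sum of the forward spline's bending energy over both output
#' coordinates; zero for a purely affine warp, non-increasing in
#' \code{lambda} for fixed control pairs.
#'
#' @param w a [Warp-class].
#' @return non-negative scalar.
#' @export
bendingEnergy <- function(w) .tpsBendingEnergy(w@forward)

.warpFileName <- function(ap) sprintf("plate_AP%+.4f", ap)

#' Save / load plate warps as text files
#'
#' Each registered plate is stored as a \code{.warp} YAML file holding
#' the plate AP, lambda, the control pairs (17 significant digits, so
#' doubles round-trip exactly) and the solved forward/inverse
#' coefficients, plus a companion \code{.csv} of the point pairs.
#' Loading refits the spline from the stored pairs, which reproduces
#' the coefficients deterministically.
#'
#' @param w a [Warp-class].
#' @param dir registrations directory.
#' @param ap plate AP coordinate (mm); also used in the file name.
#' @return \code{saveWarp}: the .warp path invisibly.
#'   \code{loadWarps}: named list of [Warp-class] (names are the APs
#'   formatted \code{"%+.4f"}), ordered anterior to posterior.
#' @export
saveWarp <- function(w, dir, ap) {
  ap <- as.numeric(ap)
  base <- file.path(dir, .warpFileName(ap))
  .writeTableExact(w@controlPairs, paste0(base, ".csv"))
  num <- function(x) sprintf("%.17g", x)
  doc <- list(
    ap_mm = num(ap), lambda = num(w@lambda),
    n_pairs = nrow(w@controlPairs),
    pairs = lapply(w@controlPairs, num),
    forward_coef = num(as.vector(w@forward$coef)),
    inverse_coef = num(as.vector(w@inverse$coef)))
  yaml::write_yaml(doc, paste0(base, ".warp"))
  invisible(paste0(base, ".warp"))
}

#' @rdname saveWarp
#' @export
loadWarps <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.warp$", full.names = TRUE))
  warps <- list()
  aps <- numeric()
  for (f in files) {
    doc <- yaml::read_yaml(f)
    pairs <- as.data.frame(lapply(doc$pairs, as.numeric))
    ps <- new("CorrespondencePointSet", pairs = pairs, history = list())
    warps[[length(warps) + 1L]] <- fitWarp(ps, lambda = as.numeric(doc$lambda))
    aps <- c(aps, as.numeric(doc$ap_mm))
  }
  ord <- order(-aps)
  warps <- warps[ord]
  names(warps) <- sprintf("%+.4f", aps[ord])
  warps
}

#' Batch registration loop over atlas plates
#'
#' For each requested plate AP: the image plane whose interpolated AP
#' is nearest is selected, correspondence points are initialized from
#' the tissue contour, the corrector callback may edit or reject them,
#' and the fitted warp is saved. Previously saved plates are skipped
#' unless \code{overwrite = TRUE}, so an interrupted loop resumes where
#' it left off.
#'
#' @param manifest a [StackManifest-class] (registration channel).
#' @param map an [AlignmentMap-class] with endpoints anchored.
#' @param atlas an [AtlasBundle-class].
#' @param plateAps AP coordinates (mm) of the plates to register; each
#'   must lie within the map's anchored AP range.
#' @param corrector callback \code{function(ps, plate, image, ap)}
#'   returning an edited [CorrespondencePointSet-class], or \code{NULL}
#'   to skip the plate. [autoCorrector()] accepts the initial points
#'   unchanged.
#' @param registrationsDir directory for saved warps; \code{NULL}
#'   disables persistence.
#' @param nPoints contour correspondence pairs per plate.
#' @param lambda spline regularization.
#' @param overwrite refit plates that already have a saved warp.
#' @return named list of [Warp-class], as in [loadWarps()].
#' @export
regiLoop <- function(manifest, map, atlas, plateAps, corrector = autoCorrector(),
                     registrationsDir = NULL, nPoints = 32, lambda = 0,
                     overwrite = FALSE) {
  a <- map@anchors
  warps <- list()
  for (ap in plateAps) {
    if (ap > a$ap_mm[1] || ap < a$ap_mm[nrow(a)])
      stop(sprintf("plate AP %+.4f outside the aligned range [%+.4f, %+.4f]",
                   ap, a$ap_mm[nrow(a)], a$ap_mm[1]))
    nm <- sprintf("%+.4f", ap)
    if (!is.null(registrationsDir) && !overwrite &&
        file.exists(file.path(registrationsDir,
                              paste0(.warpFileName(ap), ".warp")))) {
      message(sprintf("plate AP %s already registered; skipped", nm))
      next
    }
    z <- which.min(abs(interpolateAP(map, 0:(map@nPlanes - 1L)) - ap)) - 1L
    img <- tiff::readTIFF(imagePaths(manifest)[z + 1L])
    plate <- nearestPlate(atlas, ap)
    ps <- initCorrespondence(img, plate, nPoints)
    fitted <- NULL
    for (attempt in 1:2) {
      edited <- corrector(ps, plate, img, ap)
      if (is.null(edited)) break
      fitted <- tryCatch(fitWarp(edited, lambda), error = function(e) {
        message(sprintf("warp fit failed for plate AP %s: %s", nm,
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(fitted)) break
      ps <- edited  # re-prompt the corrector with its own edits
    }
    if (is.null(fitted)) {
      message(sprintf("plate AP %s skipped", nm))
      next
    }
    if (!is.null(registrationsDir)) saveWarp(fitted, registrationsDir, ap)
    warps[[nm]] <- fitted
  }
  if (!is.null(registrationsDir)) loadWarps(registrationsDir) else warps
}

#' Corrector that accepts the initial correspondence points
#'
#' @return a corrector callback for [regiLoop()].
#' @export
autoCorrector <- function() function(ps, plate, image, ap) ps
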