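## Synthetic phantom generator: image stacks, a miniature nested-region
## atlas and ground truth with exactly the structure the pipeline
## assumes, so every stage is testable without external data.

## Smoothed-tent deviation profile h(t) on [0, 1]: rises to 1 near
## `peak`, returns to 0, Gaussian-smoothed for a C-smooth morph. Max
## slope ~1/min(peak, 1 - peak), which bounds the admissible amplitude.
.morphDeviation <- function(t, peak) {
  h <- ifelse(t <= peak, t / peak, (1 - t) / (1 - peak))
  ng <- length(t)
  ## light smoothing only rounds the peak; heavier kernels would inflate
  ## the renormalized slope beyond the monotonicity budget at the
  ## maximum admissible amplitude (0.4 x AP span)
  sd_pts <- max(1, round(0.012 * ng))
  kern <- stats::dnorm(seq(-4 * sd_pts, 4 * sd_pts), sd = sd_pts)
  kern <- kern / sum(kern)
  ## pad by edge reflection so smoothing does not shrink the ends
  pad <- length(kern) %/% 2
  hp <- c(rev(h[seq_len(pad) + 1L]), h, rev(h[ng - seq_len(pad)]))
  hs <- stats::filter(hp, kern, sides = 2)[pad + seq_len(ng)]
  hs <- hs - (hs[1] + (hs[ng] - hs[1]) * t)  # pin endpoints to 0
  hs / max(hs)
}

#' True z-to-AP mapping of a phantom
#'
#' Linear ramp between the spec's endpoint APs plus a smoothed-tent
#' nonlinear deviation of the requested amplitude, shifted toward the
#' posterior. Strict monotonicity is verified and endpoint APs are
#' exact.
#'
#' @param spec a [PhantomSpec-class].
#' @return numeric vector of AP (mm), one per plane.
#' @export
phantomTrueAP <- function(spec) {
  n <- spec@nPlanes
  t <- (0:(n - 1)) / (n - 1)
  lin <- spec@apStartMm + (spec@apEndMm - spec@apStartMm) * t
  ap <- if (spec@morphAmplitudeMm > 0)
    lin - spec@morphAmplitudeMm * .morphDeviation(t, spec@morphPeak)
  else lin
  if (any(diff(ap) >= 0))
    stop("phantom morph is not strictly decreasing; lower morphAmplitudeMm")
  ap
}

.phantom_ontology <- data.frame(
  region_id = 1:7,
  acronym = c("BR", "CTX", "SUB", "PL", "IL", "TH", "HY"),
  name = c("brain", "cortex band", "subcortex band", "prelimbic patch",
           "infralimbic patch", "thalamic patch", "hypothalamic patch"),
  parent_id = c(NA, 1L, 1L, 2L, 2L, 3L, 3L),
  color_hex = c("#bfbfbf", "#70ff71", "#ff7080", "#2fa850", "#1f9d5a",
                "#ff909f", "#e64438"),
  stringsAsFactors = FALSE)

## Nested-region label mask shared by all phantom plates.
.phantomMask <- function(shape) {
  h <- shape[1]; w <- shape[2]
  xg <- matrix(rep(0:(w - 1), each = h), h, w)   # x = column, 0-based
  yg <- matrix(rep(0:(h - 1), times = w), h, w)  # y = row, 0-based
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  inEll <- function(x0, y0, a, b) ((xg - x0) / a)^2 + ((yg - y0) / b)^2 <= 1
  m <- matrix(0L, h, w)
  m[inEll(cx, cy, 0.42 * w, 0.38 * h)] <- 1L                       # tissue
  m[m == 1L & inEll(cx, cy - 0.13 * h, 0.30 * w, 0.15 * h)] <- 2L  # CTX
  m[m == 1L & inEll(cx, cy + 0.15 * h, 0.30 * w, 0.15 * h)] <- 3L  # SUB
  m[m == 2L & inEll(cx - 0.13 * w, cy - 0.13 * h, 0.08 * w, 0.10 * h)] <- 4L
  m[m == 2L & inEll(cx + 0.13 * w, cy - 0.13 * h, 0.08 * w, 0.10 * h)] <- 5L
  m[m == 3L & inEll(cx - 0.13 * w, cy + 0.15 * h, 0.08 * w, 0.10 * h)] <- 6L
  m[m == 3L & inEll(cx + 0.13 * w, cy + 0.15 * h, 0.08 * w, 0.10 * h)] <- 7L
  m
}

#' Miniature synthetic atlas bundle
#'
#' Five (or more) identical coronal plates of nested geometric regions
#' under a 7-region, 3-level ontology; the canonical example of the
#' atlas bundle format and the atlas used by the phantom pipeline.
#'
#' @param shape plate c(height, width) in pixels.
#' @param apRange c(anterior, posterior) AP limits (mm); plate APs are
#'   spread evenly across it.
#' @param nPlates number of plates (>= 2).
#' @return an [AtlasBundle-class].
#' @export
makeMiniAtlas <- function(shape = c(256L, 256L), apRange = c(0.5, -0.25),
                          nPlates = 5L) {
  m <- .phantomMask(shape)
  outline <- .traceOutline(m > 0)
  aps <- seq(apRange[1], apRange[2], length.out = nPlates)
  plates <- lapply(seq_along(aps), function(i)
    new("AtlasPlate", apMm = aps[i], plateNumber = i,
        labelMask = m, outline = outline))
  atlasBundle(plates, .phantom_ontology)
}

## Sample nCells positions uniformly within the leaf regions of the
## phantom mask, eroded so cells sit clear of region borders, with a
## minimum pairwise in-plane separation.
.placeCells <- function(mask, n, pixelSizeUm, minSepUm) {
  leaf_ids <- 4:7
  er <- EBImage::erode(matrix(as.numeric(mask > 0), nrow(mask)),
                       EBImage::makeBrush(5, "disc"))
  pools <- lapply(leaf_ids, function(id) {
    keep <- mask == id & er > 0
    which(keep)
  })
  ok <- lengths(pools) > 0
  leaf_ids <- leaf_ids[ok]; pools <- pools[ok]
  if (!length(pools)) stop("phantom regions too small to place any cells")
  xs <- ys <- numeric(0); region <- integer(0)
  attempts <- 0L
  while (length(xs) < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n)
      stop("phantom regions too small for the requested number of cells at the required separation")
    ri <- sample.int(length(pools), 1L)
    px <- sample(pools[[ri]], 1L)
    x <- ((px - 1L) %/% nrow(mask)) * pixelSizeUm   # 0-based col -> um
    y <- ((px - 1L) %% nrow(mask)) * pixelSizeUm
    if (length(xs) && min((xs - x)^2 + (ys - y)^2) < minSepUm^2) next
    xs <- c(xs, x); ys <- c(ys, y); region <- c(region, leaf_ids[ri])
  }
  data.frame(x_um = xs, y_um = ys, region_id = region)
}

#' Generate a synthetic phantom dataset
#'
#' Produces (deterministically, given the spec's seed) a coronal image
#' stack on disk, the miniature atlas it corresponds to, and full
#' ground truth. Cells are 3D Gaussian blobs: their axial spread makes
#' each appear on several adjacent planes, which is exactly the
#' duplicate-generation mechanism the cleanup stage must undo. The
#' tissue is a bright ellipse matching the atlas outline (so plate
#' registration on the phantom is a self-registration), over a dark
#' background with additive Gaussian noise.
#'
#' @param spec a [PhantomSpec-class].
#' @param dir directory for the stack's TIFF planes; \code{NULL}
#'   (with \code{render = FALSE}) skips image rendering for tests that
#'   only need the morph and cell truth.
#' @param render write the image planes.
#' @return list with elements \code{manifest} ([StackManifest-class] or
#'   NULL), \code{atlas} ([AtlasBundle-class]), and \code{truth}: a
#'   list with \code{true_ap} (per-plane AP), \code{cells} (x_um, y_um,
#'   z_center_um, z_center_plane, region_id, amplitude),
#'   \code{region_counts} (planted cells per region id) and
#'   \code{spec}.
#' @export
makePhantom <- function(spec, dir = NULL, render = !is.null(dir)) {
  if (render && is.null(dir)) stop("rendering requires an output directory")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec@seed)
  true_ap <- phantomTrueAP(spec)
  atlas <- makeMiniAtlas(spec@planeShape,
                         c(spec@apStartMm, spec@apEndMm), nPlates = 5L)
  mask <- atlas@plates[[1]]@labelMask
  cells <- if (spec@nCells > 0)
    .placeCells(mask, spec@nCells, spec@pixelSizeUm,
                minSepUm = max(60, 6 * spec@cellSigmaXyUm))
  else data.frame(x_um = numeric(0), y_um = numeric(0), region_id = integer(0))
  nz <- spec@nPlanes
  if (nrow(cells)) {
    margin <- 4L  # keep whole blobs inside the stack
    cells$z_center_um <- stats::runif(nrow(cells), margin * spec@zStepUm,
                                      (nz - 1L - margin) * spec@zStepUm)
    cells$z_center_plane <- round(cells$z_center_um / spec@zStepUm)
    cells$amplitude <- stats::runif(nrow(cells), 0.5, 0.85)
  } else {
    cells$z_center_um <- cells$amplitude <- numeric(0)
    cells$z_center_plane <- integer(0)
  }
  region_counts <- as.data.frame(table(factor(cells$region_id,
                                              levels = 1:7)),
                                 stringsAsFactors = FALSE)
  names(region_counts) <- c("region_id", "n_cells")
  region_counts$region_id <- as.integer(region_counts$region_id)
  manifest <- NULL
  if (render) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    h <- spec@planeShape[1]; w <- spec@planeShape[2]
    tissue <- 0.02 + 0.13 * (mask > 0)
    sx <- spec@cellSigmaXyUm / spec@pixelSizeUm
    win <- ceiling(4 * sx)
    paths <- character(nz)
    for (z in 0:(nz - 1L)) {
      img <- tissue
      zum <- z * spec@zStepUm
      act <- which(abs(cells$z_center_um - zum) <= 4 * spec@cellSigmaZUm)
      for (i in act) {
        az <- cells$amplitude[i] *
          exp(-(zum - cells$z_center_um[i])^2 / (2 * spec@cellSigmaZUm^2))
        cx <- cells$x_um[i] / spec@pixelSizeUm
        cy <- cells$y_um[i] / spec@pixelSizeUm
        r0 <- max(0L, floor(cy) - win):min(h - 1L, ceiling(cy) + win)
        c0 <- max(0L, floor(cx) - win):min(w - 1L, ceiling(cx) + win)
        blob <- az * exp(-(outer((r0 - cy)^2, (c0 - cx)^2, "+")) / (2 * sx^2))
        img[r0 + 1L, c0 + 1L] <- img[r0 + 1L, c0 + 1L] + blob
      }
      if (spec@noiseSd > 0)
        img <- img + matrix(stats::rnorm(h * w, sd = spec@noiseSd), h, w)
      img <- pmin(pmax(img, 0), 1)
      f <- file.path(dir, sprintf("phantom_Z%05d.tif", z))
      tiff::writeTIFF(round(img * 65535) / 65535, f, bits.per.sample = 16L)
      paths[z + 1L] <- f
    }
    manifest <- new("StackManifest", imagePaths = paths,
                    zStepUm = spec@zStepUm, pixelSizeUm = spec@pixelSizeUm,
                    channelTag = "phantom")
  }
  list(manifest = manifest, atlas = atlas,
       truth = list(true_ap = true_ap, cells = cells,
                    region_counts = region_counts, spec = spec))
}

#' Truthful chooser backed by phantom ground truth
#'
#' Stands in for the human in the choice game and midpoint check:
#' \code{choose} picks the candidate plane whose true AP is nearest the
#' reference AP (ties prefer the middle), and \code{accept} approves a
#' midpoint when the interpolated AP is within \code{acceptTolMm} of
#' the plane's true AP (a tolerance of 0 rejects every imperfect
#' midpoint, forcing maximal anchor insertion).
#'
#' @param truth the \code{truth} element of [makePhantom()] output (or
#'   any list with a \code{true_ap} vector).
#' @param acceptTolMm midpoint acceptance tolerance (mm).
#' @return chooser list with \code{choose} and \code{accept}.
#' @export
oracleChooser <- function(truth, acceptTolMm = 0.025) {
  ap <- truth$true_ap
  list(
    choose = function(left, middle, right, referenceAp, context) {
      d <- abs(ap[c(left, middle, right) + 1L] - referenceAp)
      if (d[2] <= min(d)) return("middle")
      c("left", "middle", "right")[which.min(d)]
    },
    accept = function(zIndex, apInterp, context)
      abs(ap[zIndex + 1L] - apInterp) <= acceptTolMm
  )
}
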