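## Plant isolated Gaussian spots on a plane; returns image + positions.
plantedPlane <- function(centers_px, shape = c(128, 128), sigma_px = 2,
                         amp = 0.6, noise = 0.005, seed = 1) {
  set.seed(seed)
  img <- matrix(0.02, shape[1], shape[2])
  for (i in seq_len(nrow(centers_px))) {
    cx <- centers_px[i, 1]; cy <- centers_px[i, 2]
    r0 <- pmax(0, floor(cy) - 10):pmin(shape[1] - 1, ceiling(cy) + 10)
    c0 <- pmax(0, floor(cx) - 10):pmin(shape[2] - 1, ceiling(cx) + 10)
    img[r0 + 1, c0 + 1] <- img[r0 + 1, c0 + 1] +
      amp * exp(-outer((r0 - cy)^2, (c0 - cx)^2, "+") / (2 * sigma_px^2))
  }
  img + matrix(rnorm(prod(shape), sd = noise), shape[1], shape[2])
}

test_that("segmentPlane finds planted spots and nothing on blank planes", {
  filt <- segmentationFilter()
  expect_equal(nrow(segmentPlane(matrix(0.1, 64, 64), filt, 5)), 0)
  centers <- cbind(x = c(30, 70, 100), y = c(40, 90, 30))
  img <- plantedPlane(centers)
  det <- segmentPlane(img, filt, 5)
  expect_equal(nrow(det), 3)
  for (i in 1:3) {
    d <- sqrt((det$x_um / 5 - centers[i, 1])^2 + (det$y_um / 5 - centers[i, 2])^2)
    expect_lt(min(d), 1)
  }
  expect_true(all(det$peak_intensity > 0.5))
  expect_true(all(det$area_um2 >= 100 & det$area_um2 <= 2000))
})

test_that("area bounds exclude too-small objects and sigma below a pixel errors", {
  centers <- cbind(x = 60, y = 60)
  img <- plantedPlane(centers)
  filt_ok <- segmentationFilter()
  expect_equal(nrow(segmentPlane(img, filt_ok, 5)), 1)
  ## raise the min area beyond the blob's footprint: excluded
  filt_big <- segmentationFilter(minAreaUm2 = 1900, maxAreaUm2 = 2000)
  expect_equal(nrow(segmentPlane(img, filt_big, 5)), 0)
  expect_error(segmentPlane(img, segmentationFilter(sigmaSmallUm = 3), 5),
               "below one pixel")
})

test_that("segmentLoop matches planted per-plane counts and resumes from checkpoints", {
  ph <- smallPhantom()
  filt <- segmentationFilter()
  dets <- segmentLoop(ph$manifest, filt)
  ## every planted cell appears on >= 3 adjacent planes (axial smear)
  tr <- ph$truth$cells
  for (i in seq_len(nrow(tr))) {
    hits <- sum(abs(dets$x_um - tr$x_um[i]) < 10 &
                abs(dets$y_um - tr$y_um[i]) < 10)
    expect_gte(hits, 3)
  }
  ## empty stack yields an empty table
  empty <- new("StackManifest", imagePaths = character(0), zStepUm = 2.5,
               pixelSizeUm = 5)
  expect_equal(nrow(segmentLoop(empty, filt)), 0)
  ## induced failure midway: prior planes preserved, resume identical
  d <- withr::local_tempdir()
  paths <- imagePaths(ph$manifest)
  broken <- paths
  broken[7] <- file.path(d, "missing_Z00006.tif")
  bad <- new("StackManifest", imagePaths = broken, zStepUm = 2.5,
             pixelSizeUm = 5)
  ck <- withr::local_tempdir()
  expect_error(segmentLoop(bad, filt, checkpointDir = ck), "missing_Z00006")
  file.copy(paths[7], broken[7])
  resumed <- segmentLoop(bad, filt, checkpointDir = ck)
  expect_equal(resumed, dets, ignore_attr = TRUE)
})

test_that("cleanDuplicates merges an axial chain at its intensity peak", {
  expect_equal(nrow(cleanDuplicates(randomDetections(0), cleanupParams(), 2.5)), 0)
  dets <- data.frame(x_um = c(50, 50, 50), y_um = c(80, 80, 80),
                     z_index = c(10L, 11L, 12L),
                     peak_intensity = c(5, 9, 7), area_um2 = 200)
  cells <- cleanDuplicates(dets, cleanupParams(xyThreshUm = 5, zThreshUm = 2.5),
                           zStepUm = 2.5)
  expect_equal(nrow(cells), 1)
  expect_equal(cells$z_index, 11L)
  expect_equal(cells$peak_intensity, 9)
  expect_equal(cells$n_merged, 3L)
  ## equal peaks tie toward the lower plane
  tie <- data.frame(x_um = 0, y_um = 0, z_index = c(4L, 5L),
                    peak_intensity = c(3, 3), area_um2 = 200)
  expect_equal(cleanDuplicates(tie, cleanupParams(zThreshUm = 2.5), 2.5)$z_index, 4L)
})

test_that("cleanDuplicates equals the brute-force all-pairs oracle", {
  set.seed(99)
  for (rep in 1:15) {
    n <- sample(c(20, 80, 200, 400), 1)
    dets <- randomDetections(n, extent_um = sample(c(100, 200, 400), 1))
    p <- cleanupParams(xyThreshUm = runif(1, 3, 30),
                       zThreshUm = runif(1, 0, 12))
    fast <- cleanDuplicates(dets, p, 2.5)
    slow <- bruteCleanOracle(dets, p, 2.5)
    expect_identical(fast, slow$cells)
  }
})

test_that("cell count never increases when thresholds grow, and degenerate thresholds are exact", {
  set.seed(41)
  dets <- randomDetections(300, extent_um = 300)
  counts <- sapply(c(2, 5, 10, 20, 40), function(xy)
    nrow(cleanDuplicates(dets, cleanupParams(xyThreshUm = xy, zThreshUm = 7.5), 2.5)))
  expect_true(all(diff(counts) <= 0))
  countsz <- sapply(c(0, 2.5, 5, 10, 25), function(z)
    nrow(cleanDuplicates(dets, cleanupParams(xyThreshUm = 10, zThreshUm = z), 2.5)))
  expect_true(all(diff(countsz) <= 0))
  ## z threshold 0 links only same-plane detections; with distinct planes
  ## per xy site the count equals the number of detections
  ph <- smallPhantom()
  dd <- segmentLoop(ph$manifest, segmentationFilter())
  z0 <- cleanDuplicates(dd, cleanupParams(xyThreshUm = 10, zThreshUm = 0), 2.5)
  expect_equal(nrow(z0), nrow(dd))
  ## thresholds covering the whole axial smear recover the planted count
  full <- cleanDuplicates(dd, cleanupParams(), 2.5)
  expect_equal(nrow(full), nrow(ph$truth$cells))
})
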