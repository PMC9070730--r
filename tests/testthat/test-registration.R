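## Render a clean tissue image directly from a plate's mask.
plateRendering <- function(plate, bg = 0.02, fg = 0.15)
  bg + (fg - bg) * (labelMask(plate) > 0)

test_that("initCorrespondence pairs contour samples consistently", {
  atlas <- makeMiniAtlas(shape = c(128L, 128L))
  plate <- plates(atlas)[[1]]
  img <- plateRendering(plate)
  ps <- initCorrespondence(img, plate, nPoints = 32)
  expect_equal(nrow(pointPairs(ps)), 32)
  ## self-registration: image IS the plate rendering, so paired points
  ## nearly coincide
  p <- pointPairs(ps)
  d <- sqrt((p$atlas_x - p$image_x)^2 + (p$atlas_y - p$image_y)^2)
  expect_lt(max(d), 1.5)
  expect_lt(median(d), 1)
  ## both curves are sampled in the same cyclic (clockwise) order
  ang <- function(x, y) atan2(y - mean(y), x - mean(x))
  dir_img <- sum(diff(unwrapAngles(ang(p$image_x, p$image_y))))
  dir_atl <- sum(diff(unwrapAngles(ang(p$atlas_x, p$atlas_y))))
  expect_equal(sign(dir_img), sign(dir_atl))
  expect_error(initCorrespondence(matrix(0.5, 64, 64), plate), "constant")
  expect_error(initCorrespondence(img, plate, nPoints = 4), ">= 8")
})

test_that("point edits behave and undo restores prior state exactly", {
  atlas <- makeMiniAtlas(shape = c(96L, 96L))
  img <- plateRendering(plates(atlas)[[1]])
  ps <- initCorrespondence(img, plates(atlas)[[1]], nPoints = 10)
  p0 <- pointPairs(ps)
  ps2 <- editPoints(ps, "add", list(atlas = c(1, 2), image = c(3, 4)))
  expect_equal(nrow(pointPairs(ps2)), 11)
  expect_identical(pointPairs(editPoints(ps2, "undo")), p0)
  ps3 <- editPoints(ps2, "remove", 3)
  expect_equal(nrow(pointPairs(ps3)), 10)
  expect_identical(pointPairs(ps3)[3, ], pointPairs(ps2)[4, ],
                   ignore_attr = TRUE)
  ps4 <- editPoints(ps3, "move", list(index = 1, side = "image", xy = c(7, 8)))
  expect_equal(as.numeric(pointPairs(ps4)[1, c("image_x", "image_y")]), c(7, 8))
  ## add, move, undo, undo returns to the original list
  back <- editPoints(editPoints(
    editPoints(editPoints(ps, "add", list(atlas = c(0, 0), image = c(0, 0))),
               "move", list(index = 2, side = "atlas", xy = c(9, 9))),
    "undo"), "undo")
  expect_identical(pointPairs(back), p0)
  expect_error(editPoints(ps, "undo"), "history is empty")
  expect_error(editPoints(ps, "remove", 99), "no pair")
})

test_that("any edit sequence followed by as many undos restores the initial set", {
  atlas <- makeMiniAtlas(shape = c(96L, 96L))
  img <- plateRendering(plates(atlas)[[1]])
  set.seed(6)
  for (rep in 1:10) {
    ps <- initCorrespondence(img, plates(atlas)[[1]], nPoints = 12)
    p0 <- pointPairs(ps)
    k <- sample(1:8, 1)
    for (i in seq_len(k)) {
      act <- sample(c("add", "remove", "move"), 1)
      n <- nrow(pointPairs(ps))
      ps <- switch(act,
        add = editPoints(ps, "add", list(atlas = runif(2), image = runif(2))),
        remove = if (n > 1) editPoints(ps, "remove", sample.int(n, 1))
                 else editPoints(ps, "add", list(atlas = runif(2), image = runif(2))),
        move = editPoints(ps, "move", list(index = sample.int(n, 1),
                                           side = sample(c("atlas", "image"), 1),
                                           xy = runif(2))))
    }
    for (i in seq_len(k)) ps <- editPoints(ps, "undo")
    expect_identical(pointPairs(ps), p0)
  }
})

test_that("interpolating TPS reproduces affine maps exactly and controls to 1e-6 px", {
  set.seed(17)
  src <- cbind(runif(12, 0, 100), runif(12, 0, 100))
  identity_ps <- new("CorrespondencePointSet",
                     pairs = data.frame(atlas_x = src[, 1], atlas_y = src[, 2],
                                        image_x = src[, 1], image_y = src[, 2]))
  w_id <- fitWarp(identity_ps)
  probes <- cbind(runif(50, -20, 120), runif(50, -20, 120))
  expect_lt(max(abs(applyWarp(w_id, probes) - probes)), 1e-9)
  ## pure translation everywhere
  trans_ps <- new("CorrespondencePointSet",
                  pairs = data.frame(atlas_x = src[, 1] + 10,
                                     atlas_y = src[, 2] - 5,
                                     image_x = src[, 1], image_y = src[, 2]))
  w_tr <- fitWarp(trans_ps)
  shifted <- applyWarp(w_tr, probes) - probes
  expect_lt(max(abs(shifted[, 1] - 10)), 1e-9)
  expect_lt(max(abs(shifted[, 2] + 5)), 1e-9)
  ## generic pairs: interpolation property at lambda = 0
  for (rep in 1:5) {
    s <- cbind(runif(8, 0, 200), runif(8, 0, 200))
    t <- s + cbind(rnorm(8, sd = 8), rnorm(8, sd = 8))
    ps <- new("CorrespondencePointSet",
              pairs = data.frame(atlas_x = t[, 1], atlas_y = t[, 2],
                                 image_x = s[, 1], image_y = s[, 2]))
    w <- fitWarp(ps)
    expect_lt(max(abs(applyWarp(w, s) - t)), 1e-6)
    expect_lt(max(abs(applyWarp(w, t, "inverse") - s)), 1e-6)
  }
})

test_that("TPS rejects degenerate configurations", {
  line <- data.frame(atlas_x = 1:6, atlas_y = 2 * (1:6) + 1,
                     image_x = 1:6, image_y = 2 * (1:6) + 1)
  expect_error(fitWarp(new("CorrespondencePointSet", pairs = line)),
               "collinear")
  dup <- data.frame(atlas_x = c(1, 1, 2, 3), atlas_y = c(1, 1, 5, 2),
                    image_x = c(1, 1, 2, 3), image_y = c(1, 1, 5, 2))
  expect_error(fitWarp(new("CorrespondencePointSet", pairs = dup)),
               "singular|duplicated")
  expect_error(fitWarp(new("CorrespondencePointSet", pairs = line[1:3, ])),
               "at least 4")
})

test_that("forward/inverse round trip is tight inside the control hull and energy shrinks with lambda", {
  set.seed(23)
  ## well-spread controls: a 5 x 5 grid with a mild smooth deformation
  g <- expand.grid(x = seq(0, 200, by = 50), y = seq(0, 200, by = 50))
  src <- as.matrix(g)
  dst <- src + cbind(3 * sin(src[, 2] / 60), 3 * cos(src[, 1] / 60))
  ps <- new("CorrespondencePointSet",
            pairs = data.frame(atlas_x = dst[, 1], atlas_y = dst[, 2],
                               image_x = src[, 1], image_y = src[, 2]))
  w <- fitWarp(ps)
  inside <- cbind(runif(200, 25, 175), runif(200, 25, 175))
  rt <- applyWarp(w, applyWarp(w, inside, "forward"), "inverse")
  expect_lte(max(sqrt(rowSums((rt - inside)^2))), 0.5)
  expect_identical(nrow(applyWarp(w, matrix(numeric(0), 0, 2))), 0L)
  energies <- vapply(c(0, 1, 10, 100), function(l)
    bendingEnergy(fitWarp(ps, lambda = l)), numeric(1))
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("regiLoop self-registers phantom plates and resumes idempotently", {
  ph <- smallPhantom()
  spec <- ph$truth$spec
  map <- endpointMap(ph)
  plate_aps <- vapply(plates(ph$atlas), apCoordinate, numeric(1))
  d <- withr::local_tempdir()
  warps <- regiLoop(ph$manifest, map, ph$atlas, plate_aps,
                    registrationsDir = d)
  expect_length(warps, 5)
  ## mean control residual on self-rendered phantom well under a pixel
  for (w in warps) {
    p <- pointPairs(w)
    res <- applyWarp(w, as.matrix(p[, c("image_x", "image_y")])) -
      as.matrix(p[, c("atlas_x", "atlas_y")])
    expect_lt(mean(sqrt(rowSums(res^2))), 1)
  }
  ## median displacement over the tissue mask is <= 1 px (near-identity)
  m <- labelMask(plates(ph$atlas)[[1]])
  px <- which(m > 0, arr.ind = TRUE)
  sel <- px[seq(1, nrow(px), by = 37), ]
  pts <- cbind(sel[, 2] - 1, sel[, 1] - 1)
  d1 <- applyWarp(warps[[1]], pts) - pts
  expect_lte(median(sqrt(rowSums(d1^2))), 1)
  ## resume: previously saved plates are skipped, results unchanged
  expect_message(
    warps2 <- regiLoop(ph$manifest, map, ph$atlas, plate_aps,
                       registrationsDir = d),
    "skipped")
  expect_equal(names(warps2), names(warps))
  expect_identical(pointPairs(warps2[[3]]), pointPairs(warps[[3]]))
  expect_error(regiLoop(ph$manifest, map, ph$atlas, 99), "outside")
})

test_that("warp files round-trip through their text format", {
  ph <- smallPhantom()
  map <- endpointMap(ph)
  d <- withr::local_tempdir()
  regiLoop(ph$manifest, map, ph$atlas, apCoordinate(plates(ph$atlas)[[2]]),
           registrationsDir = d)
  warps <- loadWarps(d)
  expect_length(warps, 1)
  w <- warps[[1]]
  set.seed(2)
  pr <- cbind(runif(20, 20, 100), runif(20, 20, 100))
  expect_equal(applyWarp(w, pr), applyWarp(w, pr))  # deterministic reload
  p <- pointPairs(w)
  res <- applyWarp(w, as.matrix(p[, c("image_x", "image_y")])) -
    as.matrix(p[, c("atlas_x", "atlas_y")])
  expect_lt(max(abs(res)), 1e-6)
})
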