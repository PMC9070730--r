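test_that("interpolateAP is exact at anchors and linear between them", {
  m <- alignmentMap(c(0, 100), c(2, 0), 101, 2.5)
  expect_equal(interpolateAP(m, 0), 2)
  expect_equal(interpolateAP(m, 50), 1)
  m3 <- alignmentMap(c(0, 40, 100), c(2, 1, 0), 101, 2.5,
                     source = c("endpoint", "choice_game", "endpoint"))
  ## bracketing segment (40,1)-(100,0) evaluated at 70
  expect_equal(interpolateAP(m3, 70), 0.5)
  expect_equal(interpolateAP(m3, 40), 1)
  expect_error(interpolateAP(m3, 101), "out of range")
  expect_error(interpolateAP(alignmentMap(c(0, 50), c(1, 0), 101, 2.5), 10),
               "endpoint")
})

test_that("interpolateAP is strictly decreasing for any valid map", {
  set.seed(21)
  for (rep in 1:25) {
    m <- randomAlignmentMap()
    ap <- interpolateAP(m, 0:(nPlanes(m) - 1))
    expect_true(all(diff(ap) < 0))
    expect_equal(ap[anchors(m)$z_index + 1], anchors(m)$ap_mm)
  }
})

test_that("choice game with a middle-always chooser ends at the initial middle in one cycle per level", {
  ph <- alignPhantom(seed = 5)
  m <- endpointMap(ph)
  cfg <- choiceGameConfig(referenceAps = phantomRefAps(ph))
  steps_seen <- integer()
  chooser <- function(left, middle, right, referenceAp, context) {
    steps_seen <<- c(steps_seen, context$step)
    "middle"
  }
  ref <- phantomRefAps(ph)[4]
  expected_middle <- which.min(abs(interpolateAP(m, 0:299) - ref)) - 1L
  res <- choiceGame(m, ref, chooser, cfg)
  expect_equal(res$anchor$z_index, expected_middle)
  expect_equal(res$nCalls, 4L)
  ## schedule presented in exactly the configured order
  expect_equal(steps_seen, c(200L, 100L, 30L, 10L))
  expect_equal(res$anchor$ap_mm, ref)
  expect_equal(res$anchor$source, "choice_game")
  expect_equal(nrow(anchors(res$map)), 3)
})

test_that("truthful chooser lands within the finest step of the true plane", {
  set.seed(31)
  for (rep in 1:20) {
    ph <- alignPhantom(seed = 1000 + rep, amplitude = runif(1, 0, 0.3))
    m <- endpointMap(ph)
    ch <- oracleChooser(ph$truth)
    target <- sample(15:284, 1)
    ref <- ph$truth$true_ap[target + 1]
    res <- choiceGame(m, ref, ch, choiceGameConfig())
    expect_lte(abs(res$anchor$z_index - target), 10)
    ## coarse-to-fine termination: moves are bounded by the walk to the
    ## target at the coarsest step plus refinement at each level change
    s <- c(200, 100, 30, 10)
    bound <- ceiling(300 / s[1]) + sum(ceiling(s[-length(s)] / s[-1])) +
      length(s)
    expect_lte(res$nCalls, bound)
  }
})

test_that("midpoint check leaves accepted maps unchanged and adds one anchor per rejection", {
  ph <- alignPhantom(seed = 9)
  m <- endpointMap(ph)
  cfg <- choiceGameConfig(referenceAps = phantomRefAps(ph))
  ch <- oracleChooser(ph$truth, acceptTolMm = 0.025)
  m <- alignReferencePlates(m, ch, cfg)
  accept_all <- list(choose = ch$choose, accept = function(...) TRUE)
  expect_identical(anchors(midpointCheck(m, accept_all, cfg)), anchors(m))
  ## reject exactly the first presented midpoint
  first <- TRUE
  one_reject <- list(choose = ch$choose,
                     accept = function(z, ap, ctx) {
                       if (first) { first <<- FALSE; FALSE } else TRUE
                     })
  m2 <- midpointCheck(m, one_reject, cfg)
  expect_equal(nrow(anchors(m2)), nrow(anchors(m)) + 1)
  expect_equal(sum(anchors(m2)$source == "midpoint_check"), 1)
})

test_that("midpoint check never worsens the alignment error on a nonlinear phantom", {
  for (seed in c(2, 14)) {
    ph <- alignPhantom(seed = seed, amplitude = 0.28)
    m <- endpointMap(ph)
    cfg <- choiceGameConfig(referenceAps = phantomRefAps(ph))
    ch <- oracleChooser(ph$truth, acceptTolMm = 0.01)
    m1 <- alignReferencePlates(m, ch, cfg)
    err1 <- max(abs(interpolateAP(m1, 0:299) - ph$truth$true_ap))
    m2 <- midpointCheck(m1, ch, cfg)
    err2 <- max(abs(interpolateAP(m2, 0:299) - ph$truth$true_ap))
    expect_lte(err2, err1 + 1e-12)
  }
})

test_that("morph profile implements the normalized planes-per-mm ratio", {
  ## equally spaced in both z and AP: all ratios 1
  m <- alignmentMap(c(0, 100, 200, 300), c(3, 2, 1, 0), 301, 2.5)
  expect_equal(intervals(morphProfile(m))$morph_ratio, rep(1, 3))
  ## two intervals of equal |dAP| with dz 100 and 300 planes
  m2 <- alignmentMap(c(0, 100, 400), c(2, 1, 0), 401, 2.5)
  expect_equal(intervals(morphProfile(m2))$morph_ratio, c(0.5, 1.5))
  ## single interval self-normalizes
  m1 <- alignmentMap(c(0, 57), c(1.3, -0.2), 58, 2.5)
  expect_equal(intervals(morphProfile(m1))$morph_ratio, 1)
})

test_that("morph ratios have |dAP|-weighted mean exactly 1", {
  set.seed(8)
  for (rep in 1:50) {
    m <- randomAlignmentMap()
    iv <- intervals(morphProfile(m))
    w <- abs(iv$ap_end_mm - iv$ap_start_mm)
    expect_equal(sum(iv$morph_ratio * w) / sum(w), 1, tolerance = 1e-12)
  }
})

test_that("linear prediction error is zero for endpoint-only maps and analytic for quadratic morphs", {
  m <- alignmentMap(c(0, 100), c(2, 0), 101, 2.5)
  expect_equal(linearPredictionError(m)$error_um, rep(0, 101))
  ## quadratic morph ap(z) = 2 - z/100 * (1 + z/100) evaluated at anchors
  zs <- c(0, 20, 45, 70, 100)
  quad <- function(z) 2 - (z / 100) * (1 + z / 100)
  mq <- alignmentMap(zs, quad(zs), 101, 2.5)
  tab <- linearPredictionError(mq)
  lin <- function(z) 2 + (quad(100) - 2) * z / 100
  at_anchor <- tab[tab$is_anchor, ]
  expect_equal(at_anchor$error_um, (quad(zs) - lin(zs)) * 1000,
               tolerance = 1e-9)
  ## an anchor more posterior than its linear prediction: negative error
  mneg <- alignmentMap(c(0, 50, 100), c(2, 0.8, 0), 101, 2.5)
  expect_equal(linearPredictionError(mneg)$error_um[51], -200)
})
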