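## Identity warp over a plate-sized domain.
identityWarp <- function(extent = 120) {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  src <- cbind(extent / 2 + extent / 3 * cos(th),
               extent / 2 + extent / 3 * sin(th))
  fitWarp(new("CorrespondencePointSet",
              pairs = data.frame(atlas_x = src[, 1], atlas_y = src[, 2],
                                 image_x = src[, 1], image_y = src[, 2])))
}

translationWarp <- function(dx, dy, extent = 120) {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  src <- cbind(extent / 2 + extent / 3 * cos(th),
               extent / 2 + extent / 3 * sin(th))
  fitWarp(new("CorrespondencePointSet",
              pairs = data.frame(atlas_x = src[, 1] + dx, atlas_y = src[, 2] + dy,
                                 image_x = src[, 1], image_y = src[, 2])))
}

simpleCells <- function(x_um, y_um, z) {
  data.frame(x_um = x_um, y_um = y_um, z_index = as.integer(z),
             peak_intensity = 1, n_merged = 1L)
}

test_that("forward warp fills AP from the map and transforms coordinates", {
  map <- alignmentMap(c(0, 100), c(0.5, -0.5), 101, 2.5)
  cells <- simpleCells(c(100, 250), c(150, 300), c(25, 75))
  w <- list("+0.2500" = identityWarp(), "-0.2500" = identityWarp())
  out <- forwardWarpCells(cells, w, map, pixelSizeUm = 5)
  expect_equal(out$ap_mm, interpolateAP(map, c(25, 75)))
  ## identity warp: atlas coords equal unit-converted image coords
  expect_equal(out$atlas_x, cells$x_um / 5, tolerance = 1e-9)
  expect_equal(out$atlas_y, cells$y_um / 5, tolerance = 1e-9)
  expect_true(all(out$mapped))
  ## a single translated plate shifts every cell by the translation
  wtr <- list("+0.0000" = translationWarp(10, -5))
  out2 <- forwardWarpCells(cells, wtr, map, pixelSizeUm = 5)
  expect_equal(out2$atlas_x, cells$x_um / 5 + 10, tolerance = 1e-9)
  expect_equal(out2$atlas_y, cells$y_um / 5 - 5, tolerance = 1e-9)
  expect_error(forwardWarpCells(cells, list(), map, 5), "no registered")
})

test_that("nearest-plate choice breaks AP ties toward the anterior plate", {
  ## published default plates at -0.42 and -0.93; a cell exactly midway
  map <- alignmentMap(c(0, 100), c(0, -1.35), 101, 2.5)
  w <- list("-0.4200" = identityWarp(), "-0.9300" = identityWarp())
  midway_z <- 50L  # AP = -0.675, equidistant from both plates
  cells <- simpleCells(50, 50, midway_z)
  out <- forwardWarpCells(cells, w, map, 5)
  expect_equal(out$plate_ap, -0.42)
  ## AP cutoff: default half the largest plate gap
  far <- forwardWarpCells(simpleCells(50, 50, 0), w, map, 5)
  expect_false(far$mapped)  # AP 0 is 0.42 from the nearest plate > 0.255
})

test_that("assignRegions reads the label mask and conserves cells", {
  atlas <- makeMiniAtlas(shape = c(128L, 128L), apRange = c(0.5, -0.5))
  m <- labelMask(plates(atlas)[[1]])
  map <- alignmentMap(c(0, 100), c(0.5, -0.5), 101, 2.5)
  w <- list("+0.0000" = identityWarp())
  ## pick one pixel per region id
  picks <- lapply(c(1L, 4L, 7L), function(id) {
    px <- which(m == id, arr.ind = TRUE)
    px[ceiling(nrow(px) / 2), ]
  })
  cells <- simpleCells(vapply(picks, function(p) (p[2] - 1) * 5, numeric(1)),
                       vapply(picks, function(p) (p[1] - 1) * 5, numeric(1)),
                       c(40, 50, 60))
  out <- assignRegions(forwardWarpCells(cells, w, map, 5), atlas)
  expect_equal(out$region_id, c(1L, 4L, 7L))
  ## a cell outside the tissue outline is unassigned, not dropped
  bg <- which(m == 0L, arr.ind = TRUE)[1, ]
  out2 <- assignRegions(forwardWarpCells(
    simpleCells((bg[2] - 1) * 5, (bg[1] - 1) * 5, 50), w, map, 5), atlas)
  expect_equal(out2$region_id, 0L)
  expect_equal(nrow(out2), 1)
  expect_error(assignRegions(simpleCells(1, 1, 1), atlas), "warped")
})

test_that("getTable satisfies the hierarchical count invariants", {
  atlas <- makeMiniAtlas(shape = c(64L, 64L))
  ont <- ontology(atlas)
  ## no cells: a table of zeros
  none <- data.frame(region_id = integer(0))
  t0 <- getTable(none, ont)
  expect_true(all(t0$direct_count == 0) && all(t0$rolled_count == 0))
  ## 3 cells in PL, 2 in IL; common parent CTX rolls to 5
  cells <- data.frame(region_id = c(4L, 4L, 4L, 5L, 5L))
  tab <- getTable(cells, ont)
  expect_equal(tab$rolled_count[tab$acronym == "CTX"], 5)
  expect_equal(tab$percent[tab$acronym == "PL"], 60)
  expect_equal(tab$percent[tab$acronym == "IL"], 40)
  expect_equal(tab$rolled_count[tab$acronym == "BR"], 5)
  expect_equal(tab$percent[tab$acronym == "BR"], 100, tolerance = 1e-9)
  ## rolled = direct + sum of children's rolled, for every node
  for (i in seq_len(nrow(ont))) {
    kid_acr <- ont$acronym[!is.na(ont$parent_id) &
                           ont$parent_id == ont$region_id[i]]
    expect_equal(tab$rolled_count[tab$acronym == ont$acronym[i]],
                 tab$direct_count[tab$acronym == ont$acronym[i]] +
                   sum(tab$rolled_count[tab$acronym %in% kid_acr]))
  }
  ## sorted by rolled count descending
  expect_true(all(diff(tab$rolled_count) <= 0))
  ## all cells unassigned: root rolls to zero, unassigned row holds all
  tu <- getTable(data.frame(region_id = c(0L, 0L, 0L)), ont)
  expect_equal(tu$rolled_count[tu$acronym == "unassigned"], 3)
  expect_equal(tu$rolled_count[tu$acronym == "BR"], 0)
  ## conservation: direct counts (incl. unassigned) sum to cells in
  mix <- data.frame(region_id = c(4L, 6L, 0L, 7L, 7L))
  tm <- getTable(mix, ont)
  expect_equal(sum(tm$direct_count), 5)
})

test_that("getRois honors the ontology hierarchy", {
  atlas <- makeMiniAtlas(shape = c(64L, 64L))
  ont <- ontology(atlas)
  cells <- data.frame(region_id = c(4L, 4L, 5L, 6L, 7L, 0L, 2L))
  ## root collects every assigned cell
  expect_equal(nrow(getRois(cells, ont, "BR")), 6)
  expect_equal(nrow(getRois(cells, ont, "PL")), 2)
  a <- getRois(cells, ont, "CTX")   # 2, 4, 4, 5
  expect_equal(nrow(a), 4)
  ## disjoint ROIs add; descendant-closed extraction is idempotent
  b <- getRois(cells, ont, "SUB")
  expect_equal(nrow(a) + nrow(b), nrow(getRois(cells, ont, c("CTX", "SUB"))))
  expect_identical(getRois(a, ont, "CTX"), a)
  expect_error(getRois(cells, ont, "PLx"), "unknown region")
})

test_that("sunburst hierarchy sums to the rolled counts at every node", {
  atlas <- makeMiniAtlas(shape = c(64L, 64L))
  ont <- ontology(atlas)
  cells <- data.frame(region_id = sample(c(1:7, 0L), 60, replace = TRUE,
                                         prob = c(1, 1, 1, 3, 3, 2, 2, 1)))
  tab <- getTable(cells, ont)
  doc <- sunburstData(tab, ont)
  subtreeSum <- function(node) {
    node$value + sum(vapply(node$children %||% list(), subtreeSum, numeric(1)))
  }
  checkNode <- function(node) {
    expect_equal(subtreeSum(node),
                 tab$rolled_count[tab$acronym == node$acronym])
    for (k in node$children %||% list()) checkNode(k)
  }
  checkNode(doc)
  ## single-region table: one positive-value child chain under the root
  one <- getTable(data.frame(region_id = c(6L, 6L)), ont)
  d1 <- sunburstData(one, ont)
  expect_equal(subtreeSum(d1), 2)
  ## empty table: all values zero
  d0 <- sunburstData(getTable(data.frame(region_id = integer(0)), ont), ont)
  expect_equal(subtreeSum(d0), 0)
  ## JSON export round-trips structurally
  f <- withr::local_tempfile(fileext = ".json")
  sunburstData(tab, ont, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$acronym, "BR")
  expect_length(j$children, 2)
})
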