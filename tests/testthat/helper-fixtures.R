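## Shared fixtures and independent oracles used across test files.

## Small rendered phantom, cached per session (rendering is the slow part).
smallPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantomSpec(nPlanes = 60, planeShape = c(128, 128),
                          nCells = 5, morphAmplitudeMm = 0.05, seed = 42)
      cache <<- makePhantom(spec, dir = file.path(tempdir(), "phantom-small"))
    }
    cache
  }
})

## Alignment-only phantom truth (no images, no cells needed) at full
## default stack scale.
alignPhantom <- function(seed = 1, amplitude = 0.2, nCells = 0) {
  makePhantom(phantomSpec(morphAmplitudeMm = amplitude, seed = seed,
                          nCells = nCells),
              render = FALSE)
}

## Endpoint-only map for a phantom.
endpointMap <- function(ph) {
  spec <- ph$truth$spec
  alignmentMap(c(0L, spec@nPlanes - 1L), c(spec@apStartMm, spec@apEndMm),
               spec@nPlanes, spec@zStepUm)
}

## Seven equally spaced interior reference APs for a phantom stack.
phantomRefAps <- function(ph) {
  spec <- ph$truth$spec
  seq(spec@apStartMm, spec@apEndMm, length.out = 9)[2:8]
}

## Independent brute-force oracle for duplicate cleanup: all-pairs
## adjacency + breadth-first connected components.
bruteCleanOracle <- function(dets, p, zStepUm) {
  n <- nrow(dets)
  if (!n) return(list(components = list(), cells = dets[0, ]))
  xy2 <- outer(dets$x_um, dets$x_um, "-")^2 + outer(dets$y_um, dets$y_um, "-")^2
  dz <- abs(outer(dets$z_index, dets$z_index, "-")) * zStepUm
  adj <- xy2 <= p@xyThreshUm^2 & dz <= p@zThreshUm
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comps <- split(seq_len(n), comp)
  rows <- vapply(comps, function(m)
    m[order(-dets$peak_intensity[m], dets$z_index[m])][1], integer(1))
  cells <- data.frame(x_um = dets$x_um[rows], y_um = dets$y_um[rows],
                      z_index = dets$z_index[rows],
                      peak_intensity = dets$peak_intensity[rows],
                      n_merged = lengths(comps))
  cells <- cells[order(cells$z_index, cells$x_um, cells$y_um), ]
  rownames(cells) <- NULL
  list(components = comps, cells = cells)
}

## Canonical signature of a partition into components (membership sets,
## order-independent) for equivalence checks.
componentSignature <- function(comps) {
  sig <- vapply(comps, function(m) paste(sort(m), collapse = "-"), character(1))
  sort(unname(sig))
}

## Random detection table.
randomDetections <- function(n, extent_um = 400, z_max = 40) {
  data.frame(x_um = runif(n, 0, extent_um), y_um = runif(n, 0, extent_um),
             z_index = sample.int(z_max, n, replace = TRUE) - 1L,
             peak_intensity = runif(n), area_um2 = runif(n, 100, 500))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Unwrap a cyclic angle sequence to a continuous one.
unwrapAngles <- function(a) cumsum(c(a[1], ((diff(a) + pi) %% (2 * pi)) - pi))

## Random valid alignment map (strictly decreasing APs, endpoints
## anchored).
randomAlignmentMap <- function(nPlanes = 200) {
  k <- sample(2:8, 1)
  z <- sort(sample(1:(nPlanes - 2), k - 2))
  z <- c(0L, z, nPlanes - 1L)
  ap <- sort(runif(length(z), -4, 3), decreasing = TRUE)
  while (any(diff(ap) == 0)) ap <- sort(runif(length(z), -4, 3), decreasing = TRUE)
  alignmentMap(z, ap, nPlanes, 2.5)
}
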