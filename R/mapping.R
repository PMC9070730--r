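## Forward warp of cleaned cells into atlas space, region assignment,
## hierarchical counting, ROI extraction and sunburst export.

#' Warp cells into atlas plate coordinates
#'
#' Each cell receives its AP coordinate from the alignment map
#' (interpolated at its plane), and its in-plane position is pushed
#' through the forward warp of the registered plate nearest in AP
#' (ties break toward the more anterior plate). Cells whose nearest
#' registered plate is farther away than \code{apCutoffMm} are flagged
#' unmapped rather than assigned to a distant plate.
#'
#' @param cells cell table from [cleanDuplicates()] (\code{x_um},
#'   \code{y_um}, \code{z_index}, ...).
#' @param warps named list of [Warp-class] keyed by formatted plate AP,
#'   as returned by [regiLoop()] / [loadWarps()].
#' @param map an [AlignmentMap-class].
#' @param pixelSizeUm image pixel size (um) used to convert the cell
#'   centroids into the pixel coordinates the warps were fitted in.
#' @param apCutoffMm maximum |cell AP - plate AP| for mapping; default
#'   half the largest gap between consecutive registered plates (or Inf
#'   with a single plate).
#' @return \code{cells} with added columns \code{ap_mm},
#'   \code{atlas_x}, \code{atlas_y} (plate pixels), \code{plate_ap} and
#'   \code{mapped}.
#' @export
forwardWarpCells <- function(cells, warps, map, pixelSizeUm,
                             apCutoffMm = NULL) {
  if (!length(warps)) stop("no registered plate warps supplied")
  plate_aps <- as.numeric(names(warps))
  ord <- order(-plate_aps)  # anterior first so ties pick anterior
  plate_aps <- plate_aps[ord]
  warps <- warps[ord]
  if (is.null(apCutoffMm))
    apCutoffMm <- if (length(plate_aps) > 1)
      max(abs(diff(plate_aps))) / 2 else Inf
  cells$ap_mm <- if (nrow(cells)) interpolateAP(map, cells$z_index) else numeric(0)
  cells$atlas_x <- cells$atlas_y <- rep(NA_real_, nrow(cells))
  cells$plate_ap <- rep(NA_real_, nrow(cells))
  cells$mapped <- rep(FALSE, nrow(cells))
  if (!nrow(cells)) return(cells)
  ## first near-minimum: the more anterior plate wins floating-point ties
  near <- vapply(cells$ap_mm, function(ap) {
    d <- abs(plate_aps - ap)
    which(d <= min(d) + 1e-9)[1]
  }, integer(1))
  cells$plate_ap <- plate_aps[near]
  cells$mapped <- abs(cells$plate_ap - cells$ap_mm) <= apCutoffMm
  for (i in seq_along(plate_aps)) {
    sel <- which(cells$mapped & near == i)
    if (!length(sel)) next
    px <- cbind(cells$x_um[sel], cells$y_um[sel]) / pixelSizeUm
    out <- applyWarp(warps[[i]], px, "forward")
    cells$atlas_x[sel] <- out[, 1]
    cells$atlas_y[sel] <- out[, 2]
  }
  cells
}

#' Assign warped cells to atlas regions
#'
#' Looks up each mapped cell's nearest label-mask pixel on its plate.
#' Cells landing outside the mask bounds or on background (label 0),
#' and cells flagged unmapped, are reported under the synthetic
#' \code{unassigned} region (id 0) rather than dropped, so cell totals
#' are conserved.
#'
#' @param cells output of [forwardWarpCells()].
#' @param atlas an [AtlasBundle-class].
#' @return \code{cells} with an integer \code{region_id} column.
#' @export
assignRegions <- function(cells, atlas) {
  if (is.null(cells$atlas_x)) stop("cells must be forward-warped first")
  cells$region_id <- rep(0L, nrow(cells))
  if (!nrow(cells)) return(cells)
  for (ap in unique(cells$plate_ap[cells$mapped])) {
    plate <- nearestPlate(atlas, ap)
    m <- plate@labelMask
    sel <- which(cells$mapped & cells$plate_ap == ap)
    r <- round(cells$atlas_y[sel]) + 1L
    c_ <- round(cells$atlas_x[sel]) + 1L
    inside <- r >= 1 & r <= nrow(m) & c_ >= 1 & c_ <= ncol(m)
    ids <- integer(length(sel))
    ids[inside] <- m[cbind(r[inside], c_[inside])]
    cells$region_id[sel] <- ids
  }
  cells
}

.rolledCounts <- function(direct, ont) {
  ## direct: named (by region_id) counts for every ontology row
  rolled <- direct
  ids <- ont$region_id
  kids <- split(ids, factor(ont$parent_id, levels = ids))
  roll <- function(id) {
    total <- direct[[as.character(id)]]
    for (k in kids[[as.character(id)]]) total <- total + roll(k)
    rolled[[as.character(id)]] <<- total
    total
  }
  roll(.rootId(ont))
  rolled
}

#' Hierarchical region count table
#'
#' Tabulates assigned cells per region and rolls counts up the ontology
#' (each region's rolled count is its direct count plus the rolled
#' counts of its children, so the root's rolled count equals the total
#' of assigned cells). Percentages use all cells -- including any in
#' the synthetic \code{unassigned} row -- as the denominator, so the
#' table is conservation-checkable; users preferring assigned-only
#' percentages can renormalize from the counts.
#'
#' @param cells output of [assignRegions()].
#' @param ontology ontology data.frame or [AtlasBundle-class].
#' @return data.frame sorted by rolled count (descending) with columns
#'   \code{acronym}, \code{name}, \code{direct_count},
#'   \code{rolled_count}, \code{percent}; one row per ontology region
#'   plus an \code{unassigned} row.
#' @export
getTable <- function(cells, ontology) {
  if (is(ontology, "AtlasBundle")) ontology <- ontology@ontology
  ont <- ontology
  if (is.null(cells$region_id)) stop("cells must have region assignments")
  ids <- as.character(ont$region_id)
  direct <- stats::setNames(as.list(integer(length(ids))), ids)
  tab <- table(cells$region_id)
  for (nm in names(tab)) if (nm %in% ids) direct[[nm]] <- as.integer(tab[[nm]])
  n_unassigned <- sum(cells$region_id == 0L |
                      !(cells$region_id %in% ont$region_id))
  rolled <- .rolledCounts(direct, ont)
  total <- nrow(cells)
  denom <- if (total) total else 1L
  out <- data.frame(
    acronym = ont$acronym, name = ont$name,
    direct_count = unlist(direct[ids], use.names = FALSE),
    rolled_count = unlist(rolled[ids], use.names = FALSE))
  out <- rbind(out, data.frame(acronym = "unassigned",
                               name = "outside atlas / unmapped",
                               direct_count = n_unassigned,
                               rolled_count = n_unassigned))
  out$percent <- out$rolled_count / denom * 100
  out <- out[order(-out$rolled_count, out$acronym), ]
  rownames(out) <- NULL
  out
}

#' Extract cells belonging to regions of interest
#'
#' Keeps cells whose region lies in the union of the named regions'
#' descendant sets, so asking for a parent structure collects all of
#' its subdivisions.
#'
#' @param cells output of [assignRegions()].
#' @param ontology ontology data.frame or [AtlasBundle-class].
#' @param acronyms character vector of region acronyms.
#' @return the matching subset of \code{cells}.
#' @export
getRois <- function(cells, ontology, acronyms) {
  if (is(ontology, "AtlasBundle")) ontology <- ontology@ontology
  ids <- unique(unlist(lapply(acronyms, function(a) descendants(ontology, a))))
  cells[cells$region_id %in% ids, , drop = FALSE]
}

#' Nested hierarchy for sunburst plots
#'
#' Converts a region count table into the d3-style nested document
#' (name / acronym / color / value / children) used by sunburst
#' visualizations: every node's \code{value} is its direct count, so
#' the sum over any subtree equals that node's rolled count and arc
#' lengths are proportional to total cell counts.
#'
#' @param table output of [getTable()].
#' @param ontology ontology data.frame or [AtlasBundle-class].
#' @param path optional file; when given the hierarchy is written there
#'   as JSON.
#' @return the nested list (invisibly when \code{path} is given).
#' @export
sunburstData <- function(table, ontology, path = NULL) {
  if (is(ontology, "AtlasBundle")) ontology <- ontology@ontology
  ont <- ontology
  direct <- stats::setNames(table$direct_count, table$acronym)
  build <- function(id) {
    row <- ont[ont$region_id == id, ]
    kids <- ont$region_id[!is.na(ont$parent_id) & ont$parent_id == id]
    node <- list(name = row$name, acronym = row$acronym,
                 color = row$color_hex,
                 value = as.integer(direct[[row$acronym]]))
    if (length(kids)) node$children <- lapply(kids, build)
    node
  }
  doc <- build(.rootId(ont))
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
    return(invisible(doc))
  }
  doc
}
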