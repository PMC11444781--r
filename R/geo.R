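#' Read a polygon region layer from GeoJSON
#'
#' Reads a FeatureCollection of `Polygon` / `MultiPolygon` features carrying
#' a population and an event count per region (e.g. administrative areas
#' with incidence counts).  Coordinates are taken as planar: the layer must
#' already be in a projected (or locally near-planar) coordinate system, as
#' areas are computed with the shoelace formula.
#'
#' Rings with fewer than three distinct vertices after dropping repeated
#' points are rejected with an error naming the region.
#'
#' @param path path to a GeoJSON file.
#' @param population,count names of the feature properties holding the
#'   region population and event count.
#' @param id optional property name for region identifiers; defaults to the
#'   feature index.
#' @return An object of class `"region_layer"`: a tibble with columns `id`,
#'   `population`, `count`, `area` and a list-column `geometry` (each
#'   element a list of polygon parts; each part a list of rings, first ring
#'   the outer boundary, the rest holes; each ring a 2-column coordinate
#'   matrix).  The layer bounding box is stored as attribute `bbox`
#'   (`c(xmin, ymin, xmax, ymax)`).
#' @examples
#' # a small synthetic layer shipped with the package
#' f <- system.file("extdata", "synthetic_regions.geojson", package = "sirscape")
#' layer <- read_region_layer(f)
#' score_region_layer(layer, n = 20)
#' @export
read_region_layer <- function(path, population = "population", count = "count",
                              id = NULL) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  feats <- gj$features
  rows <- purrr::imap(feats, function(f, k) {
    props <- f$properties
    rid <- if (!is.null(id)) as.character(props[[id]]) else as.character(k)
    pop <- props[[population]]
    cnt <- props[[count]]
    if (is.null(pop) || is.null(cnt)) {
      stop(sprintf("region %s lacks `%s`/`%s` properties", rid, population, count),
           call. = FALSE)
    }
    geom <- parse_geometry(f$geometry, rid)
    tibble::tibble(id = rid, population = as.numeric(pop),
                   count = as.numeric(cnt), geometry = list(geom))
  })
  layer <- dplyr::bind_rows(rows)
  if (any(layer$population <= 0)) stop("populations must be positive", call. = FALSE)
  new_region_layer(layer)
}

# normalize a GeoJSON geometry into a list of parts (part = list of rings)
parse_geometry <- function(geometry, rid) {
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # drop the closing vertex and repeated consecutive points (one repair pass)
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    dup <- c(FALSE, rowSums(abs(diff(m))) == 0)
    m <- m[!dup, , drop = FALSE]
    if (nrow(m) < 3) {
      stop(sprintf("region %s has a degenerate ring (fewer than 3 distinct vertices)", rid),
           call. = FALSE)
    }
    m
  }
  switch(geometry$type,
    Polygon = list(lapply(geometry$coordinates, ring_mat)),
    MultiPolygon = lapply(geometry$coordinates, function(poly) lapply(poly, ring_mat)),
    stop(sprintf("region %s: unsupported geometry type `%s`", rid, geometry$type),
         call. = FALSE)
  )
}

new_region_layer <- function(layer) {
  layer$area <- purrr::map_dbl(layer$geometry, region_area)
  if (any(layer$area <= 0)) stop("every region must have positive area", call. = FALSE)
  xs <- unlist(purrr::map(layer$geometry,
                          function(g) purrr::map(g, function(p) p[[1]][, 1])))
  ys <- unlist(purrr::map(layer$geometry,
                          function(g) purrr::map(g, function(p) p[[1]][, 2])))
  attr(layer, "bbox") <- c(xmin = min(xs), ymin = min(ys),
                           xmax = max(xs), ymax = max(ys))
  class(layer) <- c("region_layer", class(layer))
  layer
}

# shoelace area of one ring (absolute value)
ring_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# area of a region geometry: outer rings minus holes
region_area <- function(geom) {
  sum(purrr::map_dbl(geom, function(part) {
    a <- ring_area(part[[1]])
    if (length(part) > 1) a <- a - sum(purrr::map_dbl(part[-1], ring_area))
    a
  }))
}

# Sutherland-Hodgman clip of a ring against an axis-aligned rectangle,
# returning the clipped polygon area (0 if empty)
clip_ring_rect_area <- function(m, xmin, xmax, ymin, ymax) {
  pts <- m
  clip_edge <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- matrix(0, 2 * n, 2)
    k <- 0
    prev <- pts[n, ]
    prev_in <- inside(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) { k <- k + 1; out[k, ] <- intersect(prev, cur) }
        k <- k + 1; out[k, ] <- cur
      } else if (prev_in) {
        k <- k + 1; out[k, ] <- intersect(prev, cur)
      }
      prev <- cur; prev_in <- cur_in
    }
    out[seq_len(k), , drop = FALSE]
  }
  ix <- function(p, q, x) { t <- (x - p[1]) / (q[1] - p[1]); c(x, p[2] + t * (q[2] - p[2])) }
  iy <- function(p, q, y) { t <- (y - p[2]) / (q[2] - p[2]); c(p[1] + t * (q[1] - p[1]), y) }
  pts <- clip_edge(pts, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin))
  pts <- clip_edge(pts, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax))
  pts <- clip_edge(pts, function(p) p[2] >= ymin, function(p, q) iy(p, q, ymin))
  pts <- clip_edge(pts, function(p) p[2] <= ymax, function(p, q) iy(p, q, ymax))
  if (nrow(pts) < 3) return(0)
  ring_area(pts)
}

# overlap area of a region geometry with a rectangle
region_rect_area <- function(geom, xmin, xmax, ymin, ymax) {
  sum(purrr::map_dbl(geom, function(part) {
    a <- clip_ring_rect_area(part[[1]], xmin, xmax, ymin, ymax)
    if (length(part) > 1) {
      a <- a - sum(purrr::map_dbl(part[-1], clip_ring_rect_area,
                                  xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax))
    }
    a
  }))
}

#' Redistribute region counts onto a square grid
#'
#' Overlays an `n x n` grid on the layer bounding box and splits every
#' region's count and population across the cells in proportion to the
#' region-cell overlap area (uniform areal weighting).  Mass is conserved:
#' cell totals sum to the layer totals.  Cells receiving any positive
#' polygon overlap form the reachability mask; cells outside the mask (e.g.
#' ocean) carry no population and never count towards pattern statistics.
#'
#' @param layer a [read_region_layer()] / [make_region_layer()] object.
#' @param n grid side length (default 40).
#' @param bbox optional bounding box `c(xmin, ymin, xmax, ymax)` overriding
#'   the layer's.
#' @return An object of class `"geo_raster"`: list with `n`, `bbox`,
#'   matrices `count`, `population`, `incidence` (`count / population`, 0
#'   where no population) and logical `mask`.  Matrices are indexed
#'   `[ix, iy]` with `ix` increasing west-to-east and `iy` south-to-north.
#' @export
rasterize_layer <- function(layer, n = 40, bbox = NULL) {
  stopifnot(inherits(layer, "region_layer"))
  if (!(n >= 2)) stop("`n` must be at least 2", call. = FALSE)
  bbox <- bbox %||% attr(layer, "bbox")
  xs <- seq(bbox[["xmin"]], bbox[["xmax"]], length.out = n + 1)
  ys <- seq(bbox[["ymin"]], bbox[["ymax"]], length.out = n + 1)
  count <- matrix(0, n, n)
  pop <- matrix(0, n, n)
  mask <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(layer))) {
    geom <- layer$geometry[[r]]
    gx <- range(unlist(purrr::map(geom, function(p) purrr::map(p, function(m) m[, 1]))))
    gy <- range(unlist(purrr::map(geom, function(p) purrr::map(p, function(m) m[, 2]))))
    lo_x <- max(1L, findInterval(gx[1], xs, rightmost.closed = TRUE))
    hi_x <- min(n, findInterval(gx[2], xs, rightmost.closed = TRUE))
    lo_y <- max(1L, findInterval(gy[1], ys, rightmost.closed = TRUE))
    hi_y <- min(n, findInterval(gy[2], ys, rightmost.closed = TRUE))
    if (lo_x > hi_x || lo_y > hi_y) next
    total <- layer$area[r]
    for (ix in lo_x:hi_x) for (iy in lo_y:hi_y) {
      a <- region_rect_area(geom, xs[ix], xs[ix + 1], ys[iy], ys[iy + 1])
      if (a > 0) {
        w <- a / total
        count[ix, iy] <- count[ix, iy] + w * layer$count[r]
        pop[ix, iy] <- pop[ix, iy] + w * layer$population[r]
        mask[ix, iy] <- TRUE
      }
    }
  }
  incidence <- matrix(0, n, n)
  pos <- pop > 0
  incidence[pos] <- count[pos] / pop[pos]
  structure(list(n = n, bbox = bbox, count = count, population = pop,
                 incidence = incidence, mask = mask),
            class = "geo_raster")
}

#' @export
print.geo_raster <- function(x, ...) {
  cat(sprintf("<geo_raster> %d x %d grid, %d reachable cells, total count %.4g\n",
              x$n, x$n, sum(x$mask), sum(x$count)))
  invisible(x)
}

#' Binarize a geo raster relative to the reachable-cell mean
#'
#' A cell is occupied when its incidence fraction strictly exceeds the mean
#' incidence over *reachable* cells only, so unreachable space (outside the
#' study region) neither contributes to the mean nor can be occupied.
#'
#' @param raster a [rasterize_layer()] object.
#' @param rel_tol tie tolerance as in [binarize_above_mean()].
#' @return Logical occupancy matrix with the mask attached as attribute
#'   `mask` and `periodic = FALSE` (geographic grids are not tori).
#' @export
binarize_raster <- function(raster, rel_tol = 1e-9) {
  stopifnot(inherits(raster, "geo_raster"))
  if (!any(raster$mask)) stop("raster has no reachable cells", call. = FALSE)
  m <- mean(raster$incidence[raster$mask])
  occ <- raster$mask & (raster$incidence - m > rel_tol * abs(m))
  attr(occ, "mask") <- raster$mask
  attr(occ, "periodic") <- FALSE
  occ
}

#' Masked percolation order parameter of a geographic grid
#'
#' Computes the ACS of an occupancy grid with non-periodic 8-connectivity
#' (normalized by the full grid size `n^2`), together with its renormalized
#' value relative to the maximum ACS attainable on this mask — the value
#' obtained when every reachable cell is occupied ("fully percolated").
#' The renormalization discounts the unreachable space: a pattern occupying
#' the whole reachable area scores exactly 1.
#'
#' @param occ logical occupancy matrix, e.g. from [binarize_raster()].
#' @param mask logical reachability mask (defaults to the `mask` attribute
#'   of `occ`).
#' @return A one-row tibble with columns `acs`, `acs_full`, `normalized_acs`
#'   and `band` (band of the raw `acs`).  All `NA` when no cell is occupied.
#' @export
normalized_acs <- function(occ, mask = attr(occ, "mask")) {
  if (is.null(mask)) stop("`mask` is required", call. = FALSE)
  if (!identical(dim(occ), dim(mask))) stop("`occ` and `mask` shapes differ", call. = FALSE)
  if (any(occ & !mask)) stop("occupied cells must lie inside the mask", call. = FALSE)
  acs <- average_cluster_size(label_clusters(occ, periodic = FALSE))
  acs_full <- average_cluster_size(label_clusters(mask, periodic = FALSE))
  tibble::tibble(acs = acs, acs_full = acs_full,
                 normalized_acs = acs / acs_full,
                 band = classify_band(acs))
}

#' Superimpose two binarized grids
#'
#' Combines two occupancy grids over the same frame and mask into a single
#' pattern incorporating both datasets.  The default rule is the union
#' (occupied in either input); `"intersection"` keeps only cells occupied in
#' both.
#'
#' @param a,b logical occupancy matrices with identical shapes and masks.
#' @param rule `"union"` (default) or `"intersection"`.
#' @return Logical occupancy matrix with the shared mask and periodic
#'   attributes.
#' @export
superimpose <- function(a, b, rule = c("union", "intersection")) {
  rule <- match.arg(rule)
  if (!identical(dim(a), dim(b))) stop("grids have different shapes", call. = FALSE)
  ma <- attr(a, "mask"); mb <- attr(b, "mask")
  if (!is.null(ma) && !is.null(mb) && !identical(ma, mb)) {
    stop("grids have different masks", call. = FALSE)
  }
  out <- if (rule == "union") a | b else a & b
  attr(out, "mask") <- ma %||% mb
  attr(out, "periodic") <- FALSE
  out
}

#' One-call percolation score of a region layer
#'
#' Convenience wrapper running the full pipeline: rasterize, binarize over
#' the reachable mask, and compute the (normalized) percolation order
#' parameter.
#'
#' @inheritParams rasterize_layer
#' @return A one-row tibble: `n`, `n_reachable`, `n_occupied`, `acs`,
#'   `acs_full`, `normalized_acs`, `band`.
#' @export
score_region_layer <- function(layer, n = 40, bbox = NULL) {
  raster <- rasterize_layer(layer, n = n, bbox = bbox)
  occ <- binarize_raster(raster)
  res <- normalized_acs(occ)
  dplyr::bind_cols(tibble::tibble(n = n, n_reachable = sum(raster$mask),
                                  n_occupied = sum(occ)), res)
}
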