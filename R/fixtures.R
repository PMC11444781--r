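#' Synthetic lattice fields with known cluster structure
#'
#' Generates archetypal pattern fields whose percolation band membership is
#' provable by counting, so the classifier can be tested without running
#' simulations.  Kinds and their documented bands (on the default geometry,
#' periodic 8-connectivity):
#'
#' * `"spots"` — `n_blobs` isolated `blob x blob` squares on an even layout;
#'   band `"spots"` (ACS `= n_blobs * blob^4 / (L^2 * n_blobs * blob^2)`).
#' * `"stripes"` — full rows on/off with period `period`; band `"labyrinth"`
#'   for the default `L = 40`, `period = 4`; staggered magnetization 0.
#' * `"chequerboard"` — alternating cells; diagonal adjacency joins each
#'   colour class into one cluster of `L^2 / 2`, so ACS `= 0.5`, band
#'   `"connected"`, staggered magnetization 1 (even `L`).
#' * `"gaps"` — the complement of spots: a connected sea with isolated
#'   holes; band `"connected"`.
#' * `"uniform"` — constant field; band `"uniform"` (undefined ACS).
#' * `"random"` — i.i.d. `Uniform(0, 1)` values (band not documented).
#'
#' @param kind one of `"spots"`, `"stripes"`, `"chequerboard"`, `"gaps"`,
#'   `"uniform"`, `"random"`.
#' @param L lattice side (default 40).
#' @param n_blobs number of blobs/holes for `"spots"` / `"gaps"`.
#' @param blob blob/hole side length (must fit the layout).
#' @param period full stripe period in rows (on half, off half; even).
#' @param seed seed for `"random"`.
#' @return `L x L` numeric matrix.
#' @examples
#' percolation_summary(make_pattern("chequerboard", 40))
#' @export
make_pattern <- function(kind = c("spots", "stripes", "chequerboard", "gaps",
                                  "uniform", "random"),
                         L = 40, n_blobs = 8, blob = 2, period = 4, seed = 1) {
  kind <- match.arg(kind)
  if (L < 4) stop("`L` must be at least 4", call. = FALSE)
  field <- matrix(0, L, L)
  blobs <- function() {
    k <- ceiling(sqrt(n_blobs))
    spacing <- L %/% k
    if (spacing < blob + 2) {
      stop("blob layout does not fit: reduce `n_blobs` or `blob`", call. = FALSE)
    }
    pos <- expand.grid(bx = seq_len(k), by = seq_len(k))[seq_len(n_blobs), ]
    f <- matrix(0, L, L)
    for (q in seq_len(nrow(pos))) {
      r0 <- (pos$bx[q] - 1) * spacing + 1
      c0 <- (pos$by[q] - 1) * spacing + 1
      f[r0:(r0 + blob - 1), c0:(c0 + blob - 1)] <- 1
    }
    f
  }
  switch(kind,
    spots = blobs(),
    gaps = 1 - blobs(),
    stripes = {
      if (period < 2 || period %% 2 != 0) stop("`period` must be even and >= 2", call. = FALSE)
      on <- ((seq_len(L) - 1) %% period) < period / 2
      matrix(as.numeric(on), L, L)
    },
    chequerboard = outer(seq_len(L), seq_len(L), function(r, c) (r + c) %% 2),
    uniform = matrix(1, L, L),
    random = { set.seed(seed); matrix(runif(L * L), L, L) }
  )
}

#' Synthetic polygon region layer
#'
#' Builds a layer of rectangular regions that exactly partition a bounding
#' box (a recursive binary split: the largest rectangle is repeatedly cut at
#' a random position along its longer axis), then assigns each region a
#' population and a Poisson event count at `base_rate` events per person.
#' An optional hot-spot multiplies the rate for regions whose centroid
#' falls in a given sub-box, producing a known above-mean area for
#' round-trip tests of the rasterization pipeline.  Deterministic under
#' `seed`.
#'
#' This generator emulates the *schema* of administrative-area inputs
#' (polygons + population + count), not the statistical texture of any real
#' dataset.
#'
#' @param n_regions number of regions.
#' @param bbox bounding box `c(xmin, ymin, xmax, ymax)`.
#' @param pop_range range of region populations (uniform draw).
#' @param base_rate events per person.
#' @param hotspot optional list with `box = c(xmin, ymin, xmax, ymax)` and
#'   `factor` (rate multiplier inside the box).
#' @param seed RNG seed.
#' @return A `"region_layer"` tibble (see [read_region_layer()]).
#' @export
make_region_layer <- function(n_regions = 30, bbox = c(0, 0, 1, 1),
                              pop_range = c(1e3, 1e5), base_rate = 0.01,
                              hotspot = NULL, seed = 1) {
  if (n_regions < 1) stop("`n_regions` must be >= 1", call. = FALSE)
  set.seed(seed)
  rects <- list(c(bbox[1], bbox[2], bbox[3], bbox[4]))
  while (length(rects) < n_regions) {
    areas <- vapply(rects, function(r) (r[3] - r[1]) * (r[4] - r[2]), 0)
    k <- which.max(areas)
    r <- rects[[k]]
    f <- runif(1, 0.35, 0.65)
    if ((r[3] - r[1]) >= (r[4] - r[2])) {
      cut <- r[1] + f * (r[3] - r[1])
      halves <- list(c(r[1], r[2], cut, r[4]), c(cut, r[2], r[3], r[4]))
    } else {
      cut <- r[2] + f * (r[4] - r[2])
      halves <- list(c(r[1], r[2], r[3], cut), c(r[1], cut, r[3], r[4]))
    }
    rects <- c(rects[-k], halves)
  }
  pop <- runif(n_regions, pop_range[1], pop_range[2])
  rate <- rep(base_rate, n_regions)
  if (!is.null(hotspot)) {
    cx <- vapply(rects, function(r) (r[1] + r[3]) / 2, 0)
    cy <- vapply(rects, function(r) (r[2] + r[4]) / 2, 0)
    hb <- hotspot$box
    hot <- cx >= hb[1] & cx <= hb[3] & cy >= hb[2] & cy <= hb[4]
    rate[hot] <- rate[hot] * hotspot$factor
  }
  cnt <- rpois(n_regions, rate * pop)
  geom <- lapply(rects, function(r) {
    list(list(rbind(c(r[1], r[2]), c(r[3], r[2]), c(r[3], r[4]), c(r[1], r[4]))))
  })
  layer <- tibble::tibble(id = as.character(seq_len(n_regions)),
                          population = pop, count = as.numeric(cnt),
                          geometry = geom)
  new_region_layer(layer)
}

#' Write a region layer to GeoJSON
#'
#' Inverse of [read_region_layer()] for synthetic layers: writes a
#' FeatureCollection with `population` and `count` properties.
#'
#' @param layer a `"region_layer"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_layer <- function(layer, path) {
  stopifnot(inherits(layer, "region_layer"))
  feats <- purrr::pmap(list(layer$id, layer$population, layer$count, layer$geometry),
    function(id, pop, cnt, geom) {
      coords <- lapply(geom, function(part) {
        lapply(part, function(ring) {
          closed <- rbind(ring, ring[1, ])
          lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
        })
      })
      list(type = "Feature",
           properties = list(id = id, population = pop, count = cnt),
           geometry = if (length(coords) == 1) {
             list(type = "Polygon", coordinates = coords[[1]])
           } else {
             list(type = "MultiPolygon", coordinates = coords)
           })
    })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
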