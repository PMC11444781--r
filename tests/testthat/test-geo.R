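unit_square_layer <- function(counts, pops, squares) {
  geom <- lapply(squares, function(r) {
    list(list(rbind(c(r[1], r[2]), c(r[3], r[2]), c(r[3], r[4]), c(r[1], r[4]))))
  })
  sirscape:::new_region_layer(tibble::tibble(
    id = as.character(seq_along(counts)),
    population = pops, count = counts, geometry = geom
  ))
}

test_that("rasterization splits counts by overlap area and conserves mass", {
  # four unit squares on a 2x2 grid: each region lands exactly in one cell
  lay <- unit_square_layer(c(10, 30, 0, 0), c(100, 100, 50, 50),
                           list(c(0, 0, 1, 1), c(1, 0, 2, 1),
                                c(0, 1, 1, 2), c(1, 1, 2, 2)))
  ras <- rasterize_layer(lay, n = 2)
  expect_equal(ras$count, matrix(c(10, 30, 0, 0), 2, 2))
  expect_equal(ras$population, matrix(c(100, 100, 50, 50), 2, 2))
  expect_equal(ras$incidence[1, 1], 0.1)
  expect_equal(ras$incidence[2, 1], 0.3)
  expect_true(all(ras$mask))

  # a region split 50/50 between two cells gets half of each total
  lay2 <- unit_square_layer(c(8, 4), c(40, 20),
                            list(c(0, 0, 2, 1), c(0, 1, 2, 2)))
  ras2 <- rasterize_layer(lay2, n = 2)
  expect_equal(ras2$count, matrix(c(4, 4, 2, 2), 2, 2))
  expect_equal(ras2$population, matrix(c(20, 20, 10, 10), 2, 2))
})

test_that("redistributed totals match layer totals on random synthetic layers", {
  for (seed in 1:100) {
    lay <- make_region_layer(n_regions = 3 + seed %% 12, seed = seed,
                             base_rate = 0.02)
    ras <- rasterize_layer(lay, n = 8)
    expect_equal(sum(ras$count), sum(lay$count), tolerance = 1e-6)
    expect_equal(sum(ras$population), sum(lay$population), tolerance = 1e-6)
  }
})

test_that("rasterization is equivariant under rigid translation", {
  lay <- make_region_layer(n_regions = 12, seed = 42)
  shifted <- lay
  shifted$geometry <- lapply(lay$geometry, function(g) {
    lapply(g, function(part) lapply(part, function(ring) {
      ring + matrix(rep(c(13.5, -4.25), each = nrow(ring)), ncol = 2)
    }))
  })
  shifted <- sirscape:::new_region_layer(tibble::as_tibble(shifted[c(
    "id", "population", "count", "geometry")]))
  r1 <- rasterize_layer(lay, n = 10)
  r2 <- rasterize_layer(shifted, n = 10)
  expect_equal(r1$count, r2$count, tolerance = 1e-9)
  expect_equal(r1$population, r2$population, tolerance = 1e-9)
  expect_equal(r1$mask, r2$mask)
})

test_that("raster binarization uses the reachable-cell mean only", {
  # layer occupying the left half of a wider frame: right half unreachable
  lay <- unit_square_layer(c(6, 2), c(10, 10),
                           list(c(0, 0, 1, 2), c(1, 0, 2, 2)))
  ras <- rasterize_layer(lay, n = 4, bbox = c(xmin = 0, ymin = 0, xmax = 4, ymax = 2))
  expect_equal(sum(ras$mask), 8)   # only the covered left quarter
  occ <- binarize_raster(ras)
  # incidences 0.6 and 0.2 over reachable cells, mean 0.4: left column wins
  expect_true(all(occ[1, ]))
  expect_false(any(occ[2:4, ]))
  expect_equal(sum(occ), 4)
  expect_true(all(which(occ) %in% which(ras$mask)))

  # uniform incidence: nothing exceeds the mean
  lay_u <- unit_square_layer(c(5, 5), c(10, 10),
                             list(c(0, 0, 1, 2), c(1, 0, 2, 2)))
  expect_equal(sum(binarize_raster(rasterize_layer(lay_u, n = 2))), 0)
})

test_that("masked ACS renormalizes against the fully percolated grid", {
  # 5x5 grid, 20 reachable cells in one component, 5 occupied in one cluster
  mask <- matrix(TRUE, 5, 5)
  mask[, 5] <- FALSE
  occ <- matrix(FALSE, 5, 5)
  occ[1:5, 1] <- TRUE
  attr(occ, "mask") <- mask
  res <- normalized_acs(occ)
  expect_equal(res$acs, 0.2)        # 5^2 / (25 * 5)
  expect_equal(res$acs_full, 0.8)   # 20 / 25
  expect_equal(res$normalized_acs, 0.25)
  expect_equal(res$band, "labyrinth")

  # occupancy equal to the mask scores exactly 1
  res_full <- normalized_acs(mask, mask)
  expect_equal(res_full$normalized_acs, 1)

  # full-grid mask, fully occupied: raw ACS percolates at 1
  full <- matrix(TRUE, 5, 5)
  expect_equal(normalized_acs(full, full)$acs, 1)

  expect_error(normalized_acs(matrix(TRUE, 2, 2), matrix(FALSE, 2, 2)),
               "inside the mask")
})

test_that("superimposition unions patterns over a shared frame", {
  a <- matrix(FALSE, 3, 3); a[1, 1] <- TRUE
  b <- matrix(FALSE, 3, 3); b[3, 3] <- TRUE
  mask <- matrix(TRUE, 3, 3)
  attr(a, "mask") <- mask; attr(b, "mask") <- mask
  empty <- matrix(FALSE, 3, 3); attr(empty, "mask") <- mask

  expect_equal(sum(superimpose(a, b)), 2)
  expect_equal(as.vector(superimpose(a, empty)), as.vector(a))
  expect_equal(as.vector(superimpose(a, a)), as.vector(a))
  expect_equal(sum(superimpose(a, b, rule = "intersection")), 0)
  expect_error(superimpose(a, matrix(FALSE, 2, 2)), "shapes")
})

test_that("GeoJSON layers round-trip through write and read", {
  lay <- make_region_layer(n_regions = 9, seed = 31,
                           hotspot = list(box = c(0, 0, 0.5, 0.5), factor = 6))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_region_layer(lay, path)
  back <- read_region_layer(path, id = "id")
  expect_equal(back$population, lay$population, tolerance = 1e-12)
  expect_equal(back$count, lay$count)
  r1 <- rasterize_layer(lay, n = 10)
  r2 <- rasterize_layer(back, n = 10)
  expect_equal(r1$incidence, r2$incidence, tolerance = 1e-9)

  # degenerate ring is rejected with the offending region named
  bad <- paste0('{"type":"FeatureCollection","features":[{"type":"Feature",',
                '"properties":{"population":10,"count":1},',
                '"geometry":{"type":"Polygon","coordinates":[[[0,0],[1,1],[0,0]]]}}]}')
  f <- withr::local_tempfile(fileext = ".geojson")
  writeLines(bad, f)
  expect_error(read_region_layer(f), "degenerate ring")
})

test_that("the shipped synthetic example layer loads and scores", {
  f <- system.file("extdata", "synthetic_regions.geojson", package = "sirscape")
  expect_true(nzchar(f) && file.exists(f))
  sc <- score_region_layer(read_region_layer(f), n = 20)
  expect_equal(sc$band, "labyrinth")
  expect_equal(sc$n_reachable, 400L)
})

test_that("score_region_layer runs the whole pipeline", {
  lay <- make_region_layer(n_regions = 20, seed = 8,
                           hotspot = list(box = c(0.5, 0.5, 1, 1), factor = 10))
  sc <- score_region_layer(lay, n = 15)
  expect_true(sc$normalized_acs > 0 && sc$normalized_acs <= 1)
  expect_true(sc$band %in% c("spots", "labyrinth", "connected"))
})
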