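test_that("binarization is strict above the mean with ties unoccupied", {
  expect_false(any(binarize_above_mean(matrix(3.7, 5, 5))))

  f <- matrix(0, 4, 4); f[2, 3] <- 1
  occ <- binarize_above_mean(f)
  expect_equal(sum(occ), 1)
  expect_true(occ[2, 3])

  f2 <- matrix(rep(c(0, 2), each = 8), 4, 4)   # mean 1: the 2-cells win
  expect_equal(sum(binarize_above_mean(f2)), 8)

  # numerically uniform fields (round-off level spread) stay unoccupied
  set.seed(1)
  f3 <- matrix(1 + 1e-13 * runif(16), 4, 4)
  expect_false(any(binarize_above_mean(f3)))

  expect_error(binarize_above_mean(matrix(c(1, NA, 1, 1), 2)), "finite")
})

test_that("clusters join laterally and diagonally, wrapping only when periodic", {
  occ <- matrix(FALSE, 5, 5)
  occ[1, 1] <- TRUE; occ[2, 2] <- TRUE   # diagonal touch
  lab <- label_clusters(occ, periodic = FALSE)
  expect_equal(max(lab), 1)
  expect_equal(cluster_sizes(lab), 2L)

  # opposite edges connect on the torus, not on the plane
  occ2 <- matrix(FALSE, 5, 5)
  occ2[1, 3] <- TRUE; occ2[5, 3] <- TRUE
  expect_equal(max(label_clusters(occ2, periodic = TRUE)), 1)
  expect_equal(max(label_clusters(occ2, periodic = FALSE)), 2)

  expect_equal(max(label_clusters(matrix(FALSE, 4, 4))), 0)
  expect_length(cluster_sizes(label_clusters(matrix(FALSE, 4, 4))), 0)
})

test_that("ACS is the site-weighted mean normalized cluster size", {
  # fully occupied grid percolates: single cluster, ACS 1
  expect_equal(average_cluster_size(label_clusters(matrix(TRUE, 6, 6))), 1)

  # clusters {3, 1} on a 4x4 grid: (3*3/16 + ... ) / 4 = 0.15625
  occ <- matrix(FALSE, 4, 4)
  occ[c(1, 2, 3)] <- TRUE; occ[4, 4] <- TRUE
  lab <- label_clusters(occ, periodic = FALSE)
  expect_equal(average_cluster_size(lab), 0.15625)
  # cluster-weighted alternative: mean(3,1)/16
  expect_equal(average_cluster_size(lab, weighting = "cluster"), 0.125)

  expect_true(is.na(average_cluster_size(label_clusters(matrix(FALSE, 4, 4)))))
})

test_that("ACS agrees with an independent component oracle on random grids", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (k in 1:200) {
    occ <- random_occ(8, fill = runif(1, 0.1, 0.9))
    per <- k %% 2 == 0
    expect_equal(average_cluster_size(label_clusters(occ, periodic = per)),
                 oracle_acs(occ, periodic = per))
  }
})

test_that("ACS is invariant under torus translations and lattice symmetries", {
  set.seed(5)
  for (k in 1:20) {
    occ <- random_occ(8, fill = 0.4)
    ref <- average_cluster_size(label_clusters(occ, periodic = TRUE))
    sh <- occ[c(4:8, 1:3), c(7:8, 1:6)]
    expect_equal(average_cluster_size(label_clusters(sh, periodic = TRUE)), ref)
    for (tr in list(t(occ), occ[8:1, ], occ[, 8:1], t(occ)[8:1, ])) {
      expect_equal(average_cluster_size(label_clusters(tr, periodic = TRUE)), ref)
    }
  }
})

test_that("adding a cell that merges clusters never decreases the ACS", {
  set.seed(17)
  found <- 0
  while (found < 10) {
    occ <- random_occ(8, fill = 0.35)
    lab <- label_clusters(occ, periodic = FALSE)
    if (max(lab) < 2) next
    for (p in which(!occ)) {
      r <- (p - 1) %% 8 + 1; c <- (p - 1) %/% 8 + 1
      nb <- expand.grid(r = r + (-1:1), c = c + (-1:1))
      nb <- nb[nb$r >= 1 & nb$r <= 8 & nb$c >= 1 & nb$c <= 8, ]
      labs <- unique(lab[cbind(nb$r, nb$c)])
      labs <- labs[labs > 0]
      if (length(labs) >= 2) {
        before <- average_cluster_size(lab)
        occ2 <- occ; occ2[p] <- TRUE
        after <- average_cluster_size(label_clusters(occ2, periodic = FALSE))
        expect_gte(after, before)
        found <- found + 1
        break
      }
    }
  }
})

test_that("band thresholds are right-closed at 0.04 and 0.4", {
  expect_equal(classify_band(0.02), "spots")
  expect_equal(classify_band(0.04), "spots")
  expect_equal(classify_band(0.04 + 1e-12), "labyrinth")
  expect_equal(classify_band(0.2), "labyrinth")
  expect_equal(classify_band(0.4), "labyrinth")
  expect_equal(classify_band(0.4 + 1e-12), "connected")
  expect_equal(classify_band(1), "connected")
  expect_equal(classify_band(NA_real_), "uniform")
  expect_error(classify_band(0), "\\(0, 1\\]")
  expect_error(classify_band(1.2), "\\(0, 1\\]")
})

test_that("staggered magnetization separates chequerboard from aligned phases", {
  cheq <- outer(1:6, 1:6, function(r, c) (r + c) %% 2 == 1)
  expect_equal(staggered_magnetization(cheq), 1)
  expect_equal(staggered_magnetization(matrix(TRUE, 6, 6)), 0)
  stripes <- matrix(((row(matrix(0, 6, 6)) - 1) %% 4) < 2, 6, 6)  # full rows on/off
  expect_equal(staggered_magnetization(stripes), 0)
})

test_that("percolation_summary assembles the full pattern report", {
  ps <- percolation_summary(make_pattern("chequerboard", 20))
  expect_s3_class(ps, "percolation_summary")
  expect_equal(ps$acs, 0.5)
  expect_equal(ps$m_s, 1)
  expect_equal(ps$band, "connected")
  expect_equal(ps$n_clusters, 1)
  expect_equal(ps$lcs, 200L)
})
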