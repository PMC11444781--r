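#' Binarize a field relative to its mean
#'
#' A cell is occupied when its value strictly exceeds the field mean.  Ties
#' at the mean are unoccupied, so a constant field produces an empty
#' occupancy grid (and an undefined order parameter).  Because simulated
#' fields can homogenize to within floating-point round-off without becoming
#' exactly constant, a small relative tolerance is applied: a cell is
#' occupied only if its excess over the mean is larger than `rel_tol *
#' |mean|`.  At the default `1e-9` this is invisible for any genuinely
#' patterned field.
#'
#' @param field numeric matrix (all values finite).
#' @param rel_tol relative tolerance treating near-ties as ties.
#' @return Logical occupancy matrix of the same shape.
#' @export
binarize_above_mean <- function(field, rel_tol = 1e-9) {
  if (!is.matrix(field) || any(!is.finite(field))) {
    stop("`field` must be a finite numeric matrix", call. = FALSE)
  }
  m <- mean(field)
  field - m > rel_tol * abs(m)
}

#' Label connected clusters of occupied cells
#'
#' Connected components under 8-connectivity: two occupied cells belong to
#' the same cluster if they are adjacent laterally or diagonally.  With
#' `periodic = TRUE` adjacency wraps around the edges (torus), matching the
#' boundary conditions of the simulated lattice; geographic grids should use
#' `periodic = FALSE`.
#'
#' @param occ logical matrix of occupied cells.
#' @param periodic wrap adjacency at the edges?
#' @return Integer matrix of cluster labels (`0` for unoccupied cells),
#'   with `periodic` stored as an attribute.
#' @export
label_clusters <- function(occ, periodic = TRUE) {
  if (!is.matrix(occ) || !is.logical(occ)) {
    stop("`occ` must be a logical matrix", call. = FALSE)
  }
  nr <- nrow(occ); nc <- ncol(occ)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  dd <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  dd <- dd[!(dd[, 1] == 0 & dd[, 2] == 0), , drop = FALSE]
  for (start in which(occ)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      rr <- r + dd[, 1]; cc <- c + dd[, 2]
      if (periodic) {
        rr <- (rr - 1L) %% nr + 1L
        cc <- (cc - 1L) %% nc + 1L
        keep <- rep(TRUE, length(rr))
      } else {
        keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      }
      idx <- (cc[keep] - 1L) * nr + rr[keep]
      idx <- idx[occ[idx] & lab[idx] == 0L]
      if (length(idx)) {
        lab[idx] <- cur
        queue <- c(queue, idx)
      }
    }
  }
  attr(lab, "periodic") <- periodic
  lab
}

#' Sizes of labelled clusters
#'
#' @param labels integer label matrix from [label_clusters()].
#' @return Integer vector of cluster sizes (possibly empty).
#' @export
cluster_sizes <- function(labels) {
  v <- labels[labels > 0L]
  if (!length(v)) return(integer(0))
  tabulate(v)
}

#' Average cluster size (percolation order parameter)
#'
#' The order parameter is the mean normalized cluster size experienced by an
#' occupied site: each cluster of `r` sites counts with weight `r` (the
#' probability that a site belongs to it), its normalized size being
#' `r/L^2`.  Equivalently `ACS = sum(r^2) / (L^2 * sum(r))` over clusters.
#' The largest (possibly percolating) cluster is included — this sharpens
#' the transitions between pattern types.  With no occupied sites the value
#' is undefined and `NA` is returned.
#'
#' A cluster-weighted alternative (plain mean of `r/L^2` over clusters) is
#' available via `weighting = "cluster"` but is not the default.
#'
#' @param labels label matrix from [label_clusters()], or a logical matrix
#'   (labelled with its `periodic` attribute, default periodic).
#' @param weighting `"site"` (default) or `"cluster"`.
#' @return ACS in `(0, 1]`, or `NA` when undefined.
#' @examples
#' occ <- matrix(FALSE, 4, 4); occ[1:3, 1] <- TRUE; occ[4, 4] <- TRUE
#' average_cluster_size(label_clusters(occ, periodic = FALSE))  # 0.15625
#' @export
average_cluster_size <- function(labels, weighting = c("site", "cluster")) {
  weighting <- match.arg(weighting)
  if (is.logical(labels)) {
    labels <- label_clusters(labels, periodic = attr(labels, "periodic") %||% TRUE)
  }
  sizes <- cluster_sizes(labels)
  if (!length(sizes)) return(NA_real_)
  n2 <- length(labels)
  if (weighting == "site") {
    sum(sizes^2) / (n2 * sum(sizes))
  } else {
    mean(sizes) / n2
  }
}

#' Classify an ACS value into a pattern band
#'
#' Bands separate pattern types by order of percolation magnitude: an
#' undefined ACS is the uniform class; `(0, 0.04]` the spots band (isolated
#' clusters); `(0.04, 0.4]` the labyrinth band (maze-like regions); and
#' `(0.4, 1]` the connected band (gaps or chequerboard patterns; use
#' [staggered_magnetization()] to tell them apart).  Boundaries are
#' right-closed: `0.04` is spots, `0.4` is labyrinth.
#'
#' @param acs numeric ACS value(s) in `(0, 1]`, or `NA` for undefined.
#' @return Character vector of band labels: `"uniform"`, `"spots"`,
#'   `"labyrinth"`, `"connected"`.
#' @export
classify_band <- function(acs) {
  out <- rep(NA_character_, length(acs))
  out[is.na(acs)] <- "uniform"
  ok <- !is.na(acs)
  if (any(ok & (acs <= 0 | acs > 1))) {
    stop("defined ACS values must lie in (0, 1]", call. = FALSE)
  }
  out[ok & acs <= 0.04] <- "spots"
  out[ok & acs > 0.04 & acs <= 0.4] <- "labyrinth"
  out[ok & acs > 0.4] <- "connected"
  out
}

#' Staggered magnetization of an occupancy grid
#'
#' Maps occupancy to spins (+1 occupied, -1 empty) and measures the
#' chequerboard (anti-aligned) order:
#' `m_s = |sum (-1)^(row+col) * s| / n_cells`.  A perfect chequerboard
#' scores 1, a fully occupied or striped grid 0.  Within the connected band
#' this distinguishes chequerboard patterns (high `m_s`) from gaps patterns
#' (`m_s` near 0); `m_s > 0.5` is a reasonable chequerboard call.
#'
#' @param occ logical occupancy matrix.
#' @return `m_s` in `[0, 1]`.
#' @export
staggered_magnetization <- function(occ) {
  if (!is.matrix(occ) || !is.logical(occ)) {
    stop("`occ` must be a logical matrix", call. = FALSE)
  }
  s <- 2 * occ - 1
  parity <- outer(seq_len(nrow(occ)), seq_len(ncol(occ)), function(r, c) (-1)^(r + c))
  abs(sum(parity * s)) / length(occ)
}

#' Percolation summary of a lattice field
#'
#' Full pattern analysis of a real-valued field: binarize above the mean,
#' label clusters with 8-connectivity, and report the percolation order
#' parameter with its pattern band, the largest-cluster size, the cluster
#' count and the staggered magnetization.
#'
#' @param field numeric `L x L` matrix (e.g. [final_field()] of a run).
#' @param periodic wrap cluster adjacency at the edges?
#' @param rel_tol tie tolerance passed to [binarize_above_mean()].
#' @param weighting passed to [average_cluster_size()].
#' @return A one-row tibble of class `"percolation_summary"` with columns
#'   `n_occupied`, `n_clusters`, `lcs` (largest cluster, sites), `acs`,
#'   `m_s`, `band`.
#' @export
percolation_summary <- function(field, periodic = TRUE, rel_tol = 1e-9,
                                weighting = c("site", "cluster")) {
  weighting <- match.arg(weighting)
  occ <- binarize_above_mean(field, rel_tol = rel_tol)
  labels <- label_clusters(occ, periodic = periodic)
  sizes <- cluster_sizes(labels)
  acs <- average_cluster_size(labels, weighting = weighting)
  out <- tibble::tibble(
    n_occupied = sum(occ),
    n_clusters = length(sizes),
    lcs = if (length(sizes)) max(sizes) else 0L,
    acs = acs,
    m_s = staggered_magnetization(occ),
    band = classify_band(acs)
  )
  class(out) <- c("percolation_summary", class(out))
  out
}
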