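#' Default grid of risk-disposition values
#'
#' Evenly spaced values over the bounded risk-disposition range, by default
#' `-50, -45, ..., 45, 50` (step 5).  Together with the zero edges this
#' tiles each sign quadrant with an 11 x 11 sub-grid.
#'
#' @param from,to,by grid limits and spacing.
#' @return Numeric vector of grid values.
#' @export
alpha_grid <- function(from = -50, to = 50, by = 5) {
  seq(from, to, by = by)
}

#' Default logarithmic grid of susceptibility-acquisition values
#'
#' @return The default `zeta` grid `0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000`.
#' @export
zeta_grid <- function() c(0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000)

#' Phase diagram over the risk-disposition plane
#'
#' Runs the lattice simulation at every (`alpha_I`, `alpha_S`) grid point
#' for a fixed `zeta`, binarizes the final infection field, and records the
#' percolation summary.  With `n_runs > 1` the ACS is averaged over
#' independent random initial conditions; a point whose runs are all
#' undefined is classed `"uniform"`.
#'
#' Seeds follow a deterministic schedule derived from `base_seed` and the
#' grid indices, so any execution order (or a restart) reproduces the same
#' diagram.
#'
#' @param zeta susceptibility-acquisition value for the whole plane.
#' @param alpha_I,alpha_S grid values (defaults [alpha_grid()]).
#' @param config base [sim_config()]; its `alpha_I`, `alpha_S`, `zeta` and
#'   `seed` fields are overridden per grid point.
#' @param n_runs independent runs per grid point (default `config$n_runs`).
#' @param base_seed seed from which the per-point schedule is derived.
#' @return A tibble of class `"alpha_scan"` with one row per grid point:
#'   `alpha_I`, `alpha_S`, `zeta`, `quadrant`, `mean_acs` (NA when all runs
#'   undefined), `sd_acs`, `n_defined`, `band`, `mean_m_s`.
#' @export
scan_alpha_plane <- function(zeta, alpha_I = alpha_grid(), alpha_S = alpha_grid(),
                             config = sim_config(), n_runs = config$n_runs,
                             base_seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  grid <- tidyr_expand_grid(alpha_I, alpha_S)
  rows <- purrr::pmap(list(grid$alpha_I, grid$alpha_S, grid$ai_idx, grid$as_idx),
    function(aI, aS, ii, jj) {
      cfg <- config
      cfg$alpha_I <- aI; cfg$alpha_S <- aS; cfg$zeta <- zeta
      stats <- purrr::map(seq_len(n_runs), function(run) {
        cfg$seed <- combine_seed(base_seed, ii, jj, 1, run)
        sim <- run_simulation(cfg)
        percolation_summary(final_field(sim), periodic = TRUE)
      })
      acs <- purrr::map_dbl(stats, "acs")
      ms <- purrr::map_dbl(stats, "m_s")
      mean_acs <- if (all(is.na(acs))) NA_real_ else mean(acs, na.rm = TRUE)
      tibble::tibble(
        alpha_I = aI, alpha_S = aS, zeta = zeta,
        quadrant = quadrant_of(aI, aS),
        mean_acs = mean_acs,
        sd_acs = if (sum(!is.na(acs)) >= 2) sd(acs, na.rm = TRUE) else NA_real_,
        n_defined = sum(!is.na(acs)),
        band = classify_band(mean_acs),
        mean_m_s = mean(ms)
      )
    })
  out <- dplyr::bind_rows(rows)
  attr(out, "L") <- config$L
  attr(out, "n_runs") <- n_runs
  class(out) <- c("alpha_scan", class(out))
  out
}

# minimal expand.grid with stable index columns (alpha_I varies slowest)
tidyr_expand_grid <- function(alpha_I, alpha_S) {
  g <- expand.grid(as_idx = seq_along(alpha_S), ai_idx = seq_along(alpha_I))
  tibble::tibble(alpha_I = alpha_I[g$ai_idx], alpha_S = alpha_S[g$as_idx],
                 ai_idx = g$ai_idx, as_idx = g$as_idx)
}

#' Sweep the susceptibility-acquisition axis
#'
#' For a fixed risk-disposition pair, runs the simulation across a
#' (logarithmic) grid of `zeta` values and reports the mean and standard
#' deviation of the ACS over independent runs.  `zeta = 0` (the SIR
#' endpoint, where infection dies out and no pattern forms) is accepted as
#' a categorical endpoint; it is excluded from log-scale tipping-point
#' detection.
#'
#' @param alpha_I,alpha_S risk-disposition values.
#' @param zeta grid of `zeta` values (default [zeta_grid()]).
#' @param config base [sim_config()].
#' @param n_runs runs per `zeta` (default `config$n_runs`).
#' @param base_seed seed from which the per-run schedule is derived.
#' @return A tibble of class `"zeta_sweep"` with one row per `zeta`:
#'   `zeta`, `mean_acs`, `sd_acs`, `n_defined`, `n_runs`, `band`.
#' @export
sweep_zeta <- function(alpha_I, alpha_S, zeta = zeta_grid(),
                       config = sim_config(), n_runs = config$n_runs,
                       base_seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (any(zeta < 0)) stop("`zeta` values must be >= 0", call. = FALSE)
  rows <- purrr::imap(as.list(zeta), function(z, zi) {
    cfg <- config
    cfg$alpha_I <- alpha_I; cfg$alpha_S <- alpha_S; cfg$zeta <- z
    acs <- purrr::map_dbl(seq_len(n_runs), function(run) {
      run_acs(cfg, seed = combine_seed(base_seed, 1, 1, zi, run))
    })
    mean_acs <- if (all(is.na(acs))) NA_real_ else mean(acs, na.rm = TRUE)
    tibble::tibble(zeta = z, mean_acs = mean_acs,
                   sd_acs = if (sum(!is.na(acs)) >= 2) sd(acs, na.rm = TRUE) else NA_real_,
                   n_defined = sum(!is.na(acs)), n_runs = n_runs,
                   band = classify_band(mean_acs))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "L") <- config$L
  attr(out, "alpha_I") <- alpha_I
  attr(out, "alpha_S") <- alpha_S
  class(out) <- c("zeta_sweep", class(out))
  out
}

#' Detect the tipping point along the susceptibility-acquisition axis
#'
#' Locates the critical `zeta` as the largest log-log change of the order
#' parameter: the pair of adjacent grid points maximizing
#' `|delta log(ACS) / delta log(zeta)|`, reported as their geometric mean.
#' Undefined ACS values are replaced by a floor (default `1 / L^2`, the
#' smallest resolvable normalized cluster) so that pattern emergence out of
#' the undefined regime registers as a large change.  An exactly flat curve
#' has no critical point (`zeta_c = NA`).
#'
#' @param sweep a [sweep_zeta()] result (or any data frame with `zeta` and
#'   `mean_acs` columns); at least 3 rows with `zeta > 0`.
#' @param floor replacement for undefined ACS values.
#' @return An object of class `"critical_zeta"`: list with `zeta_c`,
#'   `bracket` (the two grid values), `max_slope`, and `slopes` (a tibble of
#'   all interval slopes).
#' @examples
#' sw <- tibble::tibble(zeta = c(0.1, 1, 3, 10), mean_acs = c(0.01, 0.01, 0.3, 0.3))
#' detect_critical_zeta(sw)$zeta_c  # sqrt(3)
#' @export
detect_critical_zeta <- function(sweep, floor = NULL) {
  if (!all(c("zeta", "mean_acs") %in% names(sweep))) {
    stop("`sweep` needs `zeta` and `mean_acs` columns", call. = FALSE)
  }
  df <- sweep[sweep$zeta > 0, , drop = FALSE]
  df <- df[order(df$zeta), , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 zeta points with zeta > 0", call. = FALSE)
  if (is.null(floor)) {
    L <- attr(sweep, "L") %||% 40
    floor <- 1 / L^2
  }
  acs <- df$mean_acs
  acs[is.na(acs)] <- floor
  slope <- abs(diff(log(acs)) / diff(log(df$zeta)))
  slopes <- tibble::tibble(zeta_lo = df$zeta[-nrow(df)], zeta_hi = df$zeta[-1],
                           slope = slope)
  if (max(slope) <= 1e-12) {
    res <- list(zeta_c = NA_real_, bracket = c(NA_real_, NA_real_),
                max_slope = 0, slopes = slopes)
  } else {
    k <- which.max(slope)
    res <- list(zeta_c = sqrt(df$zeta[k] * df$zeta[k + 1]),
                bracket = c(df$zeta[k], df$zeta[k + 1]),
                max_slope = slope[k], slopes = slopes)
  }
  structure(res, class = "critical_zeta")
}

#' @export
print.critical_zeta <- function(x, ...) {
  if (is.na(x$zeta_c)) {
    cat("<critical_zeta> no critical point (flat curve)\n")
  } else {
    cat(sprintf("<critical_zeta> zeta_c = %.4g (bracket %g..%g, |dlogACS/dlogzeta| = %.3g)\n",
                x$zeta_c, x$bracket[1], x$bracket[2], x$max_slope))
  }
  invisible(x)
}
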