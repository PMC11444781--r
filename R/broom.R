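#' Glance at a simulation result
#'
#' One-row summary of a finished run: compartment totals, the attack level
#' and the percolation statistics of the binarized final infection field.
#'
#' @param x a `"contagion_sim"` object.
#' @param periodic cluster adjacency wrap (default torus, matching the
#'   model's boundary conditions).
#' @param ... unused.
#' @return A one-row tibble: `mode`, `zeta`, `alpha_I`, `alpha_S`,
#'   `total_S`, `total_I`, `total_R`, `infected_fraction`, `acs`, `m_s`,
#'   `band`.
#' @export
glance.contagion_sim <- function(x, periodic = TRUE, ...) {
  ps <- percolation_summary(final_field(x), periodic = periodic)
  tibble::tibble(mode = x$mode, zeta = x$config$zeta,
                 alpha_I = x$config$alpha_I, alpha_S = x$config$alpha_S,
                 total_S = sum(x$state$S), total_I = sum(x$state$I),
                 total_R = sum(x$state$R),
                 infected_fraction = sum(x$state$I) / sum(x$state$P),
                 acs = ps$acs, m_s = ps$m_s, band = ps$band)
}

#' Tidy a simulation result into per-location rows
#'
#' @param x a `"contagion_sim"` object.
#' @param ... unused.
#' @return A tibble with one row per location: `row`, `col`, `P`, `S`, `I`,
#'   `R`, `infected_fraction`, `benefit`.
#' @export
tidy.contagion_sim <- function(x, ...) {
  L <- x$config$L
  rc <- loc_rowcol(seq_len(L * L), L)
  tibble::tibble(row = rc[, "row"], col = rc[, "col"],
                 P = x$state$P, S = x$state$S, I = x$state$I, R = x$state$R,
                 infected_fraction = x$state$I / x$state$P,
                 benefit = location_benefit(x$state$P, x$state$I))
}

#' Tidy an alpha-plane scan
#'
#' @param x an `"alpha_scan"` tibble.
#' @param ... unused.
#' @return A plain tibble of the grid-point summaries.
#' @export
tidy.alpha_scan <- function(x, ...) {
  tibble::as_tibble(unclass_scan(x))
}

#' Tidy a zeta sweep
#'
#' @param x a `"zeta_sweep"` tibble.
#' @param ... unused.
#' @return A plain tibble of the per-zeta summaries.
#' @export
tidy.zeta_sweep <- function(x, ...) {
  tibble::as_tibble(unclass_scan(x))
}

#' Glance at a tipping-point detection
#'
#' @param x a `"critical_zeta"` object.
#' @param ... unused.
#' @return A one-row tibble: `zeta_c`, `zeta_lo`, `zeta_hi`, `max_slope`.
#' @export
glance.critical_zeta <- function(x, ...) {
  tibble::tibble(zeta_c = x$zeta_c, zeta_lo = x$bracket[1],
                 zeta_hi = x$bracket[2], max_slope = x$max_slope)
}

#' Tidy a tipping-point detection into interval slopes
#'
#' @param x a `"critical_zeta"` object.
#' @param ... unused.
#' @return The tibble of per-interval log-log slopes.
#' @export
tidy.critical_zeta <- function(x, ...) x$slopes

unclass_scan <- function(x) {
  cls <- class(x)
  class(x) <- setdiff(cls, c("alpha_scan", "zeta_sweep"))
  x
}
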