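#' Epidemic rate parameters
#'
#' Bundles the three rates of the SIRS compartmental model: transmission
#' `beta`, recovery `gamma` and susceptibility acquisition (loss of immunity)
#' `zeta`.  `zeta = 0` gives SIR dynamics (permanent immunity); `zeta = Inf`
#' is an accepted token for the SIS limit, in which recovery returns
#' individuals directly to the susceptible compartment (see
#' [run_sis_limit()]).
#'
#' @param beta transmission rate per interaction (1/time), `>= 0`.
#' @param gamma recovery rate (1/time), `>= 0`.
#' @param zeta susceptibility-acquisition rate (1/time), `>= 0` or `Inf`.
#' @return An object of class `"epidemic_params"`.
#' @export
epidemic_params <- function(beta = 10, gamma = 5, zeta = 1) {
  for (nm in c("beta", "gamma", "zeta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      stop(sprintf("`%s` must be a single number", nm), call. = FALSE)
    }
  }
  if (beta < 0 || gamma < 0) stop("rates must be non-negative", call. = FALSE)
  if (zeta < 0) stop("`zeta` must be >= 0 (use Inf for the SIS limit)", call. = FALSE)
  structure(list(beta = beta, gamma = gamma, zeta = zeta),
            class = "epidemic_params")
}

#' Risk-disposition parameters
#'
#' The Lagrange multipliers of the maximum-entropy mobility flows.
#' `alpha_S` is the risk aversion of susceptible individuals: positive
#' values attract them to destinations with a higher fraction of unaffected
#' individuals, negative values are risk-seeking.  `alpha_I` is the adaptive
#' responsiveness of affected individuals: positive values drive them away
#' from affected locations, negative values mean acceptance of the
#' contagion.  `omega` multiplies the mobility cost; under the unit-cost
#' lattice it cancels in the flow normalization and is kept only for
#' heterogeneous cost matrices.
#'
#' @param alpha_I adaptive responsiveness (dimensionless, signed).
#' @param alpha_S risk aversion (dimensionless, signed).
#' @param omega cost-sensitivity multiplier, `>= 0`.
#' @return An object of class `"risk_disposition"`.
#' @export
risk_disposition <- function(alpha_I = 0, alpha_S = 0, omega = 1) {
  for (nm in c("alpha_I", "alpha_S", "omega")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    }
  }
  if (omega < 0) stop("`omega` must be >= 0", call. = FALSE)
  structure(list(alpha_I = alpha_I, alpha_S = alpha_S, omega = omega),
            class = "risk_disposition")
}

#' Canonical well-mixed SIRS vector field
#'
#' Evaluates the right-hand side of the single-population SIRS model
#' \deqn{\dot S = -\beta I S / N + \zeta R,\quad
#'       \dot I = \beta I S / N - \gamma I,\quad
#'       \dot R = \gamma I - \zeta R,}
#' with `N = S + I + R`.  The three derivatives sum to zero exactly, so the
#' total population is conserved.
#'
#' @param state named numeric vector or list with components `S`, `I`, `R`
#'   (all `>= 0`, total `> 0`).
#' @param params an [epidemic_params()] object (finite `zeta`).
#' @return Named numeric vector `c(dS, dI, dR)`.
#' @examples
#' sirs_derivatives(c(S = 90, I = 10, R = 0), epidemic_params(10, 5, 0))
#' @export
sirs_derivatives <- function(state, params) {
  stopifnot(inherits(params, "epidemic_params"))
  S <- state[["S"]]; I <- state[["I"]]; R <- state[["R"]]
  if (any(c(S, I, R) < 0)) stop("compartments must be non-negative", call. = FALSE)
  N <- S + I + R
  if (!(N > 0)) stop("total population must be positive", call. = FALSE)
  if (is.infinite(params$zeta)) {
    stop("zeta = Inf has no finite vector field; use run_sis_limit()",
         call. = FALSE)
  }
  infection <- params$beta * I * S / N
  dS <- -infection + params$zeta * R
  dI <- infection - params$gamma * I
  dR <- params$gamma * I - params$zeta * R
  c(dS = dS, dI = dI, dR = dR)
}

#' Location benefit: fraction of unaffected individuals
#'
#' The benefit a destination `j` offers to movers is `b_j = (P_j - I_j) /
#' P_j`, the fraction of its sub-population not currently affected.  A fully
#' affected location has benefit 0; an unaffected one has benefit 1.
#'
#' @param P sub-population size(s), `> 0`.
#' @param I affected individuals, `0 <= I <= P`.
#' @return Numeric benefit(s) in `[0, 1]`, recycled to the common length.
#' @export
location_benefit <- function(P, I) {
  if (any(!is.finite(P)) || any(!is.finite(I))) {
    stop("`P` and `I` must be finite", call. = FALSE)
  }
  if (any(P <= 0)) stop("`P` must be positive", call. = FALSE)
  if (any(I < 0) || any(I > P)) stop("`I` must satisfy 0 <= I <= P", call. = FALSE)
  (P - I) / P
}

#' Map risk-disposition signs to a contagion type
#'
#' The four sign quadrants of the (`alpha_I`, `alpha_S`) plane correspond to
#' qualitatively different contagion dynamics: both positive gives
#' epidemic-like flight from the contagion; negative responsiveness with
#' positive aversion gives polarization/segregation; both negative gives
#' social-myth spreading (everyone attracted to affected locations); and
#' positive responsiveness with negative aversion gives socio-economic
#' turbulence (boom-and-bust style).  A zero on either axis is labelled
#' `"boundary"` rather than being assigned to a quadrant.
#'
#' @param alpha_I,alpha_S risk-disposition values (vectorized).
#' @return Character vector of labels: `"epidemic"`, `"polarization"`,
#'   `"social-myth"`, `"socio-economic-turbulence"` or `"boundary"`.
#' @examples
#' quadrant_of(10, 10)
#' quadrant_of(-10, -10)
#' @export
quadrant_of <- function(alpha_I, alpha_S) {
  n <- max(length(alpha_I), length(alpha_S))
  aI <- rep_len(alpha_I, n); aS <- rep_len(alpha_S, n)
  out <- rep("boundary", n)
  out[aI > 0 & aS > 0] <- "epidemic"
  out[aI < 0 & aS > 0] <- "polarization"
  out[aI < 0 & aS < 0] <- "social-myth"
  out[aI > 0 & aS < 0] <- "socio-economic-turbulence"
  out
}
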