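#' Maximum-entropy mobility flows
#'
#' Computes the closed-form least-biased destination distributions for
#' susceptible and affected individuals.  For origin `i` and reachable
#' destination `j`, the flow is proportional to `exp(alpha * b_j - omega *
#' c_ij)` with `c_ij = 1` on the lattice, normalized over the five reachable
#' destinations.  `alpha` is `alpha_S` for susceptibles and `alpha_I` for
#' affected individuals.  A per-row maximum is subtracted before
#' exponentiation so the computation is stable for exponents up to around
#' 700 in magnitude.
#'
#' @param benefits numeric vector of per-location benefits (length `M`),
#'   typically from [location_benefit()].
#' @param lattice a [build_lattice()] object.
#' @param disp a [risk_disposition()] object.
#' @return An object of class `"mobility_flows"`: a list with `phi_S` and
#'   `phi_I` (`M x 5` row-stochastic matrices over the destinations in
#'   `lattice$nbr` order), `log_Z_S` and `log_Z_I` (per-origin log partition
#'   values, cost term included), and the generating `disp`.
#' @examples
#' lat <- build_lattice(5)
#' fl <- compute_flows(rep(1, lat$M), lat, risk_disposition(2, 2))
#' rowSums(fl$phi_S)[1:3]
#' @export
compute_flows <- function(benefits, lattice, disp) {
  stopifnot(inherits(lattice, "lattice"), inherits(disp, "risk_disposition"))
  if (length(benefits) != lattice$M) {
    stop("`benefits` must have one value per location", call. = FALSE)
  }
  if (any(!is.finite(benefits))) stop("`benefits` must be finite", call. = FALSE)

  bn <- matrix(benefits[lattice$nbr], lattice$M, ncol(lattice$nbr),
               dimnames = list(NULL, colnames(lattice$nbr)))
  softmax_rows <- function(alpha) {
    E <- alpha * bn - disp$omega * 1  # all reachable costs are 1
    m <- do.call(pmax, as.data.frame(E))  # per-row max exponent
    W <- exp(E - m)
    Z <- rowSums(W)
    list(phi = W / Z, log_Z = log(Z) + m)
  }
  sS <- softmax_rows(disp$alpha_S)
  sI <- softmax_rows(disp$alpha_I)
  structure(list(phi_S = sS$phi, phi_I = sI$phi,
                 log_Z_S = sS$log_Z, log_Z_I = sI$log_Z,
                 disp = disp),
            class = "mobility_flows")
}

#' Constraint diagnostics of the mobility flows
#'
#' The maximum-entropy flows are the least-biased distributions satisfying
#' constraints on the population mean destination benefit (one constraint
#' per compartment) and the mean mobility cost.  This function evaluates
#' those means under the current state and flows: `B_I` and `B_S` are the
#' flow-weighted mean destination benefits experienced by affected and
#' susceptible individuals, and `C_bar` the mean mobility cost (identically
#' 1 under the unit-cost lattice convention).
#'
#' When a compartment is empty its mean benefit is undefined; the value is
#' returned as `NA` with no error, since an empty compartment is a valid
#' model state.
#'
#' @param state a `population_state` (see [initialize_state()]).
#' @param flows a [compute_flows()] object.
#' @param benefits the per-location benefit vector the flows were built from.
#' @param lattice the [build_lattice()] object.
#' @return A one-row tibble with columns `B_I`, `B_S`, `C_bar`.
#' @export
constraint_diagnostics <- function(state, flows, benefits, lattice) {
  stopifnot(inherits(flows, "mobility_flows"), inherits(lattice, "lattice"))
  bn <- matrix(benefits[lattice$nbr], lattice$M, ncol(lattice$nbr))
  wmean <- function(w, phi) {
    tot <- sum(w)
    if (!(tot > 0)) return(NA_real_)
    sum(w * rowSums(phi * bn)) / tot
  }
  B_I <- wmean(state$I, flows$phi_I)
  B_S <- wmean(state$S, flows$phi_S)
  den <- sum(state$I + state$S)
  C_bar <- if (den > 0) {
    # all reachable costs are 1 and rows are stochastic
    sum((state$I * rowSums(flows$phi_I) + state$S * rowSums(flows$phi_S))) / den
  } else NA_real_
  tibble::tibble(B_I = B_I, B_S = B_S, C_bar = C_bar)
}
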