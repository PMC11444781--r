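#' Simulation configuration
#'
#' Collects every knob of a lattice contagion run.  The defaults are the
#' reference study conditions used throughout the package: a 40 x 40
#' periodic lattice, transmission rate `beta = 10`, recovery rate
#' `gamma = 5`, explicit-Euler step `dt = 0.001` over `n_steps = 10000`
#' steps (total simulated time 10), uniform sub-populations of `P = 100`
#' residents, and random initial infections of up to 5% of each
#' sub-population.
#'
#' @param L lattice side length (default 40).
#' @param beta,gamma,zeta epidemic rates; see [epidemic_params()].  `zeta =
#'   Inf` selects the exact SIS update.
#' @param alpha_I,alpha_S,omega risk disposition; see [risk_disposition()].
#' @param dt Euler time step (`> 0`).
#' @param n_steps number of Euler steps (`>= 1`).
#' @param init_max_frac maximum initial infected fraction per location, in
#'   `[0, 1]`.
#' @param P uniform number of residents per location (`> 0`).
#' @param seed integer seed for the random initial condition.
#' @param n_runs default number of independent runs for sweep utilities.
#' @param snapshot_every store the infection field every this many steps
#'   (`0` = final field only).
#' @return An object of class `"sim_config"` (a named list).
#' @export
sim_config <- function(L = 40, beta = 10, gamma = 5, zeta = 1,
                       alpha_I = 0, alpha_S = 0, omega = 1,
                       dt = 0.001, n_steps = 10000, init_max_frac = 0.05,
                       P = 100, seed = 1, n_runs = 10, snapshot_every = 0) {
  params <- epidemic_params(beta, gamma, zeta)   # validates rates
  disp <- risk_disposition(alpha_I, alpha_S, omega)
  if (!(dt > 0)) stop("`dt` must be positive", call. = FALSE)
  if (!(n_steps >= 1) || n_steps != round(n_steps)) {
    stop("`n_steps` must be a positive integer", call. = FALSE)
  }
  if (init_max_frac < 0 || init_max_frac > 1) {
    stop("`init_max_frac` must be in [0, 1]", call. = FALSE)
  }
  if (!(P > 0)) stop("`P` must be positive", call. = FALSE)
  if (L < 3) stop("`L` must be at least 3", call. = FALSE)
  structure(list(L = as.integer(L), beta = beta, gamma = gamma, zeta = zeta,
                 alpha_I = alpha_I, alpha_S = alpha_S, omega = omega,
                 dt = dt, n_steps = as.integer(n_steps),
                 init_max_frac = init_max_frac, P = P,
                 seed = as.integer(seed), n_runs = as.integer(n_runs),
                 snapshot_every = as.integer(snapshot_every)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> L=%d beta=%g gamma=%g zeta=%g ",
                     "alpha_I=%g alpha_S=%g dt=%g n_steps=%d seed=%d\n"),
              x$L, x$beta, x$gamma, x$zeta, x$alpha_I, x$alpha_S,
              x$dt, x$n_steps, x$seed))
  invisible(x)
}

#' Random initial population state
#'
#' Each location starts with `I_i ~ Uniform(0, init_max_frac * P_i)` affected
#' individuals drawn independently, `S_i = P_i - I_i` susceptibles and no
#' recovered individuals.  The draw is reproducible under a fixed seed.
#'
#' @param lattice a [build_lattice()] object.
#' @param config a [sim_config()].
#' @param seed seed for the draw; defaults to `config$seed`.
#' @return An object of class `"population_state"`: list of vectors `P`,
#'   `S`, `I`, `R` of length `M`, with the lattice side stored as attribute
#'   `L`.
#' @export
initialize_state <- function(lattice, config, seed = config$seed) {
  stopifnot(inherits(lattice, "lattice"), inherits(config, "sim_config"))
  P <- rep(config$P, lattice$M)
  set.seed(seed)
  I <- runif(lattice$M, 0, config$init_max_frac) * P
  structure(list(P = P, S = P - I, I = I, R = numeric(lattice$M)),
            class = "population_state", L = lattice$L)
}

#' Network SIRS vector field (reference implementation)
#'
#' Evaluates the per-location derivatives of the metapopulation model.  New
#' transmissions to residents of `i` arise at every mixing location `j`
#' reachable from `i`, through interactions with affected individuals that
#' travelled to `j` from any origin `k`:
#' \deqn{dI_i/dt = -\gamma I_i + \beta S_i \sum_j \phi^S_{ij}
#'   \frac{\sum_k \phi^I_{kj} I_k}{\hat N_j},}
#' where the mixing population \eqn{\hat N_j} sums susceptible and affected
#' inflows (recovered individuals do not mix).  `dS` and `dR` complete the
#' SIRS bookkeeping with waning rate `zeta`; the three derivatives sum to
#' zero at every location.
#'
#' This pure-R implementation defines the model; [run_simulation()] uses an
#' equivalent compiled loop.
#'
#' @param state a `population_state`.
#' @param flows a [compute_flows()] object for the current benefit field.
#' @param params an [epidemic_params()] object (finite `zeta`).
#' @param lattice the [build_lattice()] object.
#' @return List of numeric vectors `dS`, `dI`, `dR` (length `M`).
#' @export
network_derivatives <- function(state, flows, params, lattice) {
  stopifnot(inherits(flows, "mobility_flows"), inherits(params, "epidemic_params"),
            inherits(lattice, "lattice"))
  nbr <- lattice$nbr
  M <- lattice$M
  FS <- numeric(M); FI <- numeric(M)
  for (s in seq_len(ncol(nbr))) {
    j <- nbr[, s]  # a permutation of 1:M, so the scatter-add is collision-free
    FS[j] <- FS[j] + state$S * flows$phi_S[, s]
    FI[j] <- FI[j] + state$I * flows$phi_I[, s]
  }
  Nhat <- FS + FI
  if (any(Nhat <= 0)) {
    stop("internal invariant violated: non-positive mixing population", call. = FALSE)
  }
  mix <- FI / Nhat
  incidence <- params$beta * state$S *
    rowSums(flows$phi_S * matrix(mix[nbr], M, ncol(nbr)))
  dI <- -params$gamma * state$I + incidence
  dS <- -incidence + params$zeta * state$R
  dR <- params$gamma * state$I - params$zeta * state$R
  list(dS = dS, dI = dI, dR = dR)
}

#' Run a lattice contagion simulation
#'
#' Integrates the network SIRS model with the explicit Euler scheme.  The
#' mobility flows are fast variables: they are recomputed from the benefit
#' field at the start of every step.  If `config$zeta` is infinite the exact
#' SIS update is used (recovered mass returns to `S` within the same step
#' and `R` stays zero) rather than a stiff large-`zeta` integration.
#'
#' Round-off undershoot of a compartment below zero by less than
#' `1e-9 * P_i` is clamped; a larger undershoot raises an error advising a
#' smaller `dt`.
#'
#' @param config a [sim_config()].
#' @param init optional `population_state` overriding the random initial
#'   condition (used e.g. for equivariance checks).
#' @return An object of class `"contagion_sim"`: list with `config`, the
#'   final `state`, the final infection field `field` (`L x L` matrix of
#'   `I`), `frac` (`I / P`), `snapshots` (list of `L x L` infection
#'   matrices, possibly empty) and `mode` (`"sirs"` or `"sis"`).
#' @examples
#' \donttest{
#' sim <- run_simulation(sim_config(L = 10, alpha_I = 25, alpha_S = -25,
#'                                  zeta = 100, n_steps = 2000, seed = 1))
#' glance(sim)
#' }
#' @export
run_simulation <- function(config, init = NULL) {
  stopifnot(inherits(config, "sim_config"))
  lattice <- build_lattice(config$L)
  state <- init %||% initialize_state(lattice, config)
  if (!inherits(state, "population_state")) {
    stop("`init` must be a population_state", call. = FALSE)
  }
  sis <- is.infinite(config$zeta)
  if (sis && any(state$R > 0)) {
    # SIS has no recovered compartment: fold residual R into S
    state$S <- state$S + state$R
    state$R <- numeric(length(state$R))
  }
  out <- euler_lattice(state$P, state$S, state$I, state$R, lattice$nbr,
                       config$beta, config$gamma,
                       if (sis) 0 else config$zeta,
                       config$alpha_I, config$alpha_S,
                       config$dt, config$n_steps, sis,
                       config$snapshot_every, 1e-9)
  final <- structure(list(P = state$P, S = out$S, I = out$I, R = out$R),
                     class = "population_state", L = lattice$L)
  snaps <- lapply(out$snapshots, matrix, nrow = lattice$L)
  structure(list(config = config, state = final,
                 field = matrix(out$I, lattice$L),
                 frac = matrix(out$I / state$P, lattice$L),
                 snapshots = snaps,
                 mode = if (sis) "sis" else "sirs"),
            class = "contagion_sim")
}

#' Run the exact SIS-limit simulation
#'
#' Convenience wrapper for the `zeta -> Inf` limit of [run_simulation()]:
#' the recovered compartment is bypassed, so `R` is identically zero at all
#' times.  Pattern statistics of this integrator agree with large finite
#' `zeta` runs (e.g. `zeta = 1000`) within run-to-run variability.
#'
#' @param config a [sim_config()]; its `zeta` is ignored.
#' @param init optional initial `population_state`.
#' @return A `"contagion_sim"` object with `mode = "sis"`.
#' @export
run_sis_limit <- function(config, init = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  cfg$zeta <- Inf
  run_simulation(cfg, init = init)
}

#' @export
print.contagion_sim <- function(x, ...) {
  cat(sprintf("<contagion_sim> %s, L=%d, zeta=%g, alpha_I=%g, alpha_S=%g\n",
              x$mode, x$config$L, x$config$zeta, x$config$alpha_I, x$config$alpha_S))
  cat(sprintf("  final totals: S=%.2f I=%.2f R=%.2f of %g\n",
              sum(x$state$S), sum(x$state$I), sum(x$state$R), sum(x$state$P)))
  invisible(x)
}

#' Final infection field of a simulation
#'
#' @param sim a `"contagion_sim"` object.
#' @param as_fraction return `I / P` instead of `I`.
#' @return `L x L` numeric matrix.
#' @export
final_field <- function(sim, as_fraction = FALSE) {
  stopifnot(inherits(sim, "contagion_sim"))
  if (as_fraction) sim$frac else sim$field
}

# Deterministic seed schedule: fold indices into a base seed with a
# Lehmer-style recurrence kept below 2^31 (exact in doubles).
combine_seed <- function(base, ...) {
  h <- abs(as.double(base)) %% 2147483647
  for (k in as.double(c(...))) {
    h <- (h * 69069 + abs(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# ACS of the binarized final infection field for one run (NA if undefined)
run_acs <- function(config, seed, periodic = TRUE) {
  cfg <- config
  cfg$seed <- as.integer(seed)
  sim <- run_simulation(cfg)
  occ <- binarize_above_mean(final_field(sim))
  average_cluster_size(label_clusters(occ, periodic = periodic))
}
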