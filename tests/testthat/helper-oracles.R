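# Independent oracles used to cross-check the package implementations.

# Cluster statistics via igraph connected components (independent of the
# package's BFS labelling).
oracle_cluster_sizes <- function(occ, periodic = TRUE) {
  nr <- nrow(occ); nc <- ncol(occ)
  cells <- which(occ)
  if (!length(cells)) return(integer(0))
  id <- matrix(0L, nr, nc)
  id[cells] <- seq_along(cells)
  edges <- integer(0)
  for (p in cells) {
    r <- (p - 1L) %% nr + 1L
    c <- (p - 1L) %/% nr + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (periodic) {
        rr <- (rr - 1L) %% nr + 1L
        cc <- (cc - 1L) %% nc + 1L
      } else if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (occ[rr, cc]) edges <- c(edges, id[p], id[(cc - 1L) * nr + rr])
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(cells), directed = FALSE)
  as.integer(igraph::components(g)$csize)
}

oracle_acs <- function(occ, periodic = TRUE) {
  sizes <- oracle_cluster_sizes(occ, periodic)
  if (!length(sizes)) return(NA_real_)
  sum(sizes^2) / (length(occ) * sum(sizes))
}

# one explicit Euler step of the network model, built from the R-level
# module functions (checks the compiled loop against the model definition)
r_euler_step <- function(state, config, lattice) {
  params <- epidemic_params(config$beta, config$gamma, config$zeta)
  disp <- risk_disposition(config$alpha_I, config$alpha_S, config$omega)
  b <- location_benefit(state$P, state$I)
  fl <- compute_flows(b, lattice, disp)
  d <- network_derivatives(state, fl, params, lattice)
  list(S = state$S + config$dt * d$dS,
       I = state$I + config$dt * d$dI,
       R = state$R + config$dt * d$dR)
}

# random occupancy grid with a controlled fill fraction
random_occ <- function(n, fill = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(n * n) < fill, n, n)
}

# ACS of one full-scale run (reference study conditions unless overridden)
run_acs_for_test <- function(alpha_I, alpha_S, zeta, seed, L = 40, n_steps = 10000) {
  sim <- run_simulation(sim_config(L = L, alpha_I = alpha_I, alpha_S = alpha_S,
                                   zeta = zeta, seed = seed, n_steps = n_steps))
  percolation_summary(final_field(sim))$acs
}

# small standard config for fast simulator tests
quick_config <- function(...) {
  sim_config(L = 10, n_steps = 500, ...)
}
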