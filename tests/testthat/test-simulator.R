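test_that("initial states are reproducible uniform draws capped at the max fraction", {
  lat <- build_lattice(40)
  cfg <- sim_config(seed = 9)
  st <- initialize_state(lat, cfg)
  st2 <- initialize_state(lat, cfg)
  expect_identical(st, st2)
  expect_true(all(st$I >= 0))
  expect_true(all(st$I / st$P <= 0.05))
  expect_gt(max(st$I / st$P), 0.045)  # 1600 uniform draws reach near the cap
  expect_equal(st$S + st$I, st$P)
  expect_equal(st$R, numeric(lat$M))

  cfg0 <- sim_config(init_max_frac = 0)
  st0 <- initialize_state(lat, cfg0)
  expect_equal(st0$I, numeric(lat$M))
  expect_equal(st0$S, st0$P)
})

test_that("network derivatives conserve per-location population and respect symmetry", {
  lat <- build_lattice(4)
  params <- epidemic_params(10, 5, 1)
  disp <- risk_disposition(3, -2)

  # uniform state on a torus: identical derivatives everywhere
  st <- structure(list(P = rep(100, lat$M), S = rep(85, lat$M),
                       I = rep(10, lat$M), R = rep(5, lat$M)),
                  class = "population_state", L = lat$L)
  fl <- compute_flows(location_benefit(st$P, st$I), lat, disp)
  d <- network_derivatives(st, fl, params, lat)
  expect_lt(diff(range(d$dI)), 1e-12)
  expect_lt(diff(range(d$dS)), 1e-12)
  expect_equal(d$dS + d$dI + d$dR, numeric(lat$M))

  # disease-free equilibrium: all derivatives vanish when I = R = 0
  st0 <- structure(list(P = rep(100, lat$M), S = rep(100, lat$M),
                        I = numeric(lat$M), R = numeric(lat$M)),
                   class = "population_state", L = lat$L)
  fl0 <- compute_flows(location_benefit(st0$P, st0$I), lat, disp)
  d0 <- network_derivatives(st0, fl0, params, lat)
  expect_equal(d0$dS, numeric(lat$M))
  expect_equal(d0$dI, numeric(lat$M))
  expect_equal(d0$dR, numeric(lat$M))
})

test_that("a uniform R-free state reduces to the well-mixed SIRS field", {
  # with every location identical and R = 0, the mixing population at each
  # location is S + I = N, so the network incidence equals the canonical one
  lat <- build_lattice(4)
  params <- epidemic_params(10, 5, 2)
  disp <- risk_disposition(-7, 4)
  st <- structure(list(P = rep(100, lat$M), S = rep(90, lat$M),
                       I = rep(10, lat$M), R = numeric(lat$M)),
                  class = "population_state", L = lat$L)
  fl <- compute_flows(location_benefit(st$P, st$I), lat, disp)
  d <- network_derivatives(st, fl, params, lat)
  ref <- sirs_derivatives(c(S = 90, I = 10, R = 0), params)
  expect_equal(d$dS[1], ref[["dS"]], tolerance = 1e-12)
  expect_equal(d$dI[1], ref[["dI"]], tolerance = 1e-12)
  expect_equal(d$dR[1], ref[["dR"]], tolerance = 1e-12)
})

test_that("one compiled Euler step equals the R-level module composition", {
  cfg <- sim_config(L = 8, n_steps = 1, alpha_I = 12, alpha_S = -8,
                    zeta = 3, seed = 21)
  lat <- build_lattice(cfg$L)
  st <- initialize_state(lat, cfg)
  sim <- run_simulation(cfg)
  ref <- r_euler_step(st, cfg, lat)
  expect_equal(sim$state$S, ref$S, tolerance = 1e-12)
  expect_equal(sim$state$I, ref$I, tolerance = 1e-12)
  expect_equal(sim$state$R, ref$R, tolerance = 1e-12)
})

test_that("full runs conserve per-location population and stay non-negative", {
  cfg <- sim_config(L = 10, n_steps = 2000, alpha_I = 25, alpha_S = -25,
                    zeta = 100, seed = 2)
  sim <- run_simulation(cfg)
  tot <- sim$state$S + sim$state$I + sim$state$R
  expect_lt(max(abs(tot - sim$state$P)), 1e-9 * cfg$P)
  expect_true(all(sim$state$S >= 0 & sim$state$I >= 0 & sim$state$R >= 0))
})

test_that("beta = 0 gives the exact per-step exponential Euler decay", {
  cfg <- sim_config(L = 5, beta = 0, gamma = 5, zeta = 0, n_steps = 1000, seed = 3)
  lat <- build_lattice(cfg$L)
  st <- initialize_state(lat, cfg)
  sim <- run_simulation(cfg)
  expect_equal(sim$state$I, st$I * (1 - cfg$gamma * cfg$dt)^cfg$n_steps,
               tolerance = 1e-12)
})

test_that("dynamics are invariant to a global rescaling of sub-populations", {
  base <- sim_config(L = 5, n_steps = 1000, alpha_I = 25, alpha_S = -25,
                     zeta = 100, seed = 6)
  doubled <- base
  doubled$P <- 200
  f1 <- final_field(run_simulation(base), as_fraction = TRUE)
  f2 <- final_field(run_simulation(doubled), as_fraction = TRUE)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("final fields are equivariant under torus translations of the start", {
  cfg <- sim_config(L = 8, n_steps = 500, alpha_I = -20, alpha_S = 15,
                    zeta = 10, seed = 8)
  lat <- build_lattice(cfg$L)
  st <- initialize_state(lat, cfg)
  shift <- function(m, dr, dc) {
    m[(seq_len(nrow(m)) - 1 - dr) %% nrow(m) + 1,
      (seq_len(ncol(m)) - 1 - dc) %% ncol(m) + 1]
  }
  st_shift <- st
  for (f in c("P", "S", "I", "R")) {
    st_shift[[f]] <- as.vector(shift(matrix(st[[f]], cfg$L), 3, 5))
  }
  f1 <- final_field(run_simulation(cfg, init = st))
  f2 <- final_field(run_simulation(cfg, init = st_shift))
  expect_equal(shift(f1, 3, 5), f2, tolerance = 1e-9)
})

test_that("indifferent mobility homogenizes the infection field", {
  cfg <- sim_config(L = 10, n_steps = 2000, alpha_I = 0, alpha_S = 0,
                    zeta = 10, seed = 4)
  lat <- build_lattice(cfg$L)
  st <- initialize_state(lat, cfg)
  sim <- run_simulation(cfg)
  expect_lt(var(as.vector(final_field(sim, as_fraction = TRUE))),
            var(st$I / st$P))
})

test_that("the SIS limit keeps R at zero and decays when beta = 0", {
  cfg <- sim_config(L = 6, n_steps = 800, alpha_I = 5, alpha_S = 5, seed = 10)
  sim <- run_sis_limit(cfg)
  expect_equal(sim$mode, "sis")
  expect_equal(sim$state$R, numeric(36))
  expect_equal(sim$state$S + sim$state$I, sim$state$P, tolerance = 1e-9)

  cfg0 <- sim_config(L = 6, beta = 0, n_steps = 800, seed = 10)
  sim0 <- run_sis_limit(cfg0)
  expect_lt(sum(sim0$state$I), sum(initialize_state(build_lattice(6), cfg0)$I))
})

test_that("unstable time steps raise a stability error advising smaller dt", {
  cfg <- sim_config(L = 5, dt = 0.5, n_steps = 200, alpha_I = 10,
                    alpha_S = 10, zeta = 1, seed = 1)
  expect_error(run_simulation(cfg), "reduce dt")
})

test_that("snapshots record the infection field on the requested stride", {
  cfg <- sim_config(L = 5, n_steps = 100, snapshot_every = 50, zeta = 1, seed = 2)
  sim <- run_simulation(cfg)
  expect_length(sim$snapshots, 2)
  expect_equal(sim$snapshots[[2]], sim$field)
})
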