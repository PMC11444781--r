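#!/usr/bin/env Rscript

# Full phase-diagram batch: the complete risk-disposition plane
# (alpha_I, alpha_S in -50..50, step 5) at four susceptibility-acquisition
# values, 10 independent runs per grid point, at the reference study
# conditions (L = 40, beta = 10, gamma = 5, dt = 0.001, 10^4 steps).
#
# This is a batch job, not a test: 21 x 21 points x 4 zeta x 10 runs
# ~ 17,600 lattice integrations (order of a day on a single core; grid
# points are independent, so it parallelizes trivially by splitting the
# zeta values or grid rows across processes).
#
#   Rscript scripts/phase_diagram_batch.R [--seed N] [--runs K] [--out DIR]

suppressPackageStartupMessages(library(sirscape))

args <- commandArgs(trailingOnly = TRUE)
get_opt <- function(name, default) {
  i <- which(args == name)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_opt("--seed", 1))
runs <- as.integer(get_opt("--runs", 10))
out <- get_opt("--out", "results/phase_diagrams")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (zeta in c(0.3, 1, 100, 1000)) {
  message("scanning zeta = ", zeta, " ...")
  sc <- scan_alpha_plane(zeta, alpha_grid(), alpha_grid(),
                         config = sim_config(seed = seed),
                         n_runs = runs, base_seed = seed)
  csv <- file.path(out, sprintf("alpha_scan_zeta%g.csv", zeta))
  utils::write.csv(tidy(sc), csv, row.names = FALSE)
  ggplot2::ggsave(file.path(out, sprintf("phase_diagram_zeta%g.png", zeta)),
                  autoplot(sc), width = 7, height = 6, dpi = 150)
  write_run_manifest(file.path(out, sprintf("manifest_zeta%g.json", zeta)),
                     sim_config(seed = seed), seed, csv,
                     extra = list(zeta = zeta, n_runs = runs))
}
message("done; outputs in ", out)
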