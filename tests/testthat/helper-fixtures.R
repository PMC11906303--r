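# Shared in-code fixtures for the test suite.

# measured species of the default N2O enrichment system, in rate-table order
measured_species <- c("acetate", "n2o", "nh4", "biomass")

rate_table <- function(rates, sds) {
  data.frame(species = measured_species, rate = rates, sd = sds)
}

# printed steady-state (D, Y_X/Ac) triples of the two regimes
exc_points <- data.frame(D = c(0.006, 0.028, 0.089), Y = c(0.15, 0.25, 0.27))
lim_points <- data.frame(D = c(0.006, 0.027, 0.086), Y = c(0.24, 0.32, 0.33))

# printed yield table (six rows, both regimes)
yield_rows <- data.frame(
  regime   = rep(c("N2Oexc", "N2Olim"), each = 3),
  D        = c(0.006, 0.028, 0.089, 0.006, 0.027, 0.086),
  y_x_ac   = c(0.15, 0.25, 0.27, 0.24, 0.32, 0.33),
  y_x_ac_sd = c(0.03, 0.02, 0.01, 0.04, 0.04, 0.03),
  y_x_n2o  = c(0.09, 0.16, 0.17, 0.15, 0.22, 0.26),
  y_n2o_ac = c(3.42, 3.06, 3.1, 3.1, 2.86, 2.49),
  y_n2o_ac_sd = c(0.35, 0.2, 0.17, 0.15, 0.51, 0.29))

# independent reconciliation oracle: project the measured vector onto the
# constraint null space by weighted least squares on a null-space basis —
# no shared code with the Lagrange-multiplier solution in reconcile()
reconcile_oracle <- function(r, sd, E) {
  sv <- svd(E, nv = ncol(E))
  rank <- sum(sv$d > 1e-12 * max(sv$d))
  N <- sv$v[, (rank + 1):ncol(E), drop = FALSE]
  w <- 1 / sd^2
  fit <- stats::lm.wfit(x = N, y = r, w = w)
  r_hat <- as.vector(N %*% fit$coefficients)
  h <- sum(w * (r - r_hat)^2)
  list(r_hat = r_hat, h = h)
}

# random full-row-rank constraint system on n measured species
random_system <- function(n, n_constraints, seed) {
  set.seed(seed)
  repeat {
    E <- matrix(round(stats::runif(n_constraints * n, -4, 4), 1),
                n_constraints, n)
    if (qr(E)$rank == n_constraints && all(rowSums(abs(E)) > 0)) break
  }
  r <- round(stats::rnorm(n, 0, 10), 2)
  sd <- round(stats::runif(n, 0.2, 2), 2)
  list(E = E, r = r, sd = sd)
}
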