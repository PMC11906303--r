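sys <- n2o_species_system()
E_full <- conservation_matrix(sys)

test_that("constraint reduction returns E itself when everything is measured", {
  E <- rbind(c(2, 1, 0), c(0, 1, 1))
  colnames(E) <- c("a", "b", "c")
  expect_equal(reduce_constraints(E, c(TRUE, TRUE, TRUE)), E)
})

test_that("the enrichment system reduces to the single electron balance", {
  red <- reduce_constraints(E_full, measured = measured_species)
  expect_equal(nrow(red), 1L)
  # unique up to scale: the degree-of-reduction balance at N valence 0,
  # coefficients (8, -2, 3, 4.8) on (acetate, N2O, NH4+, biomass)
  v <- as.vector(red[1, measured_species]) / red[1, "acetate"] * 8
  expect_equal(v, c(8, -2, 3, 4.8), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a single measured rate leaves zero testable constraints", {
  red <- reduce_constraints(E_full,
                            measured = colnames(E_full) == "acetate")
  expect_equal(nrow(red), 0L)
  r1 <- data.frame(species = "acetate", rate = -10, sd = 0.5)
  expect_warning(fit <- reconcile(r1, E = red), "zero redundancy")
  expect_true(fit$dof_zero)
  expect_identical(fit$dof, 0L)
  expect_true(is.na(fit$h_statistic))
  expect_equal(fit$reconciled$rate, -10)
})

test_that("exact catabolic rates pass unchanged and unmeasured rates back-solve", {
  r <- rate_table(c(-10, -40, 0, 0), c(0.5, 2, 0.1, 0.1))
  fit <- reconcile(r, system = sys)
  expect_equal(fit$h_statistic, 0, tolerance = 1e-20)
  expect_equal(fit$reconciled$rate, r$rate, tolerance = 1e-12)
  expect_equal(fit$solved_unmeasured[["co2"]], 20, tolerance = 1e-9)
  expect_equal(fit$solved_unmeasured[["n2"]], 40, tolerance = 1e-9)
  expect_equal(fit$solved_unmeasured[["h2o"]], 20, tolerance = 1e-9)
})

test_that("reconciliation equals the null-space weighted least-squares oracle", {
  r <- c(-10, -38, 0, 0); sd <- c(0.5, 2, 0.1, 0.1)
  red <- reduce_constraints(E_full, measured = measured_species)
  fit <- reconcile(rate_table(r, sd), E = red)
  ora <- reconcile_oracle(r, sd, red)
  expect_equal(fit$reconciled$rate, ora$r_hat, tolerance = 1e-8)
  expect_equal(fit$h_statistic, ora$h, tolerance = 1e-8)
  # reconciled rates satisfy the constraint to 1e-8 relative
  expect_lt(max(abs(red %*% fit$reconciled$rate)) /
              max(abs(fit$reconciled$rate)), 1e-8)
})

test_that("oracle equivalence holds on randomized small systems", {
  for (seed in 1:25) {
    n <- sample(3:8, 1)
    k <- sample(1:min(3, n - 1), 1)
    s <- random_system(n, k, seed)
    rt <- data.frame(species = paste0("s", 1:n), rate = s$r, sd = s$sd)
    fit <- reconcile(rt, E = s$E)
    ora <- reconcile_oracle(s$r, s$sd, s$E)
    expect_equal(fit$reconciled$rate, ora$r_hat, tolerance = 1e-8)
    expect_equal(fit$h_statistic, ora$h, tolerance = 1e-8)
    expect_lt(max(abs(s$E %*% fit$reconciled$rate)),
              1e-8 * max(1, max(abs(fit$reconciled$rate))))
  }
})

test_that("reconciliation is an idempotent projection", {
  r <- rate_table(c(-10, -36, -0.4, 1.6), c(0.5, 2, 0.1, 0.1))
  fit1 <- reconcile(r, system = sys)
  fit2 <- reconcile(fit1$reconciled[, c("species", "rate")] |>
                      transform(sd = r$sd), system = sys)
  expect_equal(fit2$reconciled$rate, fit1$reconciled$rate, tolerance = 1e-10)
  expect_equal(fit2$h_statistic, 0, tolerance = 1e-16)
})

test_that("h is invariant to a common rescaling of rates and sds", {
  r <- rate_table(c(-10, -36, -0.4, 1.6), c(0.5, 2, 0.1, 0.1))
  fit1 <- reconcile(r, system = sys)
  r2 <- transform(r, rate = rate * 7.3, sd = sd * 7.3)
  fit2 <- reconcile(r2, system = sys)
  expect_equal(fit2$h_statistic, fit1$h_statistic, tolerance = 1e-10)
})

test_that("shrinking a species' sd pulls its reconciled rate toward the measurement", {
  r0 <- c(-10, -36, -0.4, 1.6)
  sds <- c(0.5, 2, 0.1, 0.1)
  gaps <- vapply(c(2, 0.5, 0.1, 0.02), function(s_n2o) {
    fit <- reconcile(rate_table(r0, replace(sds, 2, s_n2o)), system = sys)
    abs(fit$reconciled$rate[2] - r0[2])
  }, numeric(1))
  expect_true(all(diff(gaps) <= 1e-12))
})

test_that("degenerate inputs raise named errors", {
  r <- rate_table(c(-10, -36, -0.4, 1.6), c(0.5, 2, 0.1, 0.1))
  expect_error(reconcile(transform(r, sd = c(0, 2, 0.1, 0.1)), system = sys),
               "sd > 0")
  # duplicated constraint rows make P singular
  red <- reduce_constraints(E_full, measured = measured_species)
  expect_error(reconcile(r, E = rbind(red, red)), "singular")
  # species missing from the rate table is named
  expect_error(reconcile(r[-2, ], system = sys), "n2o")
})

test_that("the gross-error test passes at the chi-squared boundary and fails beyond", {
  r <- rate_table(c(-10, -40, 0, 0), c(0.5, 2, 0.1, 0.1))
  fit0 <- reconcile(r, system = sys)
  expect_true(gross_error_test(fit0, alpha = 0.5)$pass)

  make_fit_with_h <- function(h_target) {
    # scale the n2o rate so the single-constraint h lands on target
    red <- reduce_constraints(E_full, measured = measured_species)
    f <- function(d) {
      reconcile(rate_table(c(-10, -40 + d, 0, 0), c(0.5, 2, 0.1, 0.1)),
                E = red)$h_statistic - h_target
    }
    d <- uniroot(f, c(0, 50), tol = 1e-12)$root
    reconcile(rate_table(c(-10, -40 + d, 0, 0), c(0.5, 2, 0.1, 0.1)),
              E = red)
  }
  fit_b <- make_fit_with_h(qchisq(0.95, 1))
  expect_equal(fit_b$p_value, 0.05, tolerance = 1e-6)
  expect_true(gross_error_test(fit_b, alpha = 0.05)$pass)  # strict <
  fit_f <- make_fit_with_h(10)
  gt <- gross_error_test(fit_f, alpha = 0.05)
  expect_false(gt$pass)
  # with one constraint the standardized adjustments are proportional to
  # sd_i * |E_i|: acetate (0.5*8) and n2o (2*2) tie for the largest
  expect_match(gt$message, "acetate|n2o")
  expect_equal(gt$p_value, pchisq(10, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("exempting ammonium removes it from the balance set", {
  r <- rate_table(c(-10, -36, -0.4, 1.6), c(0.5, 2, 0.1, 0.1))
  fit <- reconcile(r[-3, ], system = sys, exempt = "nh4")
  expect_equal(fit$dof, 1L)
  expect_false("nh4" %in% fit$reconciled$species)
})
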