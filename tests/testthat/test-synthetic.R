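test_that("generators are bit-reproducible given a seed", {
  tr <- chemostat_ground_truth("N2Oexc")
  d1 <- generate_chemostat_dataset(tr, seed = 123)
  d2 <- generate_chemostat_dataset(tr, seed = 123)
  expect_identical(d1, d2)
  b1 <- generate_batch_series(0.5, 0.9, seed = 5)
  b2 <- generate_batch_series(0.5, 0.9, seed = 5)
  expect_identical(b1, b2)
  s1 <- generate_spectral_counts(c(a = 0.6, b = 0.4), seed = 9)
  s2 <- generate_spectral_counts(c(a = 0.6, b = 0.4), seed = 9)
  expect_identical(s1, s2)
})

test_that("pre-noise chemostat rates close every conservation balance exactly", {
  sys <- n2o_species_system()
  E <- conservation_matrix(sys)
  red <- reduce_constraints(E, measured = measured_species)
  for (preset in c("N2Oexc", "N2Olim")) {
    tr <- chemostat_ground_truth(preset, cv = 0)
    d <- generate_chemostat_dataset(tr, seed = 1)
    for (i in seq_along(d$true_rates)) {
      r <- d$true_rates[[i]]$rate
      expect_lt(max(abs(red %*% r)), 1e-9 * max(abs(r)))
    }
  }
})

test_that("noiseless closed loop: h = 0 at every D and m_s recovered exactly", {
  tr <- chemostat_ground_truth("N2Oexc", cv = 0)
  d <- generate_chemostat_dataset(tr, seed = 1)
  sys <- n2o_species_system()
  for (rt in d$rates) {
    rt$sd <- pmax(abs(rt$rate) * 0.05, 1e-6)  # nominal sds for the test
    expect_lt(reconcile(rt, system = sys)$h_statistic, 1e-16)
  }
  fit <- estimate_maintenance(d$true_yields$D, d$true_yields$Y)
  expect_equal(fit$m_s, 0.019, tolerance = 1e-10)
  expect_equal(fit$y_max, 0.29, tolerance = 1e-10)
})

test_that("the residual statistic follows chi-squared(1) on consistent noisy data", {
  tr <- chemostat_ground_truth("N2Oexc", cv = 0.05)
  sys <- n2o_species_system()
  E <- conservation_matrix(sys)
  red <- reduce_constraints(E, measured = measured_species)
  set.seed(2024)
  h <- replicate(1000, {
    d <- generate_chemostat_dataset(tr)
    rt <- d$rates[[1]]
    rt$sd <- tr$cv * abs(d$true_rates[[1]]$rate)
    reconcile(rt[, c("species", "rate", "sd")], E = red)$h_statistic
  })
  expect_equal(mean(h), 1, tolerance = 0.15)
  expect_equal(unname(quantile(h, 0.95)), qchisq(0.95, 1), tolerance = 0.2)
  expect_gt(ks.test(h, pchisq, df = 1)$p.value, 0.01)
})

test_that("Monte-Carlo maintenance recovery is within 10% at 5% rate noise", {
  tr <- chemostat_ground_truth("N2Oexc", cv = 0.05)
  set.seed(77)
  m_s_hat <- replicate(500, {
    d <- generate_chemostat_dataset(tr)
    Y <- vapply(d$rates, function(rt) {
      r <- setNames(rt$rate, rt$species)
      abs(r[["biomass"]] / (2 * r[["acetate"]]))
    }, numeric(1))
    estimate_maintenance(tr$D, Y)$m_s
  })
  expect_lt(abs(mean(m_s_hat) - tr$m_s) / tr$m_s, 0.10)
})

test_that("batch generator inverts within 5% over 200 seeds and validates inputs", {
  q <- 0.5; X <- 0.9
  slopes <- vapply(1:200, function(s) {
    bs <- generate_batch_series(q, X, n_points = 8, dt = 0.25,
                                noise_sd = 0.02, seed = s)
    fit_volumetric_rate(bs)$rate
  }, numeric(1))
  expect_lt(abs(mean(slopes) - q * X) / (q * X), 0.05)
  # noiseless recovery is exact
  bs0 <- generate_batch_series(q, X, noise_sd = 0, seed = 1)
  expect_equal(fit_volumetric_rate(bs0)$rate, q * X, tolerance = 1e-12)
  expect_error(generate_batch_series(q, X, n_points = 3), "at least four")
  expect_error(generate_batch_series(-1, X), "domain error")
})

test_that("spectral-count sampling recovers proteome fractions", {
  f <- c(p1 = 0.5, p2 = 0.3, p3 = 0.2)
  g <- generate_spectral_counts(f, depth = 1e6, n_injections = 2, seed = 3)
  sh <- normalize_spectral_counts(g$table)
  expect_lt(max(abs(rowMeans(sh) - f)), 0.005)

  # single protein takes all counts
  g1 <- generate_spectral_counts(c(only = 1), depth = 100, seed = 1)
  expect_equal(unname(colSums(g1$table$counts)), rep(100, 4))

  # contaminants carry one unique peptide and are filtered out
  gc <- generate_spectral_counts(f, depth = 20000,
                                 contaminant_fraction = 0.05,
                                 n_contaminants = 3, seed = 8)
  sh <- normalize_spectral_counts(gc$table)
  ab <- filter_and_average(sh, gc$table)
  expect_false(any(ab$retained[gc$truth$contaminant]))
  expect_error(generate_spectral_counts(c(0.5, 0.4)), "sum to 1")
})

test_that("MAG proteome fractions are recovered from multinomial sampling", {
  f <- c(0.7, 0.2, 0.1)
  prot_per_mag <- 20
  mags <- rep(c("M1", "M2", "M3"), each = prot_per_mag)
  fractions <- unlist(lapply(f, function(x) rep(x / prot_per_mag,
                                                prot_per_mag)))
  names(fractions) <- sprintf("p%03d", seq_along(fractions))
  g <- generate_spectral_counts(fractions, depth = 20000, seed = 21)
  sh <- normalize_spectral_counts(g$table)
  ab <- filter_and_average(sh, g$table)
  frac <- mag_proteome_fraction(ab, data.frame(protein_id = names(fractions),
                                               mag_id = mags))
  got <- setNames(frac$spectra_pct, frac$mag_id)[c("M1", "M2", "M3")]
  expect_lt(max(abs(got - 100 * f)), 3)
})

test_that("Poisson read sampling recovers MAG abundances and read shares", {
  cl <- data.frame(contig_id = sprintf("c%d", 1:4),
                   mag_id = c("M1", "M1", "M2", "M2"),
                   length_bp = c(1e6, 1e6, 1.2e6, 0.8e6))
  a <- c(M1 = 0.8, M2 = 0.2)
  cm <- generate_mag_reads(a, cl, total_reads = 1e6, seed = 4)
  # equal genome sizes: read split approximately 80/20
  rf <- mag_read_fraction(cm, total_reads = sum(cm$mapped_reads))
  got <- setNames(rf$per_mag$read_pct, rf$per_mag$mag_id)
  expect_lt(abs(got[["M1"]] - 80), 0.5)
  na <- mag_normalized_abundance(cm)
  expect_lt(max(abs(setNames(na$rel_abundance, na$mag_id)[names(a)] - a)),
            0.01)

  # single MAG at abundance 1: the full read pool maps to it
  cm1 <- generate_mag_reads(c(M1 = 1), cl[1:2, ], total_reads = 1e6,
                            seed = 5)
  rf1 <- mag_read_fraction(cm1, total_reads = sum(cm1$mapped_reads))
  expect_equal(rf1$binned_pct, 100)

  # zero total reads -> all-zero table
  cm0 <- generate_mag_reads(a, cl, total_reads = 0, seed = 6)
  expect_true(all(cm0$mapped_reads == 0))
  expect_error(generate_mag_reads(c(M1 = 0.9, M2 = 0.2), cl, 100),
               "sum <= 1")
})

test_that("unbinned remainder becomes a pseudo-bin with the leftover reads", {
  cl <- data.frame(contig_id = c("c1", "c2"), mag_id = c("M1", "M2"),
                   length_bp = c(2e6, 2e6))
  cm <- generate_mag_reads(c(M1 = 0.6, M2 = 0.2), cl, total_reads = 1e6,
                           seed = 11)
  expect_true("unbinned" %in% cm$mag_id)
  rf <- mag_read_fraction(cm, total_reads = sum(cm$mapped_reads))
  expect_lt(abs(rf$binned_pct - 80), 1)
})
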