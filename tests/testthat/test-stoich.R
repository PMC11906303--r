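test_that("formula parsing handles fractional subscripts and charges", {
  ac <- parse_formula("C2H3O2-")
  expect_equal(c(ac$n_C, ac$n_H, ac$n_O, ac$n_N, ac$charge),
               c(2, 3, 2, 0, -1))
  bio <- parse_formula("CH1.8O0.5N0.2")
  expect_equal(c(bio$n_C, bio$n_H, bio$n_O, bio$n_N, bio$charge),
               c(1, 1.8, 0.5, 0.2, 0))
  expect_equal(parse_formula("NH4+")$charge, 1)
  expect_equal(parse_formula("H+")$n_H, 1)
  expect_error(parse_formula(""), "composition|parse")
  expect_error(parse_formula("SO4-2"), "unsupported element")
  expect_error(elemental_composition(), "empty composition")
  expect_error(elemental_composition(n_C = -1), "non-negative")
})

test_that("degree of reduction matches the reference electron bookkeeping", {
  expect_equal(degree_of_reduction("C2H3O2-"), 8)
  expect_equal(degree_of_reduction("CH1.8O0.5N0.2"), 4.2)
  expect_equal(degree_of_reduction("CO2"), 0)
  expect_equal(degree_of_reduction("CO2", n_reference_valence = 0), 0)
  expect_equal(degree_of_reduction("N2O", n_reference_valence = 0), -2)
  expect_equal(degree_of_reduction("NH4+"), 0)
})

test_that("degree of reduction is linear in composition", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0.1, 3); b <- runif(1, 0.1, 3)
    c1 <- elemental_composition(runif(1, 0, 3), runif(1, 0, 6),
                                runif(1, 0, 3), runif(1, 0, 2),
                                runif(1, -2, 2))
    c2 <- elemental_composition(runif(1, 0, 3), runif(1, 0, 6),
                                runif(1, 0, 3), runif(1, 0, 2),
                                runif(1, -2, 2))
    comb <- elemental_composition(a * c1$n_C + b * c2$n_C,
                                  a * c1$n_H + b * c2$n_H,
                                  a * c1$n_O + b * c2$n_O,
                                  a * c1$n_N + b * c2$n_N,
                                  a * c1$charge + b * c2$charge)
    vn <- runif(1, -3, 0)
    expect_equal(degree_of_reduction(comb, vn),
                 a * degree_of_reduction(c1, vn) +
                   b * degree_of_reduction(c2, vn))
  }
})

test_that("conservation matrix reads atom counts off the formulas", {
  s2 <- species_system(species("ac", "C2H3O2-", measured = TRUE),
                       species("co2", "CO2"))
  expect_equal(unname(conservation_matrix(s2, "C")), rbind(c(2, 1)))
  s3 <- species_system(species("n2o", "N2O", measured = TRUE),
                       species("n2", "N2"), species("nh4", "NH4+"))
  expect_equal(unname(conservation_matrix(s3, "N")), rbind(c(2, 2, 1)))
  E <- conservation_matrix(n2o_species_system())
  expect_equal(dim(E), c(5L, 8L))
  expect_equal(unname(E[, "biomass"]), c(1, 1.8, 0.5, 0.2, 0))
  expect_error(conservation_matrix(n2o_species_system(), character(0)),
               "empty balance set")
})

test_that("catabolic balancing yields 4 N2O per acetate and closes all balances", {
  rxn <- balance_catabolism(
    species("acetate", "C2H3O2-", role = "electron_donor"),
    species("n2o", "N2O", role = "electron_acceptor"),
    products = c("CO2", "N2", "H2O", "H+"))
  expect_equal(unclass(rxn)[c("acetate", "n2o", "H+", "CO2", "N2", "H2O")],
               c(acetate = -1, n2o = -4, `H+` = -1, CO2 = 2, N2 = 4,
                 H2O = 2))
  # every conservation row closes to 1e-9
  sysr <- species_system(c(
    list(species("acetate", "C2H3O2-", measured = TRUE),
         species("n2o", "N2O")),
    lapply(c("CO2", "N2", "H2O", "H+"), function(f) species(f, f))))
  E <- conservation_matrix(sysr)
  expect_lt(max(abs(E %*% unclass(rxn)[colnames(E)])), 1e-9)
})

test_that("hydrogen as two-electron donor takes one N2O", {
  rxn <- balance_catabolism(species("h2", "H2", role = "electron_donor"),
                            species("n2o", "N2O",
                                    role = "electron_acceptor"),
                            products = c("N2", "H2O"))
  expect_equal(rxn[["n2o"]], -1)
  expect_equal(rxn[["N2"]], 1)
})

test_that("missing product species raises a stoichiometry error naming a balance", {
  expect_error(
    balance_catabolism(species("acetate", "C2H3O2-", role = "electron_donor"),
                       species("n2o", "N2O", role = "electron_acceptor"),
                       products = c("CO2", "H2O", "H+")),
    "stoichiometry error")
})

test_that("electron-balance yield closure reproduces catabolism and Table-consistent yields", {
  expect_equal(predict_yields_from_electron_balance(0)$y_n2o_ac, 4)
  p <- predict_yields_from_electron_balance(0.15)
  expect_equal(p$y_n2o_ac, 3.37)
  # predicted 3.37 is within the printed SD of the measured 3.42 +/- 0.35
  expect_lt(abs(p$y_n2o_ac - 3.42), 0.35)
  p2 <- predict_yields_from_electron_balance(0.24)
  expect_equal(p2$y_x_n2o, 2 * 0.24 / (4 - 4.2 * 0.24), tolerance = 1e-12)
  expect_lt(abs(p2$y_x_n2o - 0.15), 0.03)
  expect_error(predict_yields_from_electron_balance(0.96), "domain error")
  expect_error(predict_yields_from_electron_balance(-0.01), "domain error")
})

test_that("yield closure at zero growth matches balance_catabolism for any donor ratio", {
  # property: catabolic donor:acceptor ratio equals the zero-growth closure
  rxn <- balance_catabolism(
    species("acetate", "C2H3O2-", role = "electron_donor"),
    species("n2o", "N2O", role = "electron_acceptor"),
    products = c("CO2", "N2", "H2O", "H+"))
  expect_equal(abs(rxn[["n2o"]] / rxn[["acetate"]]),
               predict_yields_from_electron_balance(0)$y_n2o_ac)
  for (y in seq(0, 0.9, by = 0.15)) {
    p <- predict_yields_from_electron_balance(y)
    expect_equal(8.4 * y + 2 * p$y_n2o_ac, 8, tolerance = 1e-12)
  }
})

test_that("species systems validate names, measured flags and config loading", {
  expect_error(species_system(species("a", "CO2", measured = TRUE),
                              species("a", "N2")),
               "duplicate")
  expect_error(species_system(species("a", "CO2"), species("b", "N2")),
               "at least one measured")
  cfg <- system.file("extdata", "species_n2o.yml", package = "chemobalance")
  sys <- read_species_config(cfg)
  expect_s3_class(sys, "species_system")
  expect_identical(names(sys), names(n2o_species_system()))
  expect_equal(sys$biomass$composition$n_N, 0.2)
})
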