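test_that("the solved carbohydrate reaction reproduces the published stoichiometry", {
  rx <- build_carbohydrate_reaction(biomass_yield = 0.042,
                                    ratios = scfa_ratios(0.31, 0.15))
  cf <- rx$coefficients
  # acetate from the electron balance: (4 - 0.042*20) / (8 + 0.31*14 + 0.15*20)
  expect_equal(cf[["acetate"]], (4 - 0.84) / 15.34)
  published <- c(biomass = 0.042, acetate = 0.206, propionate = 0.064,
                 n_butyrate = 0.031, co2 = 0.063, h2o = 0.102,
                 nh3 = -0.042)
  for (sp in names(published)) {
    expect_lt(abs(cf[[sp]] - published[[sp]]), 0.001)
  }
  bal <- check_balance(rx, tolerance = 0.005)
  expect_true(all(bal$ok))
})

test_that("the homoacetogenic limit is forced by the carbon and electron balances", {
  rx <- build_carbohydrate_reaction(biomass_yield = 0,
                                    ratios = scfa_ratios(0, 0))
  expect_equal(rx$coefficients[["acetate"]], 0.5)
  expect_equal(rx$coefficients[["co2"]], 0)
  expect_equal(rx$coefficients[["h2o"]], -0.087)
  expect_equal(cod_yield_fractions(rx)[["acetate"]], 1)
})

test_that("infeasible biomass yields are rejected with the violated balance named", {
  expect_error(build_carbohydrate_reaction(biomass_yield = 0.25),
               "\\[0, substrate C/5\\]")
  # low-electron substrate: biomass demands more electrons than available
  expect_error(
    build_carbohydrate_reaction(parse_formula("CH0.5O1"),
                                biomass_yield = 0.15),
    "electron balance")
})

test_that("the fixed protein reaction closes its balances within 1%", {
  rx <- protein_reaction()
  expect_equal(rx$coefficients[["biomass"]], 0.020)
  expect_equal(rx$coefficients[["nh3"]], 0.261)      # net NH3 release
  expect_equal(rx$coefficients[["h2o"]], -0.180)     # water consumed
  bal <- check_balance(rx, tolerance = 0.01)
  expect_true(all(bal$ok))
  n_res <- bal$residual[bal$quantity == "N"]
  cod_res <- bal$residual[bal$quantity == "COD"]
  expect_equal(abs(n_res), 0.0078, tolerance = 0.05)   # ~0.8% N residual
  expect_equal(abs(cod_res), 0.0051, tolerance = 0.05) # ~0.5% COD residual
  # ... which is why 0.5% would be too strict for this reaction
  expect_false(all(check_balance(rx, tolerance = 0.004)$ok))
})

test_that("check_balance flags corrupted stoichiometry", {
  rx <- build_carbohydrate_reaction()
  bad <- rx
  bad$coefficients[["acetate"]] <- bad$coefficients[["acetate"]] + 0.1
  bal <- check_balance(bad, tolerance = 0.01)
  cod_res <- bal$residual[bal$quantity == "COD"]
  expect_equal(cod_res, 0.1 * 8 / 4, tolerance = 1e-6)
  expect_false(bal$ok[bal$quantity == "COD"])
  expect_error(cod_yield_fractions(bad), "not balanced")
  # zero-electron substrate is degenerate
  zero <- rx
  zero$substrate <- parse_formula("CO2")
  expect_error(check_balance(zero), "degenerate")
})

test_that("COD yield fractions follow coefficient x species e-eq / substrate e-eq", {
  fr <- cod_yield_fractions(build_carbohydrate_reaction())
  expect_equal(fr[["biomass"]], 0.21)            # 0.042*20/4
  expect_equal(fr[["acetate"]], 0.412, tolerance = 1e-3)
  expect_equal(fr[["propionate"]], 0.2235, tolerance = 1e-3)
  expect_equal(fr[["n_butyrate"]], 0.1545, tolerance = 1e-3)
  expect_equal(sum(fr), 1)                       # solved reaction: exact

  fp <- cod_yield_fractions(protein_reaction())
  expect_equal(unname(fp[c("biomass", "acetate", "propionate",
                           "iso_butyrate", "aromatics")]),
               c(0.101, 0.402, 0.152, 0.217, 0.134),
               tolerance = 5e-3)
  expect_equal(sum(fp), 1, tolerance = 0.01)     # printed coefficients: ~0.5% off
  expect_equal(sum(cod_yield_fractions(protein_reaction(),
                                       normalize = TRUE)), 1)
})

test_that("solved reactions balance for any feasible yield and ratios", {
  set.seed(103)
  for (i in 1:40) {
    y <- stats::runif(1, 0, 0.19)
    rx <- build_carbohydrate_reaction(
      biomass_yield = y,
      ratios = scfa_ratios(stats::runif(1, 0, 1), stats::runif(1, 0, 1)))
    bal <- check_balance(rx, tolerance = 0.005)
    expect_true(all(bal$ok))
    expect_equal(sum(cod_yield_fractions(rx)), 1)
  }
})

test_that("reactions survive a JSON round trip", {
  rx <- build_carbohydrate_reaction()
  rx2 <- reaction_from_json(reaction_to_json(rx))
  expect_equal(rx2$coefficients, rx$coefficients)
  expect_equal(electron_equivalents(rx2$substrate),
               electron_equivalents(rx$substrate))
})
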