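test_that("chemostat hydrolyzed and absorbed fractions follow k*theta/(1+k*theta)", {
  expect_equal(hydrolyzed_fraction(2.8, 1), 2.8 / 3.8)   # 0.7368
  expect_equal(hydrolyzed_fraction(2.2, 1), 2.2 / 3.2)   # 0.6875
  expect_equal(hydrolyzed_fraction(0, 5), 0)
  expect_equal(fat_absorbed_fraction(0.48, 1), 0.48 / 1.48)
  # monotone, bounded
  k <- seq(0, 100, by = 5)
  f <- hydrolyzed_fraction(k, 1)
  expect_true(all(diff(f) > 0) && all(f < 1))
})

test_that("the fat-rate inversion is the exact inverse of the residual relation", {
  expect_equal(invert_fat_rate(1 / 1.48, 1), 0.48)
  expect_equal(invert_fat_rate(1, 3), 0)
  expect_equal(invert_fat_rate(0.5, 2), 0.5)
  set.seed(105)
  for (i in 1:20) {
    r <- stats::runif(1, 0.05, 1)
    th <- stats::runif(1, 0.3, 3)
    k <- invert_fat_rate(r, th)
    expect_equal(fat_absorbed_fraction(k, th), 1 - r)
  }
  expect_error(invert_fat_rate(0, 1), "\\(0, 1\\]")
  expect_error(invert_fat_rate(1.1, 1), "\\(0, 1\\]")
})

test_that("a resistant-starch-only ICO is routed as hydrolysis then fermentation", {
  cp <- colon_params(k_hyd_rs = 2.8, theta = 1)
  out <- colon_transform(c(rs = 10), cp)
  hyd <- 10 * 2.8 / 3.8                       # 7.368 gCOD/d hydrolyzed
  fr <- cod_yield_fractions(build_carbohydrate_reaction())
  expect_equal(out$feces[["rs"]], 10 - hyd)                 # 2.632
  expect_equal(out$feces[["biomass_carb"]], hyd * fr[["biomass"]]) # 1.547
  expect_equal(out$lga[["acetate"]], 0.95 * hyd * fr[["acetate"]]) # 2.884
  scfa_prod <- hyd * (fr[["acetate"]] + fr[["propionate"]] +
                        fr[["n_butyrate"]])
  fecal_scfa <- sum(out$feces[c("acetate", "propionate", "n_butyrate",
                                "iso_butyrate")])
  expect_equal(fecal_scfa, 0.05 * scfa_prod)                # 0.291
  expect_equal(sum(out$lga) + sum(out$feces), 10)           # conservation
})

test_that("a fat-only ICO splits by the colonic absorption fraction", {
  out <- colon_transform(c(fat = 100), colon_params(k_abs_fat = 0.48,
                                                    theta = 1))
  expect_equal(out$lga[["fat"]], 100 * 0.48 / 1.48)   # 32.43
  expect_equal(out$feces[["fat"]], 100 / 1.48)        # 67.57
})

test_that("degenerate colon inputs behave", {
  cp <- colon_params()
  zero <- colon_transform(numeric(0), cp)
  expect_true(all(zero$lga == 0) && all(zero$feces == 0))
  expect_error(colon_transform(c(rs = -1), cp), "negative")
  expect_error(colon_transform(c(starch = 1), cp), "unknown")
  # all rates zero and no instantly-fermentable pools: feces = ICO
  ico <- c(rs = 5, nsp = 3, protein = 8, fat = 6)
  out <- colon_transform(ico, colon_params(k_hyd_rs = 0, k_hyd_nsp = 0,
                                           k_hyd_protein = 0,
                                           k_abs_fat = 0))
  expect_equal(out$feces[names(ico)], ico)
  expect_true(all(out$lga == 0))
  # zero SCFA absorption: only fat crosses the colon wall
  out2 <- colon_transform(c(avss = 10, fat = 5),
                          colon_params(scfa_absorbed_fraction = 0))
  expect_equal(sum(out2$lga) , out2$lga[["fat"]])
})

test_that("fecal SCFA is the (1-s)/s complement of absorbed SCFA", {
  scfas <- c("acetate", "propionate", "n_butyrate", "iso_butyrate")
  for (s in c(0.5, 0.8, 0.95)) {
    out <- colon_transform(c(avss = 20, protein = 10),
                           colon_params(scfa_absorbed_fraction = s))
    expect_equal(sum(out$feces[scfas]),
                 (1 - s) / s * sum(out$lga[scfas]))
  }
})

test_that("the colon conserves COD for arbitrary inputs and parameters", {
  set.seed(106)
  comps <- gi_components()
  for (i in 1:50) {
    ico <- stats::setNames(stats::runif(length(comps), 0, 50), comps)
    cp <- colon_params(k_hyd_rs = stats::runif(1, 0, 10),
                       k_hyd_nsp = stats::runif(1, 0, 5),
                       k_hyd_protein = stats::runif(1, 0, 10),
                       k_abs_fat = stats::runif(1, 0, 2),
                       theta = stats::runif(1, 0.2, 3),
                       scfa_absorbed_fraction = stats::runif(1))
    out <- colon_transform(ico, cp)
    expect_equal(sum(out$lga) + sum(out$feces), sum(ico),
                 tolerance = 1e-12)
    expect_true(all(out$lga >= 0) && all(out$feces >= 0))
  }
})

test_that("longer transit never decreases colonic energy salvage", {
  ico <- gei_vector(gi_fixtures()$diet)  # treat the whole diet as ICO
  lga <- sapply(seq(0.2, 3, by = 0.2), function(th) {
    sum(colon_transform(ico, colon_params(theta = th))$lga)
  })
  expect_true(all(diff(lga) > 0))
})
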