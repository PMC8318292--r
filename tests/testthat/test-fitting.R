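test_that("the least-squares objective and R-squared behave canonically", {
  expect_equal(chi_squared(c(1, 2), c(1, 2)), 0)
  expect_equal(chi_squared(c(1, 2), c(0, 0)), 5)
  expect_equal(chi_squared(c(1, 2) + 3, c(0, 0) + 3), 5)  # shift invariance
  expect_error(chi_squared(1:3, 1:2), "equal length")
  obs <- c(1, 2, 3, 5)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_lt(r_squared(obs, rev(obs)), 0)                  # worse than mean
  expect_error(r_squared(c(2, 2), c(1, 2)), "zero total variance")
})

test_that("noise-free ileostomy data regenerate the upper-GI parameters", {
  fx <- gi_fixtures()
  truth <- upper_gi_params(
    carbohydrate = list(alpha = 0.90, beta = 1.041, arl = 0.43,
                        secretion_gcod = 3.4),
    protein = list(alpha = 0.90, beta = 1.147, arl = 0.11,
                   secretion_gcod = 5.7),
    fat = list(alpha = 0.96, beta = 0.930, arl = 0, secretion_gcod = 3.1))
  obs <- generate_group_a(truth, fx$diet, study_design(cv = 0))
  fit <- fit_upper_gi(obs, fx$diet)
  for (m in c("carbohydrate", "protein", "fat")) {
    expect_lt(abs(fit$params[[m]]$beta - truth[[m]]$beta), 1e-3)
    expect_lt(abs(fit$params[[m]]$arl - truth[[m]]$arl), 1e-3)
  }
  expect_lt(fit$chi_squared, 1e-6)
  expect_true(all(fit$r_squared > 1 - 1e-9))
  # and a non-default truth, with alpha free
  truth2 <- upper_gi_params(
    carbohydrate = list(alpha = 0.82, beta = 0.8, arl = 0.30,
                        secretion_gcod = 3.4))
  obs2 <- generate_group_a(truth2, fx$diet, study_design(cv = 0))
  fit2 <- fit_upper_gi(obs2, fx$diet, config = list(fix_alpha = FALSE))
  expect_lt(abs(fit2$params$carbohydrate$alpha - 0.82), 1e-3)
  expect_lt(abs(fit2$params$carbohydrate$beta - 0.8), 1e-3)
  expect_lt(abs(fit2$params$carbohydrate$arl - 0.30), 1e-3)
})

test_that("noisy ileostomy data recover the upper-GI parameters approximately", {
  fx <- gi_fixtures()
  obs <- generate_group_a(fx$upper, fx$diet,
                          study_design(cv = 0.05, seed = 1))
  fit <- fit_upper_gi(obs, fx$diet)
  for (m in c("carbohydrate", "protein", "fat")) {
    expect_lt(abs(fit$params[[m]]$beta - fx$upper[[m]]$beta),
              0.1 * fx$upper[[m]]$beta)
    expect_lt(abs(fit$params[[m]]$arl - fx$upper[[m]]$arl), 0.1)
  }
  # the optimum can be no worse than the generating parameters
  expect_lte(fit$chi_squared, local({
    gei <- gei_vector(fx$diet)
    sum((obs$value_kcal_per_day -
           unlist(lapply(c("carbohydrate", "protein", "fat"), function(ch) {
             o <- obs[obs$channel == ch, ]
             colonergy:::.ico_channel_kcal(gei, fx$upper,
                                           o$removed_fraction, ch)
           })))^2)
  }) + 1e-9)
})

test_that("a single-resection-level design is rejected as unidentifiable", {
  fx <- gi_fixtures()
  obs <- generate_group_a(fx$upper, fx$diet,
                          study_design(grid = 0.5, cv = 0))
  expect_error(fit_upper_gi(obs, fx$diet), "not identifiable")
  obs_b <- generate_group_b(fx$upper, fx$colon, fx$diet,
                            study_design(grid = c(0, 0.5), cv = 0))
  expect_error(fit_lower_gi(obs_b, fx$diet, fx$upper), "not identifiable")
})

test_that("noise-free fecal data regenerate the colonic rate constants", {
  fx <- gi_fixtures()
  truth <- colon_params(k_hyd_rs = 2.8, k_hyd_protein = 2.2,
                        k_abs_fat = 0.48, theta = 0.7)
  obs <- generate_group_b(fx$upper, truth, fx$diet, study_design(cv = 0))
  init <- colon_params(k_hyd_rs = 1, k_hyd_protein = 1, k_abs_fat = 1,
                       theta = 0.7)
  fit <- fit_lower_gi(obs, fx$diet, fx$upper, config = list(init = init))
  expect_lt(abs(fit$params$k_hyd_rs - 2.8), 1e-3)
  expect_lt(abs(fit$params$k_hyd_protein - 2.2), 1e-3)
  expect_lt(abs(fit$params$k_abs_fat - 0.48), 1e-3)
  expect_true(all(fit$r_squared > 1 - 1e-9))
})

test_that("only the product k*theta is identifiable from steady-state fractions", {
  fx <- gi_fixtures()
  truth <- colon_params(theta = 0.7)   # fitted rates at theta = 0.7
  obs <- generate_group_b(fx$upper, truth, fx$diet, study_design(cv = 0))
  init <- colon_params(k_hyd_rs = 1, k_hyd_protein = 1, k_abs_fat = 1,
                       theta = 1.4)    # transit time mis-specified 2x
  fit <- fit_lower_gi(obs, fx$diet, fx$upper, config = list(init = init))
  expect_equal(fit$params$k_hyd_rs * 1.4, truth$k_hyd_rs * 0.7,
               tolerance = 1e-3)
  expect_equal(fit$params$k_hyd_protein * 1.4,
               truth$k_hyd_protein * 0.7, tolerance = 1e-3)
  expect_equal(fit$params$k_abs_fat * 1.4, truth$k_abs_fat * 0.7,
               tolerance = 1e-3)
  expect_equal(fit$conditioned_on[["theta"]], 1.4)
})

test_that("a missing protein channel skips stage 2 with a warning", {
  fx <- gi_fixtures()
  obs <- generate_group_b(fx$upper, fx$colon, fx$diet, study_design(cv = 0))
  obs <- obs[obs$channel != "protein", ]
  init <- colon_params(k_hyd_rs = 1, k_hyd_protein = 1.23, k_abs_fat = 1)
  expect_warning(
    fit <- fit_lower_gi(obs, fx$diet, fx$upper, config = list(init = init)),
    "protein")
  expect_equal(fit$params$k_hyd_protein, 1.23)    # untouched
  expect_lt(abs(fit$params$k_abs_fat - 0.48), 1e-3)
  expect_true(fit$fixed[["k_hyd_protein"]])
})
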