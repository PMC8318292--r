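# Compare a computed value with a table cell as printed: agreement within
# 0.1% relative error or within half of the printed last digit, whichever
# is looser (printed cells are independently rounded).
expect_close_printed <- function(value, printed, digits = 0) {
  tol <- max(0.001 * abs(printed), 0.5 * 10^(-digits) + 1e-9)
  expect_lt(abs(value - printed), tol)
}

# random CHON pseudo-formula with at least some carbon
random_formula <- function() {
  elemental_formula(c = stats::runif(1, 0.5, 8),
                    h = stats::runif(1, 0, 12),
                    o = stats::runif(1, 0, 4),
                    n = stats::runif(1, 0, 1))
}

# GEI component vector for a diet, gCOD/d
gei_vector <- function(diet) {
  dt <- diet_to_fluxes(diet)
  gei <- stats::setNames(numeric(length(gi_components())), gi_components())
  gei[dt$component] <- dt$gcod_per_day
  gei
}
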