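#' Packaged reference fixtures
#'
#' The reference configuration the package ships with: the ~2370 kcal/d
#' Western reference diet (50% carbohydrate, 20% protein, 30% fat by gross
#' energy; dietary fiber split equally between resistant starch and NSP),
#' the literature/fitted upper-GI digestibility parameters with their
#' secretion fluxes, the fitted colonic rate constants, and the energy
#' constant tables.
#'
#' @return A list with elements `diet` ([diet_intake()]), `upper`
#'   ([upper_gi_params()]), `colon` ([colon_params()]), and `constants`
#'   ([energy_constants()]).
#' @examples
#' fx <- gi_fixtures()
#' fx$diet$protein        # 83.9 g/d
#' fx$upper$carbohydrate$beta
#' @export
gi_fixtures <- function() {
  list(diet = diet_intake(avss = 266.1, rs = 11.5, nsp = 11.5,
                          protein = 83.9, fat = 76.5),
       upper = upper_gi_params(),
       colon = colon_params(),
       constants = energy_constants())
}

#' Design of a synthetic clinical-style study
#'
#' Describes the observation design the generator emulates: a grid of
#' resection fractions, a per-point subject count drawn uniformly from a
#' range, and mean-zero Gaussian noise on the channel means with standard
#' error `cv * mean / sqrt(n)` — the error structure clinical cohort tables
#' report (a standard error shrinking with subject count).
#'
#' @param grid Resection fractions, each in `[0,1]`. Default spans 0–0.95,
#'   the clinically observed range.
#' @param n_subjects Integer range `c(min, max)` of subjects per grid
#'   point (default 2–15).
#' @param cv Coefficient of variation of a single subject's channel value
#'   (default 0.05); `cv = 0` gives noise-free model output.
#' @param seed Optional integer; fixes the full generated output.
#' @return A list of class `study_design`.
#' @export
study_design <- function(grid = c(0, 0.10, 0.25, 0.35, 0.50, 0.75, 0.95),
                         n_subjects = c(2, 15), cv = 0.05, seed = NULL) {
  if (any(grid < 0 | grid > 1)) {
    stop("grid values must lie in [0, 1]", call. = FALSE)
  }
  if (length(n_subjects) != 2 || any(n_subjects < 1) ||
      n_subjects[1] > n_subjects[2]) {
    stop("n_subjects must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  structure(list(grid = grid, n_subjects = n_subjects, cv = cv,
                 seed = seed), class = "study_design")
}

# run fn with a locally-seeded RNG, leaving the global stream untouched
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  fn()
}

.noisy_rows <- function(means, rf, channel, boundary, design) {
  ns <- seq(design$n_subjects[1], design$n_subjects[2])
  n <- if (length(ns) == 1L) rep(ns, length(means))
       else sample(ns, length(means), replace = TRUE)
  se <- design$cv * means / sqrt(n)
  value <- pmax(0, means + stats::rnorm(length(means), 0, se))
  data.frame(removed_fraction = rf, channel = channel, boundary = boundary,
             value_kcal_per_day = value, standard_error = se,
             n_subjects = n, row.names = NULL)
}

#' Generate an ileostomy-cohort (Group A) observation set
#'
#' Emulates a cohort with total colonic resection: the ileocecal output is
#' observed directly, per macronutrient channel, at each resection fraction
#' of the design. Reported values are the model channel means plus
#' mean-zero Gaussian noise with SE `cv * mean / sqrt(n)`, truncated at 0;
#' fully reproducible from the design's seed.
#'
#' @param true_upper The generating [upper_gi_params()].
#' @param diet A [diet_intake()].
#' @param design A [study_design()].
#' @return Observation data frame (ICO boundary) in the schema
#'   [fit_upper_gi()] consumes.
#' @export
generate_group_a <- function(true_upper, diet, design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  constants <- energy_constants()
  dt <- diet_to_fluxes(diet, constants)
  gei <- stats::setNames(numeric(length(gi_components())), gi_components())
  gei[dt$component] <- dt$gcod_per_day
  .with_seed(design$seed, function() {
    do.call(rbind, lapply(c("carbohydrate", "protein", "fat"),
                          function(ch) {
      means <- .ico_channel_kcal(gei, true_upper, design$grid, ch,
                                 constants)
      .noisy_rows(means, design$grid, ch, "ICO", design)
    }))
  })
}

#' Generate an intact-colon (Group B) observation set
#'
#' Emulates a cohort with the colon intact and varying small-intestine
#' resection: fecal macronutrient channels from the full pipeline,
#' including the 55/45 protein/carbohydrate attribution of fecal microbial
#' biomass. The design grid must stay within the clinically observed 0–0.95
#' range.
#'
#' @param true_upper,true_colon The generating parameter sets.
#' @param diet A [diet_intake()].
#' @param design A [study_design()].
#' @return Observation data frame (FE boundary) in the schema
#'   [fit_lower_gi()] consumes.
#' @export
generate_group_b <- function(true_upper, true_colon, diet,
                             design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  if (any(design$grid > 0.95)) {
    stop("Group B grid is capped at 0.95 removed", call. = FALSE)
  }
  .with_seed(design$seed, function() {
    do.call(rbind, lapply(c("carbohydrate", "protein", "fat"),
                          function(ch) {
      means <- .fe_channel_kcal(diet, true_upper, true_colon, design$grid,
                                ch)
      .noisy_rows(means, design$grid, ch, "FE", design)
    }))
  })
}
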