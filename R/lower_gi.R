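#' Colon (lower-GI) parameters
#'
#' Kinetic and absorption parameters of the single-chemostat colon:
#' first-order hydrolysis constants for the particulate pools, the fat
#' absorption rate, the transit time, and the fraction of colonic SCFAs
#' absorbed by the host.
#'
#' Defaults are the fitted rates `k_hyd_rs = 2.8`/d, `k_hyd_protein =
#' 2.2`/d, `k_abs_fat = 0.48`/d; NSP is inert by default (`k_hyd_nsp = 0`,
#' it persists in stool and no rate has been estimated for it); 95% of
#' SCFAs are absorbed. The transit time `theta` defaults to 0.7 d — no
#' published value accompanies the fitted rates, and only the product
#' `k * theta` is identifiable, so `theta` was calibrated once (within
#' 0.5–3 d, the span of normal-to-fast colonic transit) against the
#' intact-physiology energy-recovery outputs and then frozen; see the
#' package vignette.
#'
#' @param k_hyd_rs,k_hyd_nsp,k_hyd_protein First-order hydrolysis
#'   constants, 1/d.
#' @param k_abs_fat First-order colonic fat absorption constant, 1/d.
#' @param theta Colon transit time, d (> 0).
#' @param scfa_absorbed_fraction Fraction of colonic SCFA absorbed, `[0,1]`.
#' @return A list of class `colon_params`.
#' @export
colon_params <- function(k_hyd_rs = 2.8, k_hyd_nsp = 0,
                         k_hyd_protein = 2.2, k_abs_fat = 0.48,
                         theta = 0.7, scfa_absorbed_fraction = 0.95) {
  rates <- c(k_hyd_rs = k_hyd_rs, k_hyd_nsp = k_hyd_nsp,
             k_hyd_protein = k_hyd_protein, k_abs_fat = k_abs_fat)
  if (any(rates < 0) || any(!is.finite(rates))) {
    stop("rate constants must be finite and >= 0 (1/d)", call. = FALSE)
  }
  if (!is.finite(theta) || theta <= 0) {
    stop("theta (transit time, d) must be > 0", call. = FALSE)
  }
  if (scfa_absorbed_fraction < 0 || scfa_absorbed_fraction > 1) {
    stop("scfa_absorbed_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(k_hyd_rs = k_hyd_rs, k_hyd_nsp = k_hyd_nsp,
                 k_hyd_protein = k_hyd_protein, k_abs_fat = k_abs_fat,
                 theta = theta,
                 scfa_absorbed_fraction = scfa_absorbed_fraction),
            class = "colon_params")
}

#' Fraction of an entering polymer hydrolyzed in the chemostat colon
#'
#' Under first-order kinetics in a well-mixed reactor with residence time
#' `theta`, the surviving particulate fraction is `1/(1 + k*theta)`, so the
#' hydrolyzed fraction is `k*theta / (1 + k*theta)` — in `[0, 1)`, monotone
#' in `k*theta`, saturating at 1.
#'
#' @param k_hyd First-order hydrolysis constant, 1/d (>= 0, vectorized).
#' @param theta Transit time, d (> 0).
#' @return Hydrolyzed fraction in `[0, 1)`.
#' @examples
#' hydrolyzed_fraction(2.8, 1) # 0.7368
#' @export
hydrolyzed_fraction <- function(k_hyd, theta) {
  if (any(k_hyd < 0)) stop("k_hyd must be >= 0", call. = FALSE)
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  kt <- k_hyd * theta
  kt / (1 + kt)
}

#' Fraction of entering fat absorbed by the colon
#'
#' Same chemostat form as hydrolysis: residual fat fraction
#' `1/(1 + k_abs*theta)`, absorbed fraction `k_abs*theta/(1 + k_abs*theta)`.
#'
#' @param k_abs First-order absorption constant, 1/d (>= 0).
#' @param theta Transit time, d (> 0).
#' @return Absorbed fraction in `[0, 1)`.
#' @examples
#' fat_absorbed_fraction(0.48, 1) # 0.3243
#' @export
fat_absorbed_fraction <- function(k_abs, theta) {
  hydrolyzed_fraction(k_abs, theta)
}

#' Invert the colonic fat-residual relation for the rate constant
#'
#' Given an observed residual fraction `r = M_fat / M_fat0` the first-order
#' chemostat relation inverts to `k_abs = (1 - r) / (theta * r)`.
#'
#' @param residual_fraction Residual fat fraction, in `(0, 1]`.
#' @param theta Transit time, d (> 0).
#' @return `k_abs` in 1/d, satisfying
#'   `fat_absorbed_fraction(k_abs, theta) == 1 - residual_fraction`.
#' @examples
#' invert_fat_rate(1 / 1.48, 1) # 0.48
#' @export
invert_fat_rate <- function(residual_fraction, theta) {
  if (any(residual_fraction <= 0 | residual_fraction > 1)) {
    stop("residual_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  (1 - residual_fraction) / (theta * residual_fraction)
}

# reaction-species -> component pool, per substrate family
.carb_product_pool <- c(biomass = "biomass_carb", acetate = "acetate",
                        propionate = "propionate", n_butyrate = "n_butyrate",
                        iso_butyrate = "iso_butyrate",
                        aromatics = "aromatics")
.prot_product_pool <- c(biomass = "biomass_prot", acetate = "acetate",
                        propionate = "propionate", n_butyrate = "n_butyrate",
                        iso_butyrate = "iso_butyrate",
                        aromatics = "aromatics")

# yield fractions sit inside sweep/fitting loops that reuse the same two
# reactions; memoize on the reaction object itself
.yield_fractions_cached <- function(reaction, slot) {
  ent <- .pkg_cache[[paste0("fr_", slot)]]
  if (!is.null(ent) && identical(ent$rx, reaction)) return(ent$fr)
  fr <- cod_yield_fractions(reaction, normalize = TRUE)
  .pkg_cache[[paste0("fr_", slot)]] <- list(rx = reaction, fr = fr)
  fr
}

# the default reactions, built once per session
.default_carb_reaction <- function() {
  if (is.null(.pkg_cache$carb_rx)) {
    .pkg_cache$carb_rx <- build_carbohydrate_reaction()
  }
  .pkg_cache$carb_rx
}
.default_prot_reaction <- function() {
  if (is.null(.pkg_cache$prot_rx)) .pkg_cache$prot_rx <- protein_reaction()
  .pkg_cache$prot_rx
}

#' Colonic transformation of the ileocecal output
#'
#' Routes each ICO component through the colon:
#' * soluble carbohydrate (AvSS) and free amino acids are taken as
#'   immediately fermentable; hydrolysis limits only the particulate pools
#'   (RS, NSP, protein), each contributing its [hydrolyzed_fraction()];
#' * fermentable carbohydrate COD is split among carbohydrate-utilizing
#'   biomass and SCFAs by the carbohydrate reaction's COD yield fractions
#'   (normalized so COD is conserved exactly); hydrolyzed protein likewise
#'   through the protein reaction (biomass, SCFAs incl. iso-butyrate,
#'   aromatics);
#' * SCFAs — produced plus any arriving in the ICO — are absorbed at
#'   `scfa_absorbed_fraction` per acid, the remainder leaving in feces;
#' * fat is absorbed at [fat_absorbed_fraction()];
#' * unhydrolyzed polymers, microbial biomass and aromatics are never
#'   absorbed and leave entirely in feces.
#'
#' Total COD is conserved: `sum(ico) == sum(lga) + sum(feces)` to machine
#' precision.
#'
#' @param ico Named numeric vector over [gi_components()] (missing
#'   components taken as 0), gCOD/d, all >= 0.
#' @param params A [colon_params()] object.
#' @param carb_reaction,prot_reaction `fermentation_reaction`s for the
#'   carbohydrate and protein pools; defaults
#'   [build_carbohydrate_reaction()] and [protein_reaction()].
#' @return List with named vectors `lga` (absorbed by the colon) and
#'   `feces`, gCOD/d.
#' @export
colon_transform <- function(ico, params = colon_params(),
                            carb_reaction = .default_carb_reaction(),
                            prot_reaction = .default_prot_reaction()) {
  stopifnot(inherits(params, "colon_params"))
  comps <- gi_components()
  x <- stats::setNames(numeric(length(comps)), comps)
  unknown <- setdiff(names(ico), comps)
  if (length(unknown)) {
    stop("unknown ICO components: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  x[names(ico)] <- ico
  if (any(x < 0)) {
    stop("negative ICO components: ",
         paste(comps[x < 0], collapse = ", "), call. = FALSE)
  }

  th <- params$theta
  f_rs <- hydrolyzed_fraction(params$k_hyd_rs, th)
  f_nsp <- hydrolyzed_fraction(params$k_hyd_nsp, th)
  f_prot <- hydrolyzed_fraction(params$k_hyd_protein, th)
  f_fat <- fat_absorbed_fraction(params$k_abs_fat, th)

  pool <- stats::setNames(numeric(length(comps)), comps)
  # surviving particulates
  pool["rs"] <- x["rs"] * (1 - f_rs)
  pool["nsp"] <- x["nsp"] * (1 - f_nsp)
  pool["protein"] <- x["protein"] * (1 - f_prot)
  # pass-through pools
  pool["aromatics"] <- x["aromatics"]
  pool["biomass_carb"] <- x["biomass_carb"]
  pool["biomass_prot"] <- x["biomass_prot"]
  scfas <- c("acetate", "propionate", "n_butyrate", "iso_butyrate")
  pool[scfas] <- x[scfas]

  # fermentation, COD-conserving
  ferm_carb <- x["avss"] + x["rs"] * f_rs + x["nsp"] * f_nsp
  if (ferm_carb > 0) {
    fr <- .yield_fractions_cached(carb_reaction, "carb")
    dest <- .carb_product_pool[names(fr)]
    pool[dest] <- pool[dest] + ferm_carb * fr
  }
  ferm_prot <- x["protein"] * f_prot + x["amino_acids"]
  if (ferm_prot > 0) {
    fr <- .yield_fractions_cached(prot_reaction, "prot")
    dest <- .prot_product_pool[names(fr)]
    pool[dest] <- pool[dest] + ferm_prot * fr
  }

  lga <- stats::setNames(numeric(length(comps)), comps)
  lga[scfas] <- pool[scfas] * params$scfa_absorbed_fraction
  lga["fat"] <- x["fat"] * f_fat

  feces <- pool
  feces[scfas] <- pool[scfas] - lga[scfas]
  feces["fat"] <- x["fat"] - lga["fat"]

  list(lga = lga, feces = feces)
}
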