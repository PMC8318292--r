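#' Daily dietary intake in grams of the five macronutrient pools
#'
#' @param avss Available starch and sugars, g/d.
#' @param rs Resistant starch, g/d.
#' @param nsp Non-starch polysaccharides, g/d.
#' @param protein,fat g/d.
#' @param amino_acids Free amino acids, g/d (rarely reported; defaults 0).
#' @return A list of class `diet_intake`.
#' @examples
#' diet_intake(avss = 266.1, rs = 11.5, nsp = 11.5, protein = 83.9,
#'             fat = 76.5) # the packaged reference diet, ~2370 kcal/d gross
#' @export
diet_intake <- function(avss = 0, rs = 0, nsp = 0, protein = 0, fat = 0,
                        amino_acids = 0) {
  x <- list(avss = avss, rs = rs, nsp = nsp, protein = protein, fat = fat,
            amino_acids = amino_acids)
  if (any(!vapply(x, is.numeric, logical(1))) ||
      any(unlist(x) < 0) || any(!is.finite(unlist(x)))) {
    stop("diet intakes must be finite and >= 0 (g/d)", call. = FALSE)
  }
  structure(x, class = "diet_intake")
}

#' Upper-GI absorption parameters
#'
#' One record per macronutrient channel (carbohydrate, protein, fat), each
#' holding the piecewise absorption model's coefficients and the
#' gastrointestinal secretion flux:
#' * `alpha`: true digestibility with intact physiology (fraction of the
#'   absorbable pool taken up);
#' * `beta`: decline in absorption per unit of small intestine removed
#'   beyond the anatomical reserve;
#' * `arl`: anatomical reserve length as a fraction of small-intestine
#'   length — the breakpoint below which resection has no effect;
#' * `secretion_gcod`: gastrointestinal secretions (mucin carbohydrate,
#'   protein, fat) added to the lumen, gCOD/d.
#'
#' The carbohydrate record governs the AvSS pool only: resistant starch and
#' NSP are, by definition, not digested in the small intestine and pass to
#' the colon in full.
#'
#' @param carbohydrate,protein,fat Named lists with entries `alpha`, `beta`,
#'   `arl`, `secretion_gcod`.
#' @return A list of class `upper_gi_params`.
#' @export
upper_gi_params <- function(
    carbohydrate = list(alpha = 0.90, beta = 1.041, arl = 0.43,
                        secretion_gcod = 3.4),
    protein = list(alpha = 0.90, beta = 1.147, arl = 0.11,
                   secretion_gcod = 5.7),
    fat = list(alpha = 0.96, beta = 0.930, arl = 0,
               secretion_gcod = 3.1)) {
  p <- list(carbohydrate = carbohydrate, protein = protein, fat = fat)
  for (m in names(p)) {
    r <- p[[m]]
    need <- c("alpha", "beta", "arl", "secretion_gcod")
    if (!all(need %in% names(r))) {
      stop("upper-GI record for ", m, " must have fields: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (r$alpha < 0 || r$alpha > 1) stop(m, ": alpha must be in [0,1]",
                                         call. = FALSE)
    if (r$beta < 0) stop(m, ": beta must be >= 0", call. = FALSE)
    if (r$arl < 0 || r$arl > 1) stop(m, ": arl must be in [0,1]",
                                     call. = FALSE)
    if (r$secretion_gcod < 0) stop(m, ": secretion must be >= 0",
                                   call. = FALSE)
  }
  structure(p, class = "upper_gi_params")
}

#' Net fractional absorption under partial small-intestine resection
#'
#' The piecewise absorption model: `alpha - beta * max(0, removed - arl)`.
#' Absorption is unchanged while the removed fraction stays within the
#' anatomical reserve, then declines linearly with slope `beta`. The result
#' may be negative, which represents net addition of unreabsorbed
#' secretions to the lumen (observed for protein at high resection).
#'
#' @param params One macronutrient record (list with `alpha`, `beta`,
#'   `arl`), e.g. `upper_gi_params()$protein`.
#' @param removed_fraction Fraction of small intestine removed, in `[0,1]`
#'   (vectorized).
#' @return Net fraction of the pool's gross intake absorbed.
#' @examples
#' absorbed_fraction(upper_gi_params()$carbohydrate, 0.2) # 0.90, within ARL
#' absorbed_fraction(upper_gi_params()$protein, 1.0)      # negative
#' @export
absorbed_fraction <- function(params, removed_fraction) {
  if (any(!is.finite(removed_fraction)) ||
      any(removed_fraction < 0 | removed_fraction > 1)) {
    stop("removed_fraction must lie in [0, 1]", call. = FALSE)
  }
  params$alpha - params$beta * pmax(0, removed_fraction - params$arl)
}

# macronutrient record governing each absorbable component
.absorption_channel <- c(
  avss = "carbohydrate", rs = NA, nsp = NA,
  protein = "protein", amino_acids = "protein", fat = "fat",
  acetate = NA, propionate = NA, n_butyrate = NA, iso_butyrate = NA,
  aromatics = NA, biomass_carb = NA, biomass_prot = NA)

# secretion pool of each macronutrient record
.secretion_pool <- c(carbohydrate = "avss", protein = "protein",
                     fat = "fat")

#' Upper-GI absorption and ileocecal output
#'
#' Applies the piecewise absorption model to the gross-energy-intake (GEI)
#' component vector and adds the gastrointestinal secretions (GIS):
#' `UGA = GEI * absorbed_fraction` for the absorbable pools (AvSS, protein
#' and amino acids, fat; RS and NSP pass through untouched), and
#' `ICO = GEI - UGA + GIS` per component. The identity
#' `GEI + GIS = UGA + ICO` holds to machine precision. UGA may be negative
#' (net secretion); should parameters ever drive an ICO component negative
#' it is floored at zero with a warning (impossible with the default
#' parameter set).
#'
#' @param gei Named numeric vector of gross intake per component
#'   ([gi_components()]), gCOD/d. Missing components are taken as 0.
#' @param params An [upper_gi_params()] object.
#' @param removed_fraction Fraction of small intestine removed, `[0,1]`.
#' @return A list with components `uga`, `ico`, `gis`: named vectors over
#'   [gi_components()], gCOD/d.
#' @export
compute_uga_ico <- function(gei, params, removed_fraction) {
  stopifnot(inherits(params, "upper_gi_params"))
  comps <- gi_components()
  g <- stats::setNames(numeric(length(comps)), comps)
  g[names(gei)] <- gei

  af <- stats::setNames(numeric(length(comps)), comps)
  for (cp in comps) {
    ch <- .absorption_channel[[cp]]
    if (!is.na(ch)) af[cp] <- absorbed_fraction(params[[ch]],
                                                removed_fraction)
  }
  gis <- stats::setNames(numeric(length(comps)), comps)
  for (m in names(.secretion_pool)) {
    gis[.secretion_pool[[m]]] <- params[[m]]$secretion_gcod
  }
  uga <- g * af
  ico <- g - uga + gis
  if (any(ico < 0)) {
    warning("negative ileocecal output floored at 0 for: ",
            paste(comps[ico < 0], collapse = ", "))
    # keep the COD ledger closed: the floored mass is treated as absorbed
    uga[ico < 0] <- uga[ico < 0] + ico[ico < 0]
    ico[ico < 0] <- 0
  }
  list(uga = uga, ico = ico, gis = gis)
}
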