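#' Canonical component pools tracked by the model
#'
#' The 13-component ledger: three carbohydrate pools (available starch +
#' sugars `avss`, resistant starch `rs`, non-starch polysaccharides `nsp`),
#' `protein` and free `amino_acids`, `fat`, the four acids (`acetate`,
#' `propionate`, `n_butyrate`, `iso_butyrate`), `aromatics`, and the two
#' microbial biomass pools (`biomass_carb`, `biomass_prot`).
#'
#' @return Character vector of component names, in canonical order.
#' @export
gi_components <- function() {
  c("avss", "rs", "nsp", "protein", "amino_acids", "fat",
    "acetate", "propionate", "n_butyrate", "iso_butyrate",
    "aromatics", "biomass_carb", "biomass_prot")
}

# component -> energy class used for kcal conversion
.component_class <- c(
  avss = "carbohydrate", rs = "carbohydrate", nsp = "carbohydrate",
  protein = "protein", amino_acids = "protein", fat = "fat",
  acetate = "acetate", propionate = "propionate",
  n_butyrate = "n_butyrate", iso_butyrate = "iso_butyrate",
  aromatics = "aromatics", biomass_carb = "biomass", biomass_prot = "biomass"
)

#' Energy conversion constants
#'
#' The fixed constant tables that tie the COD ledger to calories:
#'
#' * `kcal_per_gcod`: gross energy per gCOD by component class. The
#'   macronutrient and SCFA values are literature constants (3.643
#'   carbohydrate, 4.771 protein, 3.263 fat; 3.266/3.258/3.260 for
#'   acetate/propionate/butyrate, iso-butyrate sharing n-butyrate's value as
#'   its structural isomer). They are stored verbatim rather than derived as
#'   gross-energy/COD because the protein constant is not that ratio
#'   (5.65/1.132 = 4.992, while the published conversion is 4.771); the
#'   carbohydrate and fat constants do coincide with the ratio. Microbial
#'   biomass, which is about 55% protein, is valued at the 55/45
#'   protein/carbohydrate mix; the aromatics value is an assumed 3.3
#'   kcal/gCOD, typical of organics, as no published value exists.
#' * `gross_energy_per_gram`: combustion enthalpies 4.1/5.65/9.3 kcal/g for
#'   carbohydrate/protein/fat.
#' * `atwater_per_gram`: the conventional 4/4/9 kcal/g.
#' * `post_absorption_mei_per_gram`: energy retained by the host per gram
#'   absorbed: 4.1/4.39/9.3 kcal/g. Protein is the only macronutrient whose
#'   post-absorption value differs from its gross value, because reduced
#'   nitrogen leaves in urine.
#'
#' @return A list of class `energy_constants` with the four tables.
#' @export
energy_constants <- function() {
  structure(list(
    kcal_per_gcod = c(
      carbohydrate = 3.643, protein = 4.771, fat = 3.263,
      acetate = 3.266, propionate = 3.258,
      n_butyrate = 3.260, iso_butyrate = 3.260,
      biomass = 0.55 * 4.771 + 0.45 * 3.643,
      aromatics = 3.3
    ),
    gross_energy_per_gram = c(carbohydrate = 4.1, protein = 5.65, fat = 9.3),
    atwater_per_gram = c(carbohydrate = 4, protein = 4, fat = 9),
    post_absorption_mei_per_gram = c(carbohydrate = 4.1, protein = 4.39,
                                     fat = 9.3)
  ), class = "energy_constants")
}

#' Convert a COD flux to kcal/d
#'
#' @param flux Flux in gCOD/d (vectorized).
#' @param component_class One of the classes named in
#'   `energy_constants()$kcal_per_gcod` (e.g. `"carbohydrate"`,
#'   `"acetate"`), or a model component name from [gi_components()], which
#'   is mapped to its class.
#' @param constants An `energy_constants` object.
#' @return Flux in kcal/d.
#' @examples
#' convert_cod_to_kcal(3.4, "carbohydrate") # mucin secretion, ~12.4 kcal/d
#' @export
convert_cod_to_kcal <- function(flux, component_class,
                                constants = energy_constants()) {
  cls <- component_class
  if (cls %in% names(.component_class)) cls <- .component_class[[cls]]
  k <- constants$kcal_per_gcod
  if (!cls %in% names(k)) {
    stop("no kcal/gCOD conversion constant for component class '",
         component_class, "'", call. = FALSE)
  }
  flux * k[[cls]]
}

# Exact kcal/gCOD used for metabolizable energy of absorbed material:
# macronutrients at their post-absorption kcal/g divided by their COD
# content; SCFAs at their gross constants (no urinary correction applies).
.mei_kcal_per_gcod <- function(constants = energy_constants()) {
  ent <- .pkg_cache$mei_k
  if (!is.null(ent) && identical(ent$constants, constants)) return(ent$v)
  v <- .mei_kcal_per_gcod_build(constants)
  .pkg_cache$mei_k <- list(constants = constants, v = v)
  v
}

.mei_kcal_per_gcod_build <- function(constants) {
  post <- constants$post_absorption_mei_per_gram
  cods <- c(carbohydrate = cod_per_gram(species_formulas("carbohydrate")),
            protein = cod_per_gram(species_formulas("protein")),
            fat = cod_per_gram(species_formulas("fat")))
  k <- constants$kcal_per_gcod
  c(avss = post[["carbohydrate"]] / cods[["carbohydrate"]],
    rs   = post[["carbohydrate"]] / cods[["carbohydrate"]],
    nsp  = post[["carbohydrate"]] / cods[["carbohydrate"]],
    protein = post[["protein"]] / cods[["protein"]],
    amino_acids = post[["protein"]] / cods[["protein"]],
    fat = post[["fat"]] / cods[["fat"]],
    acetate = k[["acetate"]], propionate = k[["propionate"]],
    n_butyrate = k[["n_butyrate"]], iso_butyrate = k[["iso_butyrate"]],
    aromatics = k[["aromatics"]], biomass_carb = k[["biomass"]],
    biomass_prot = k[["biomass"]])
}

# gross kcal/gCOD per component, used for display and fecal-energy totals
.gross_kcal_per_gcod <- function(constants = energy_constants()) {
  ent <- .pkg_cache$gross_k
  if (!is.null(ent) && identical(ent$constants, constants)) return(ent$v)
  k <- constants$kcal_per_gcod
  v <- vapply(gi_components(), function(cp) k[[.component_class[[cp]]]],
              numeric(1))
  .pkg_cache$gross_k <- list(constants = constants, v = v)
  v
}
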