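#' Fermentation reaction on a per-carbon-mole substrate basis
#'
#' A `fermentation_reaction` couples one C-normalized substrate formula to
#' signed stoichiometric coefficients over the canonical product species
#' (`biomass`, `acetate`, `propionate`, `n_butyrate`, `iso_butyrate`,
#' `aromatics`, `nh3`, `co2`, `h2o`). Products are positive; species
#' consumed alongside the substrate (e.g. NH3 for biomass synthesis, or
#' water) are negative. There is no external electron acceptor: a valid
#' anaerobic reaction conserves the substrate's electron equivalents across
#' its products.
#'
#' @name fermentation_reaction
NULL

.reaction_species <- c("biomass", "acetate", "propionate", "n_butyrate",
                       "iso_butyrate", "aromatics", "nh3", "co2", "h2o")

new_reaction <- function(substrate, coefficients) {
  substrate <- parse_formula(substrate)
  stopifnot(is.numeric(coefficients))
  coef <- stats::setNames(numeric(length(.reaction_species)),
                          .reaction_species)
  unknown <- setdiff(names(coefficients), .reaction_species)
  if (length(unknown)) {
    stop("unknown reaction species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  coef[names(coefficients)] <- coefficients
  structure(list(substrate = substrate, coefficients = coef),
            class = "fermentation_reaction")
}

#' @export
print.fermentation_reaction <- function(x, ...) {
  cat("<fermentation reaction>\n  substrate:", format_formula(x$substrate),
      "\n")
  nz <- x$coefficients[x$coefficients != 0]
  for (sp in names(nz)) {
    cat(sprintf("  %+8.4f %s\n", nz[[sp]], sp))
  }
  invisible(x)
}

#' Molar SCFA product ratios
#'
#' Propionate and n-butyrate yields expressed relative to acetate. The model
#' default is the typical human-fecal ratio 1 Ac : 0.31 Prop : 0.15 n-But.
#'
#' @param prop_to_ac,but_to_ac Molar ratios (>= 0).
#' @return A list of class `scfa_ratios`.
#' @export
scfa_ratios <- function(prop_to_ac = 0.31, but_to_ac = 0.15) {
  if (prop_to_ac < 0 || but_to_ac < 0) {
    stop("SCFA ratios must be >= 0", call. = FALSE)
  }
  structure(list(prop_to_ac = prop_to_ac, but_to_ac = but_to_ac),
            class = "scfa_ratios")
}

#' Solve the carbohydrate fermentation stoichiometry
#'
#' Builds the anaerobic carbohydrate reaction from conservation constraints
#' rather than hard-coded coefficients: with the biomass yield fixed and the
#' propionate:acetate and butyrate:acetate molar ratios imposed, the acetate
#' coefficient is the unique solution of the electron-equivalent (COD)
#' balance; CO2 then follows from the carbon balance, NH3 from nitrogen, and
#' H2O from oxygen (the hydrogen balance is left as a redundant check). With
#' the default yield 0.042 mol biomass/C-mol and ratios 1:0.31:0.15 this
#' reproduces the published carbohydrate stoichiometry to +-0.001.
#'
#' @param substrate Substrate formula (C-mole basis). Default: model
#'   carbohydrate `CH1.826O0.913`.
#' @param biomass_yield Mol biomass (C5H7O2N) per C-mol substrate, in
#'   `[0, substrate C / 5]`.
#' @param ratios An [scfa_ratios()] object.
#' @return A `fermentation_reaction`.
#' @examples
#' build_carbohydrate_reaction() # acetate 0.206, propionate 0.064, ...
#' @export
build_carbohydrate_reaction <- function(substrate = species_formulas("carbohydrate"),
                                        biomass_yield = 0.042,
                                        ratios = scfa_ratios()) {
  s <- parse_formula(substrate)
  stopifnot(inherits(ratios, "scfa_ratios"))
  if (biomass_yield < 0 || biomass_yield > s$c / 5) {
    stop("biomass_yield must lie in [0, substrate C/5] = [0, ",
         format(s$c / 5), "]", call. = FALSE)
  }
  e_s <- electron_equivalents(s)
  e_b <- electron_equivalents(species_formulas("biomass"))       # 20
  e_ac <- electron_equivalents(species_formulas("acetate"))      # 8
  e_pr <- electron_equivalents(species_formulas("propionate"))   # 14
  e_bu <- electron_equivalents(species_formulas("n_butyrate"))   # 20

  # electron balance: e_s = y*e_b + ac*(e_ac + rp*e_pr + rb*e_bu)
  e_per_ac <- e_ac + ratios$prop_to_ac * e_pr + ratios$but_to_ac * e_bu
  acetate <- (e_s - biomass_yield * e_b) / e_per_ac
  tol <- 1e-9
  if (acetate < -tol) {
    stop("infeasible electron balance: fixed biomass yield carries more ",
         "electron equivalents than the substrate supplies ",
         "(acetate coefficient ", format(acetate, digits = 4), ")",
         call. = FALSE)
  }
  acetate <- max(acetate, 0)
  propionate <- ratios$prop_to_ac * acetate
  butyrate <- ratios$but_to_ac * acetate

  co2 <- s$c - 5 * biomass_yield - 2 * acetate - 3 * propionate -
    4 * butyrate
  if (co2 < -0.01 * s$c) {
    stop("infeasible carbon balance: products carry more carbon than the ",
         "substrate supplies (CO2 coefficient ", format(co2, digits = 4),
         ")", call. = FALSE)
  }
  nh3 <- s$n - biomass_yield                 # negative: NH3 consumed
  h2o <- s$o - (2 * biomass_yield + 2 * acetate + 2 * propionate +
                  2 * butyrate + 2 * co2)
  new_reaction(s, c(biomass = biomass_yield, acetate = acetate,
                    propionate = propionate, n_butyrate = butyrate,
                    nh3 = nh3, co2 = co2, h2o = h2o))
}

#' The fixed protein fermentation stoichiometry
#'
#' Protein fermentation is carried as published constants rather than solved
#' from a yield/ratio recipe, because its branched-chain acid and aromatics
#' yields are empirical: per C-mol protein (CH2.063O0.626N0.282), 0.020
#' biomass, 0.199 acetate, 0.043 propionate, 0.043 iso-butyrate, 0.016
#' aromatics (C7.25H7.2O1.2N0.2), 0.091 CO2, releasing 0.261 NH3 and
#' consuming 0.180 H2O. The printed coefficients close the nitrogen balance
#' only to ~0.8% and the COD balance to ~0.5%, which motivates the 1%
#' default validation tolerance used throughout.
#'
#' @return A `fermentation_reaction`.
#' @export
protein_reaction <- function() {
  new_reaction(species_formulas("protein"),
               c(biomass = 0.020, nh3 = 0.261, acetate = 0.199,
                 propionate = 0.043, iso_butyrate = 0.043,
                 aromatics = 0.016, co2 = 0.091, h2o = -0.180))
}

#' Element and COD balance residuals of a reaction
#'
#' Checks conservation of C, H, O, N and of electron equivalents (COD)
#' between the substrate side (substrate plus negatively-signed
#' co-reactants) and the product side. Residuals are reported as fractions
#' of the substrate-side quantity.
#'
#' @param reaction A `fermentation_reaction`.
#' @param tolerance Flagging threshold as a fraction (> 0); default 1%.
#' @return A data frame with columns `quantity` (`C`,`H`,`O`,`N`,`COD`),
#'   `residual` (signed fraction), and `ok` (`|residual| <= tolerance`).
#' @export
check_balance <- function(reaction, tolerance = 0.01) {
  stopifnot(inherits(reaction, "fermentation_reaction"), tolerance > 0)
  sp <- species_formulas()
  s <- reaction$substrate
  atoms <- function(f) c(C = f$c, H = f$h, O = f$o, N = f$n)
  s_atoms <- atoms(s)
  e_s <- electron_equivalents(s)
  if (e_s <= 0) {
    stop("degenerate reaction: substrate carries no electron equivalents",
         call. = FALSE)
  }
  net <- -s_atoms
  reactant_side <- s_atoms
  e_net <- -e_s
  for (name in names(reaction$coefficients)) {
    cf <- reaction$coefficients[[name]]
    if (cf == 0) next
    a <- atoms(sp[[name]])
    net <- net + cf * a
    if (cf < 0) reactant_side <- reactant_side + abs(cf) * a
    e_net <- e_net + cf * electron_equivalents(sp[[name]])
  }
  denom <- pmax(reactant_side, .Machine$double.eps)
  res <- c(net / denom, COD = e_net / e_s)
  data.frame(quantity = c("C", "H", "O", "N", "COD"),
             residual = unname(res),
             ok = abs(unname(res)) <= tolerance,
             row.names = NULL)
}

#' Fraction of substrate COD routed to each product species
#'
#' For a balanced reaction, each electron-carrying product receives the COD
#' fraction `coefficient * species e-eq / substrate e-eq`. CO2, H2O and NH3
#' carry zero electron equivalents and receive nothing. The fractions sum to
#' 1 within the reaction's balance residual; `normalize = TRUE` rescales
#' them to sum to exactly 1, which is how the colon model applies them so
#' that COD is conserved to machine precision.
#'
#' @param reaction A `fermentation_reaction`.
#' @param tolerance Balance tolerance the reaction must satisfy (default 1%).
#' @param normalize Rescale fractions to sum to exactly 1 (default `FALSE`).
#' @return Named numeric vector of COD fractions over the electron-carrying
#'   product species.
#' @examples
#' cod_yield_fractions(build_carbohydrate_reaction())
#' @export
cod_yield_fractions <- function(reaction, tolerance = 0.01,
                                normalize = FALSE) {
  bal <- check_balance(reaction, tolerance)
  if (!all(bal$ok)) {
    bad <- bal$quantity[!bal$ok]
    stop("reaction is not balanced within ", tolerance * 100, "%: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sp <- species_formulas()
  e_s <- electron_equivalents(reaction$substrate)
  cf <- reaction$coefficients
  frac <- vapply(names(cf), function(name) {
    if (cf[[name]] <= 0) return(0)
    cf[[name]] * electron_equivalents(sp[[name]]) / e_s
  }, numeric(1))
  frac <- frac[frac > 0]
  if (normalize) frac <- frac / sum(frac)
  frac
}

#' Serialize a reaction to JSON (and back)
#'
#' @param reaction A `fermentation_reaction`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `reaction_to_json()`: JSON string or (invisibly) `path`;
#'   `reaction_from_json()`: a `fermentation_reaction`.
#' @export
reaction_to_json <- function(reaction, path = NULL) {
  stopifnot(inherits(reaction, "fermentation_reaction"))
  x <- list(substrate = format_formula(reaction$substrate),
            coefficients = as.list(
              reaction$coefficients[reaction$coefficients != 0]))
  if (is.null(path)) {
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname reaction_to_json
#' @param json JSON string or file path produced by [reaction_to_json()].
#' @export
reaction_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  new_reaction(x$substrate, unlist(x$coefficients))
}
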