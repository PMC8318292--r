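#' Elemental (pseudo-)formula of an organic substance
#'
#' The model does all of its mass accounting in chemical oxygen demand (COD),
#' which is fixed entirely by a substance's CHON composition. Fractional
#' coefficients are the norm: bulk macronutrients are carried as carbon-
#' normalized pseudo-formulas such as `CH1.826O0.913` (carbohydrate).
#'
#' @param c,h,o,n Atoms per formula unit. All must be non-negative and at
#'   least one positive; fractional values are allowed.
#' @return An object of class `elemental_formula`.
#' @examples
#' elemental_formula(c = 1, h = 1.826, o = 0.913) # model carbohydrate
#' parse_formula("C5H7O2N")                       # microbial biomass
#' @seealso [parse_formula()], [electron_equivalents()], [cod_per_gram()]
#' @export
elemental_formula <- function(c = 0, h = 0, o = 0, n = 0) {
  coef <- c(c = as.numeric(c), h = as.numeric(h),
            o = as.numeric(o), n = as.numeric(n))
  if (any(!is.finite(coef)) || any(coef < 0)) {
    stop("formula coefficients must be finite and >= 0", call. = FALSE)
  }
  if (all(coef == 0)) {
    stop("at least one formula coefficient must be > 0", call. = FALSE)
  }
  structure(as.list(coef), class = "elemental_formula")
}

#' Parse a formula literal such as "CH1.826O0.913"
#'
#' Accepts the compact dialect used throughout the nutrition/COD literature:
#' element symbols C, H, O, N (case-sensitive), each optionally followed by a
#' decimal coefficient (implicit 1 when absent), e.g. `"C2H4O2"`, `"C5H7O2N"`,
#' `"C7.25H7.2O1.2N0.2"`.
#'
#' @param x A single formula string, or an `elemental_formula` (returned
#'   unchanged).
#' @return An `elemental_formula`.
#' @export
parse_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop("expected a single formula string", call. = FALSE)
  }
  m <- gregexpr("([CHON])([0-9]*\\.?[0-9]*)", x, perl = TRUE)[[1]]
  pieces <- regmatches(x, gregexpr("([CHON])([0-9]*\\.?[0-9]*)", x, perl = TRUE))[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula string: ", x, call. = FALSE)
  }
  coef <- c(C = 0, H = 0, O = 0, N = 0)
  for (p in pieces) {
    el <- substr(p, 1, 1)
    num <- substr(p, 2, nchar(p))
    coef[el] <- coef[el] + if (nzchar(num)) as.numeric(num) else 1
  }
  elemental_formula(c = coef[["C"]], h = coef[["H"]],
                    o = coef[["O"]], n = coef[["N"]])
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), "\n")
  invisible(x)
}

format_formula <- function(f) {
  fmt1 <- function(sym, v) {
    if (v == 0) return("")
    if (v == 1) return(sym)
    paste0(sym, format(v, trim = TRUE, scientific = FALSE))
  }
  paste0(fmt1("C", f$c), fmt1("H", f$h), fmt1("O", f$o), fmt1("N", f$n))
}

#' Electron equivalents transferred on complete oxidation
#'
#' Moles of electrons released when one formula unit is fully oxidized to
#' CO2 (and, for nitrogen, NH3/NH4+ at the -III state):
#' `4*C + H - 2*O - 3*N`. One electron equivalent corresponds to 8 g COD,
#' because one mole of O2 (32 g) accepts 4 moles of electrons.
#'
#' @param formula An `elemental_formula` or formula string.
#' @return Electron equivalents per formula unit (may be 0 for fully
#'   oxidized species such as CO2 or H2O).
#' @examples
#' electron_equivalents("CH1.826O0.913") # 4: model carbohydrate
#' electron_equivalents("C5H7O2N")       # 20: microbial biomass
#' @export
electron_equivalents <- function(formula) {
  f <- parse_formula(formula)
  4 * f$c + f$h - 2 * f$o - 3 * f$n
}

# Integer atomic masses: the COD constant table of the source literature is
# built on C=12, H=1, O=16, N=14 (e.g. carbohydrate formula weight 28.434 g,
# fat COD 2.850 gCOD/g); IUPAC masses would give 2.845 for fat. Fixed, not
# configurable.
.atomic_mass <- c(c = 12, h = 1, o = 16, n = 14)

#' Formula weight in grams per formula unit
#'
#' Uses integer atomic masses (C=12, H=1, O=16, N=14), the convention under
#' which the model's published COD constants are exact.
#'
#' @inheritParams electron_equivalents
#' @return Grams per formula unit.
#' @examples
#' formula_weight("CH1.826O0.913") # 28.434
#' @export
formula_weight <- function(formula) {
  f <- parse_formula(formula)
  sum(.atomic_mass * c(f$c, f$h, f$o, f$n))
}

#' COD content of a substance, gCOD per gram
#'
#' `8 * electron_equivalents / formula_weight`: the grams of O2 needed to
#' fully oxidize one gram of the substance.
#'
#' @inheritParams electron_equivalents
#' @return gCOD per g (0 only for zero-electron species).
#' @examples
#' cod_per_gram("CH1.826O0.913") # 1.125 gCOD/g carbohydrate
#' cod_per_gram("C2H4O2")        # 1.067 gCOD/g acetic acid (prints as 1.066)
#' @export
cod_per_gram <- function(formula) {
  f <- parse_formula(formula)
  8 * electron_equivalents(f) / formula_weight(f)
}

#' Canonical pseudo-formulas used by the model
#'
#' Named set covering the three macronutrients, the SCFAs, microbial biomass,
#' the aromatic protein-fermentation products, and the small inorganics the
#' reactions exchange.
#'
#' @param name Optional species name; when given, returns that single
#'   `elemental_formula`.
#' @return A named list of `elemental_formula` objects, or one formula.
#' @export
species_formulas <- function(name = NULL) {
  tab <- .pkg_cache$species
  if (is.null(tab)) {
    tab <- .build_species_tab()
    .pkg_cache$species <- tab
  }
  if (is.null(name)) return(tab)
  if (!name %in% names(tab)) stop("unknown species: ", name, call. = FALSE)
  tab[[name]]
}

# parsing is regex-based and species_formulas sits on the hot path of the
# colon model, so the table is built once per session
.pkg_cache <- new.env(parent = emptyenv())

.build_species_tab <- function() {
  list(
    carbohydrate = parse_formula("CH1.826O0.913"),
    protein      = parse_formula("CH2.063O0.626N0.282"),
    fat          = parse_formula("CH1.838O0.118"),
    biomass      = parse_formula("C5H7O2N"),
    acetate      = parse_formula("C2H4O2"),
    propionate   = parse_formula("C3H6O2"),
    n_butyrate   = parse_formula("C4H8O2"),
    iso_butyrate = parse_formula("C4H8O2"),
    aromatics    = parse_formula("C7.25H7.2O1.2N0.2"),
    nh3          = parse_formula("NH3"),
    co2          = parse_formula("CO2"),
    h2o          = parse_formula("H2O")
  )
}
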