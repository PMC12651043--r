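# IUPAC 2021 conventional atomic weights (g/mol) for the elements that
# occur in small-molecule drugs and buffers handled here.
ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, Cl = 35.45, Na = 22.990, K = 39.098, Fe = 55.845,
  Mg = 24.305, Ca = 40.078
)

parse_formula <- function(formula) {
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula))
    stop("cannot parse chemical formula '", formula, "'", call. = FALSE)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]+$", "", tokens)
  n <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                         sub("^[A-Za-z]+", "", tokens), "1"))
  tapply(n, el, sum)
}

#' Molar mass of a chemical formula
#'
#' Formula mass from embedded IUPAC 2021 conventional atomic weights.
#' An optional adduct (e.g. the hydrochloride salt `"HCl"`) is added to
#' the parent formula, as in minocycline hydrochloride
#' C23H27N3O7·HCl (493.94 g/mol).
#'
#' @param formula Hill-notation formula string, e.g. `"C23H27N3O7"`.
#' @param adduct optional adduct formula string, e.g. `"HCl"`.
#' @return Molar mass in g/mol (unrounded; round only for display).
#' @examples
#' round(molar_mass("C23H27N3O7", adduct = "HCl"), 2)  # 493.94
#' round(molar_mass("H2O"), 2)                         # 18.02
#' @export
molar_mass <- function(formula, adduct = NULL) {
  counts <- parse_formula(formula)
  if (!is.null(adduct)) {
    ad <- parse_formula(adduct)
    for (el in names(ad))
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + ad[[el]]
  }
  unknown <- setdiff(names(counts), names(ATOMIC_WEIGHTS))
  if (length(unknown) > 0)
    stop("no atomic weight for element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sum(counts * ATOMIC_WEIGHTS[names(counts)])
}

#' Molar concentration from a dissolved dose
#'
#' `mass / (molar mass x volume)`. For example, a 200 mg dose
#' distributed over 5 L gives 8.1e-5 mol/L for minocycline
#' hydrochloride (Mr 493.94) -- an assumed dose/volume pairing, stated
#' here only as arithmetic.
#'
#' @param mass_g dissolved mass in grams.
#' @param volume_l solution volume in litres.
#' @param mr molar mass in g/mol.
#' @return Concentration in mol/L.
#' @examples
#' molarity_from_dose(0.2, 5, 493.94)  # 8.10e-05
#' @export
molarity_from_dose <- function(mass_g, volume_l, mr) {
  if (any(!is.finite(c(mass_g, volume_l, mr))) ||
      mass_g <= 0 || volume_l <= 0 || mr <= 0)
    stop("mass, volume and molar mass must all be positive", call. = FALSE)
  mass_g / mr / volume_l
}
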