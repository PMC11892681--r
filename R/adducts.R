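# Accurate-mass arithmetic: elemental monoisotopic masses, molecular-formula
# parsing, adduct m/z and ppm errors. These underpin both metabolite
# annotation and drug-ion identification.

# CODATA/IUPAC monoisotopic masses of the most abundant isotope (Da).
.MONOISOTOPIC <- c(
  C = 12.0,          H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151,   S = 31.97207069,  Cl = 34.96885271,  Na = 22.98976928,
  K = 38.9637064864, F = 18.9984031627, Br = 78.9183376,  I = 126.904473,
  Se = 79.9165218,   Fe = 55.9349375,  Si = 27.9769265
)

# Electron-corrected mass shifts for singly charged adducts (Da).
# [M+H]+ = M + m(H) - m(e); [M-H]- = M - m(H) + m(e); etc.
.ADDUCT_DELTA <- c(
  "[M+H]+"  =  1.007276,
  "[M+Na]+" = 22.989218,
  "[M+K]+"  = 38.963158,
  "[M-H]-"  = -1.007276,
  "[M+Cl]-" = 34.969402
)

#' Known adduct names
#' @return character vector of supported adduct labels
#' @export
known_adducts <- function() names(.ADDUCT_DELTA)

#' Default adducts per polarity
#'
#' Positive mode carries protonated, sodiated and potassiated species
#' (electrospray convention); negative mode deprotonated and chloridated
#' species (MALDI 9-AA convention).
#' @param polarity "positive" or "negative"
#' @return character vector of adduct labels
#' @export
default_adducts <- function(polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (polarity == "positive") c("[M+H]+", "[M+Na]+", "[M+K]+")
  else c("[M-H]-", "[M+Cl]-")
}

#' Monoisotopic mass of a molecular formula
#'
#' Parses formulae such as "C25H30N6O3" (element symbols followed by optional
#' counts; no parentheses or charges) and sums monoisotopic element masses.
#'
#' @param formula character vector of molecular formulae
#' @return numeric vector of monoisotopic neutral masses (Da)
#' @examples
#' formula_mass("C25H30N6O3")  # AZD2014 neutral mass, 462.2379 Da
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    f <- gsub("[[:space:]]", "", f)
    if (!nzchar(f)) stopf("empty molecular formula")
    parts <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (sum(nchar(parts)) != nchar(f))
      stopf("cannot parse molecular formula '%s'", f)
    total <- 0
    for (p in parts) {
      el <- sub("[0-9]*$", "", p)
      nc <- sub("^[A-Za-z]+", "", p)
      n <- if (nzchar(nc)) as.numeric(nc) else 1
      if (!el %in% names(.MONOISOTOPIC))
        stopf("unknown element '%s' in formula '%s'", el, f)
      total <- total + .MONOISOTOPIC[[el]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Theoretical adduct m/z
#'
#' @param neutral_mass monoisotopic neutral mass (Da)
#' @param adduct adduct label, one of [known_adducts()]
#' @return theoretical m/z (Da), vectorised over `neutral_mass`
#' @examples
#' adduct_mz(462.2379, "[M+H]+")  # 463.2452
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (any(neutral_mass <= 0)) stopf("neutral_mass must be > 0")
  if (length(adduct) != 1L || !adduct %in% names(.ADDUCT_DELTA))
    stopf("unknown adduct '%s' (supported: %s)",
          paste(adduct, collapse = ","), paste(known_adducts(), collapse = ", "))
  neutral_mass + .ADDUCT_DELTA[[adduct]]
}

#' Relative mass error in parts per million
#'
#' ppm = (observed - theoretical) / theoretical * 1e6.
#' @param observed observed m/z
#' @param theoretical theoretical m/z
#' @return signed ppm error
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
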