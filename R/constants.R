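#' Physical constants used by the package (CODATA 2018)
#'
#' Fixed module-level constants used by the quasi-harmonic entropy and ITC
#' thermodynamics code. All values are CODATA 2018; they are echoed into run
#' reports for auditability.
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K.}
#'   \item{hbar}{Reduced Planck constant, J s.}
#'   \item{amu}{Atomic mass unit, kg.}
#'   \item{NA_avogadro}{Avogadro constant, 1/mol.}
#'   \item{R_J}{Molar gas constant, J/(mol K).}
#'   \item{R_cal}{Molar gas constant, cal/(mol K).}
#'   \item{R_kcal}{Molar gas constant, kcal/(mol K).}
#' }
#' @export
baf_constants <- list(
  kB          = 1.380649e-23,
  hbar        = 1.054571817e-34,
  amu         = 1.66053906660e-27,
  NA_avogadro = 6.02214076e23,
  R_J         = 8.31446261815324,
  R_cal       = 8.31446261815324 / 4.184,
  R_kcal      = 8.31446261815324 / 4184
)

# Standard atomic masses (amu) for the elements that occur in protein
# structures; unknown elements fall back to 12.0 with a warning (mass only
# matters for the quasi-harmonic entropy).
.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38,
  MG = 24.305, CA = 40.078, "NA" = 22.990, K = 39.098, CL = 35.45
)

#' Atomic mass lookup
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of masses in amu. Unknown elements map to 12.0
#'   with a warning.
#' @export
element_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .element_masses[key]
  unknown <- is.na(m)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(key[unknown]), collapse = ", "),
            "; assigning mass 12.0 amu", call. = FALSE)
    m[unknown] <- 12.0
  }
  unname(m)
}
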