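#' Load the force-field parameter set
#'
#' All model constants live in one versioned JSON file shipped with the
#' package (`inst/extdata/ff_params.json`); tests read them from here
#' rather than hard-coding values.
#'
#' @param file optional path to an alternative parameter file.
#' @return nested list of parameters (class `ff_params`).
#' @export
ff_params <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "ff_params.json", package = "cgsearch")
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  class(p) <- "ff_params"
  p
}

#' Debye screening length
#'
#' `lambda_D = 1 / sqrt(8 pi l_B N_A I)` with Bjerrum length
#' `l_B = e^2 / (4 pi eps0 eps_r kB T)` evaluated at the given temperature
#' and relative dielectric; `I` is the monovalent ionic strength (= salt
#' molarity).
#'
#' @param Cs salt concentration in mM (monovalent), > 0.
#' @param T temperature in K.
#' @param dielectric relative dielectric constant.
#' @return Debye length in Angstrom.
#' @examples
#' debye_length(20)   # ~21.5 A at 300 K
#' @export
debye_length <- function(Cs, T = 300, dielectric = 78) {
  if (any(Cs <= 0)) stop("Cs must be > 0 (disable screening explicitly, not via Cs = 0)")
  # physical constants (SI)
  e <- 1.602176634e-19; eps0 <- 8.8541878128e-12
  kB <- 1.380649e-23; NA_ <- 6.02214076e23
  lB <- e^2 / (4 * pi * eps0 * dielectric * kB * T)          # meters
  I <- Cs * 1e-3 * 1e3 * NA_                                 # ions / m^3
  lam <- 1 / sqrt(8 * pi * lB * I)                           # meters
  lam * 1e10
}

#' Screened Coulomb (Debye-Huckel) pair energy
#'
#' `U = k_C q_i q_j exp(-r / lambda_D) / (eps_r r)`, in kcal/mol for
#' charges in units of e and r in Angstrom.
#'
#' @param qi,qj charges (e).
#' @param r separation (A), > 0.
#' @param eparams list with `lambda` (A), `kpref` (= coulomb_k /
#'   dielectric, kcal mol^-1 A e^-2); see [electrostatics_params()].
#' @return energy in kcal/mol (vectorized over `r`).
#' @export
screened_coulomb <- function(qi, qj, r, eparams) {
  if (any(r <= 0)) stop("r must be > 0")
  eparams$kpref * qi * qj * exp(-r / eparams$lambda) / r
}

#' Electrostatics parameter bundle
#'
#' @param Cs salt (mM).
#' @param T temperature (K).
#' @param params force-field parameter set ([ff_params()]).
#' @return list: `Cs`, `T`, `dielectric`, `lambda` (Debye length, A),
#'   `kpref` (kcal mol^-1 A), `cutoff` (= 5 lambda by default).
#' @export
electrostatics_params <- function(Cs, T = 300, params = ff_params()) {
  el <- params$electrostatics
  lam <- debye_length(Cs, T = T, dielectric = el$dielectric)
  list(Cs = Cs, T = T, dielectric = el$dielectric, lambda = lam,
       kpref = el$coulomb_k / el$dielectric,
       cutoff = el$cutoff_lambda_mult * lam)
}
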