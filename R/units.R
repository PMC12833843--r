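# Internal unit system: Angstrom, picosecond, amu, Kelvin.
# Diffusion coefficients cross the API boundary in 1e-9 m^2/s.

.kB <- 1.380649e-23          # J/K, SI exact
.N_AVOGADRO <- 6.02214076e23 # 1/mol, SI exact

# 1 A^2/ps = 1e-20 m^2 / 1e-12 s = 1e-8 m^2/s = 100 x 1e-9 m^2/s
.A2PS_PER_1E9M2S <- 100

#' Convert a diffusion coefficient between internal and reported units
#'
#' Internally mean-squared displacements are accumulated in \eqn{\AA^2}
#' against lag times in ps, so fitted slopes carry \eqn{\AA^2/ps}. All
#' user-facing diffusion coefficients are expressed in \eqn{10^{-9}} m\eqn{^2}/s,
#' the unit in which solution diffusion coefficients of small solutes are
#' conventionally tabulated. The conversion factor is exact:
#' 1 \eqn{\AA^2}/ps = 100 \eqn{\times 10^{-9}} m\eqn{^2}/s.
#'
#' @param value numeric vector of diffusion coefficients.
#' @param from,to one of `"A2_per_ps"` or `"1e-9_m2_per_s"`.
#' @return numeric vector in the target unit.
#' @examples
#' convertDiffusion(0.1, from = "A2_per_ps", to = "1e-9_m2_per_s") # 10
#' @export
convertDiffusion <- function(value, from = c("A2_per_ps", "1e-9_m2_per_s"),
                             to = c("1e-9_m2_per_s", "A2_per_ps")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(value)
  if (from == "A2_per_ps") value * .A2PS_PER_1E9M2S else value / .A2PS_PER_1E9M2S
}

#' Molar concentration of n copies in a periodic cell
#'
#' Converts a copy number in a simulation cell of given volume to a molar
#' concentration: \eqn{c = n / (N_A V)}, reported in mmol/L. Twenty copies
#' in a 664,424 \eqn{\AA^3} cubic cell correspond to the 50 mM condition
#' used throughout the packaged reference tables.
#'
#' @param nCopies number of solute copies (>= 0).
#' @param boxVolume cell volume in \eqn{\AA^3} (> 0).
#' @return concentration in mM.
#' @examples
#' concentrationMM(20, 664424) # ~50 mM
#' @export
concentrationMM <- function(nCopies, boxVolume) {
  stopifnot(is.numeric(nCopies), is.numeric(boxVolume))
  if (any(!is.finite(nCopies)) || any(nCopies < 0))
    stop("'nCopies' must be finite and >= 0")
  if (any(!is.finite(boxVolume)) || any(boxVolume <= 0))
    stop("'boxVolume' must be finite and > 0")
  # A^3 -> L: 1 A^3 = 1e-27 L; mol -> mmol: 1e3
  nCopies / (.N_AVOGADRO * boxVolume * 1e-27) * 1e3
}
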