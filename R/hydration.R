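#' @rdname radiusOfGyration
setMethod("radiusOfGyration", "matrix", function(x, masses = NULL, ...) {
  if (nrow(x) < 1L) stop("empty selection")
  if (is.null(masses)) masses <- rep(1, nrow(x))
  com <- colSums(x * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(x, 2, com)^2)) / sum(masses))
})

#' @rdname radiusOfGyration
#' @param map a [SystemMap-class].
#' @param soluteIndex solute copy to analyze (default 1).
#' @param frames frame indices (default all).
#' @param masses per-atom masses for the matrix method (default unit).
setMethod("radiusOfGyration", "Trajectory",
  function(x, map, soluteIndex = 1, frames = NULL, ...) {
    g <- map@soluteGroups[[soluteIndex]]
    if (!length(g)) stop("empty selection")
    if (is.null(frames)) frames <- seq_len(nFrames(x))
    per <- vapply(frames, function(f)
      radiusOfGyration(matrix(x@coords[g, , f], ncol = 3), map@masses[g]),
      numeric(1))
    list(mean = mean(per), sd = if (length(per) > 1) sd(per) else 0,
         perFrame = per)
  })

#' Number of entrained waters from the spherical-envelope model
#'
#' Treats the hydrodynamic radius as the radius of a sphere comprising
#' the solute plus its tightly bound waters and the radius of gyration
#' as the radius of the bare-solute sphere; the volume difference
#' divided by the volume of one water (30 \eqn{\AA^3}) counts the
#' entrained waters:
#' \eqn{N_W = \frac{4}{3}\pi (R_H^3 - R_g^3) / V_W}.
#' For extended polymers \eqn{R_g} can exceed \eqn{R_H}; the resulting
#' negative count is reported with a warning rather than clamped, as a
#' diagnostic that the spherical-envelope picture does not apply.
#'
#' @param rH hydrodynamic radius in \eqn{\AA} (> 0), vectorized.
#' @param rG radius of gyration in \eqn{\AA} (> 0), vectorized.
#' @param vW volume of a single water in \eqn{\AA^3} (default 30).
#' @return entrained water count (dimensionless).
#' @examples
#' entrainedWaters(3.93, 2.64) # ~5.9, glucose
#' @export
entrainedWaters <- function(rH, rG, vW = 30) {
  if (any(vW <= 0)) stop("vW must be positive")
  if (any(rH <= 0) || any(rG <= 0)) stop("radii must be positive")
  nW <- 4 / 3 * pi * (rH^3 - rG^3) / vW
  if (any(nW < 0))
    warning("R_H < R_g for some inputs: negative entrained-water count; ",
            "the spherical-envelope model does not hold for extended ",
            "polymers")
  nW
}

#' Predict the hydrodynamic radius from R_g and an entrained-water count
#'
#' Inverts the spherical-envelope relation: the hydrodynamic sphere is
#' the bare-solute sphere augmented by \eqn{N} water volumes,
#' \eqn{R_H = (3 V_W N / (4\pi) + R_g^3)^{1/3}}. With \eqn{N = 0} this
#' reduces to \eqn{R_H = R_g}. It is the exact algebraic inverse of
#' [entrainedWaters].
#'
#' @param rG radius of gyration in \eqn{\AA}.
#' @param n entrained-water count, from a hydration number or from
#'   [entrainedWaters] (>= 0).
#' @param vW water volume in \eqn{\AA^3} (default 30).
#' @return predicted \eqn{R_H} in \eqn{\AA}.
#' @examples
#' predictRH(2.34, 1.1 * 5) # ~3.73, xylose
#' @export
predictRH <- function(rG, n, vW = 30) {
  if (any(n < 0)) stop("entrained-water count must be >= 0")
  if (any(rG <= 0)) stop("rG must be positive")
  (3 * vW * n / (4 * pi) + rG^3)^(1 / 3)
}

#' Predict a diffusion coefficient from R_g and the polar-atom count
#'
#' The empirical predictor: the entrained-water count is approximated as
#' 1.1 waters per polar atom, the hydrodynamic radius follows from
#' [predictRH], and the diffusion coefficient from the Stokes-Einstein
#' relation in experimental water (eta = 0.00089 kg/m s, 298 K) unless
#' another solvent is given.
#'
#' @param rG radius of gyration in \eqn{\AA}, vectorized.
#' @param nPA polar-atom count (>= 0), vectorized.
#' @param solvent a [SolventModel-class] (default experimental water).
#' @param watersPerPolarAtom waters per polar atom (default 1.1).
#' @param vW water volume in \eqn{\AA^3} (default 30).
#' @return predicted D in 1e-9 m^2/s.
#' @examples
#' predictD(2.34, 5)  # ~0.66, xylose
#' predictD(2.64, 6)  # ~0.61, glucose
#' @export
predictD <- function(rG, nPA, solvent = solventModel("water"),
                     watersPerPolarAtom = 1.1, vW = 30) {
  if (any(nPA < 0)) stop("nPA must be >= 0")
  rh <- predictRH(rG, watersPerPolarAtom * nPA, vW)
  stokesEinstein(rh, solvent, direction = "RH_to_D")
}

#' Polar-atom count from a functional-group composition
#'
#' Oxygen atoms count as the polar atoms; carboxylate, amide and ester
#' groups contribute two polar atoms each.
#'
#' @param groups named numeric vector of group counts. Recognized names:
#'   `hydroxyl`, `ring_oxygen`, `glycosidic`, `ether` (weight 1 each);
#'   `carboxylate`, `amide`, `ester` (weight 2 each).
#' @return integer polar-atom count.
#' @examples
#' polarAtomCount(c(hydroxyl = 4, ring_oxygen = 1)) # xylose: 5
#' @export
polarAtomCount <- function(groups) {
  weights <- c(hydroxyl = 1, ring_oxygen = 1, glycosidic = 1, ether = 1,
               carboxylate = 2, amide = 2, ester = 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("'groups' must be a named vector of functional-group counts")
  unknown <- setdiff(names(groups), names(weights))
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  as.integer(round(sum(groups * weights[names(groups)])))
}
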