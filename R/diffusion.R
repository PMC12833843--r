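#' Mean squared displacement of solute centers of mass
#'
#' For each lag time \eqn{t}, the squared center-of-mass displacement is
#' averaged over all solute copies and (by default) over all time
#' origins, giving \eqn{\langle\Delta r^2(t)\rangle} in \eqn{\AA^2}. With
#' `multiOrigin = FALSE` only the first frame serves as origin,
#' reproducing the literal single-origin form of the displacement sum.
#' The trajectory must be unwrapped ([unwrapTrajectory]); wrapped input
#' is detected by center-of-mass jumps exceeding half a box length.
#'
#' @param traj an unwrapped [Trajectory-class].
#' @param map a [SystemMap-class] defining the solute copies.
#' @param maxLag largest lag in ps (default: half the trajectory span).
#' @param multiOrigin average over all time origins (default TRUE).
#' @param removeDrift subtract the net system center-of-mass motion
#'   (all mapped atoms) before computing displacements (default FALSE).
#' @param lagStride evaluate every `lagStride`-th lag (default 1).
#' @return an [MSDSeries-class].
#' @export
computeMSD <- function(traj, map, maxLag = NULL, multiOrigin = TRUE,
                       removeDrift = FALSE, lagStride = 1L) {
  nf <- nFrames(traj)
  if (nf < 2L) stop("at least 2 frames required")
  dt <- traj@frameInterval
  span <- traj@times[nf] - traj@times[1]
  if (is.null(maxLag)) maxLag <- span / 2
  if (maxLag > span + 1e-9)
    stop("maxLag exceeds the available trajectory span")
  com <- .comPaths(traj, map)
  ns <- dim(com)[1]
  halfBox <- apply(traj@box, 1, min) / 2
  for (f in 2:nf) {
    d <- .frameMatrix(com, f) - .frameMatrix(com, f - 1)
    if (any(sqrt(rowSums(d * d)) > halfBox[f]))
      stop("center-of-mass jump > half box between frames ", f - 1, " and ",
           f, ": trajectory appears wrapped; call unwrapTrajectory() first")
  }
  if (removeDrift) {
    ref <- centerOfMass(.frameMatrix(traj@coords, 1), map@masses)
    for (f in seq_len(nf)) {
      drift <- centerOfMass(.frameMatrix(traj@coords, f), map@masses) - ref
      com[, , f] <- sweep(.frameMatrix(com, f), 2, drift)
    }
  }
  maxLagFrames <- min(nf - 1L, floor(maxLag / dt + 1e-9))
  lags <- seq(0L, maxLagFrames, by = as.integer(lagStride))
  msd <- numeric(length(lags))
  for (k in seq_along(lags)) {
    L <- lags[k]
    if (L == 0L) { msd[k] <- 0; next }
    if (multiOrigin) {
      d <- com[, , (1L + L):nf, drop = FALSE] -
        com[, , 1L:(nf - L), drop = FALSE]
      msd[k] <- mean(colSums(aperm(d * d, c(2, 1, 3))))
    } else {
      d <- .frameMatrix(com, 1L + L) - .frameMatrix(com, 1L)
      msd[k] <- mean(rowSums(d * d))
    }
  }
  new("MSDSeries", lagTimes = lags * dt, msd = msd,
      perReplicate = matrix(numeric(0), length(lags), 0))
}

#' Average MSD curves over replicate simulations
#'
#' Replicate curves are averaged pointwise before fitting, and retained
#' per replicate so the dispersion of replicate-level estimates can be
#' reported.
#'
#' @param seriesList list of [MSDSeries-class] on identical lag grids.
#' @return an [MSDSeries-class] whose `perReplicate` slot holds the
#'   individual curves.
#' @export
averageMSD <- function(seriesList) {
  stopifnot(length(seriesList) >= 1)
  lags <- seriesList[[1]]@lagTimes
  for (s in seriesList)
    if (!isTRUE(all.equal(s@lagTimes, lags)))
      stop("replicate MSD series must share one lag grid")
  per <- vapply(seriesList, function(s) s@msd, numeric(length(lags)))
  per <- matrix(per, nrow = length(lags))
  new("MSDSeries", lagTimes = lags, msd = rowMeans(per), perReplicate = per)
}

.fitSlope <- function(lag, msd, weighted, throughOrigin) {
  w <- if (weighted) 1 / pmax(lag, min(lag[lag > 0])) else NULL
  fit <- if (throughOrigin) lm(msd ~ lag + 0, weights = w)
  else lm(msd ~ lag, weights = w)
  # suppress the "essentially perfect fit" note on noiseless input
  co <- suppressWarnings(summary(fit)$coefficients)
  co["lag", c("Estimate", "Std. Error")]
}

#' Fit a diffusion coefficient to an MSD curve
#'
#' Ordinary least squares of \eqn{\langle\Delta r^2(t)\rangle} against
#' lag time over a fit window; the diffusion coefficient follows from the
#' slope as \eqn{D = \mathrm{slope}/(2n)} with \eqn{n = 3} dimensions
#' (i.e. slope/6), converted to 1e-9 m^2/s. The default window spans 10%
#' to 50% of the maximum lag, excluding the short-time non-diffusive and
#' the long-lag high-variance regions. When per-replicate curves are
#' present, each replicate is also fitted individually.
#'
#' @param series an [MSDSeries-class].
#' @param window numeric length-2 lag window in ps (default
#'   `c(0.1, 0.5) * max(lag)`).
#' @param weighted weight points by inverse lag (default FALSE).
#' @param throughOrigin force a zero intercept (default FALSE).
#' @return a [DiffusionEstimate-class]. A nonpositive fitted slope is
#'   flagged (with a warning), never silently made positive.
#' @examples
#' lag <- 0:100
#' fitDiffusion(new("MSDSeries", lagTimes = as.numeric(lag),
#'                  msd = 6 * 0.1 * lag,
#'                  perReplicate = matrix(numeric(0), 101, 0)))
#' @export
fitDiffusion <- function(series, window = NULL, weighted = FALSE,
                         throughOrigin = FALSE) {
  lags <- series@lagTimes
  if (is.null(window)) window <- c(0.1, 0.5) * max(lags)
  if (window[1] >= window[2] || window[2] > max(lags) + 1e-9)
    stop("fit window outside available lag times")
  sel <- lags >= window[1] & lags <= window[2]
  if (sum(sel) < 3L) stop("fewer than 3 points in the fit window")
  est <- .fitSlope(lags[sel], series@msd[sel], weighted, throughOrigin)
  n <- 3L
  conv <- .A2PS_PER_1E9M2S / (2 * n)
  D <- unname(est[1]) * conv
  se <- unname(est[2]) * conv
  flagged <- D <= 0
  if (flagged)
    warning("nonpositive fitted slope: D = ", signif(D, 4),
            " x 1e-9 m^2/s is not physical")
  repD <- numeric(0)
  if (ncol(series@perReplicate) > 0) {
    repD <- apply(series@perReplicate[sel, , drop = FALSE], 2, function(y)
      unname(.fitSlope(lags[sel], y, weighted, throughOrigin)[1]) * conv)
  }
  new("DiffusionEstimate", D = D, stderr = se,
      fitWindow = as.numeric(window), nDimensions = n,
      replicateValues = repD, flagged = flagged)
}

#' Stokes-Einstein conversion between D and hydrodynamic radius
#'
#' \eqn{D = k_B T / (6\pi\eta R_H)}: the diffusion coefficient of a
#' sphere of radius \eqn{R_H} in a solvent of viscosity \eqn{\eta} at
#' temperature \eqn{T}. The relation is its own inverse, so a single
#' function converts in both directions; a round trip is the identity.
#'
#' @param value D in 1e-9 m^2/s (`direction = "D_to_RH"`) or
#'   \eqn{R_H} in \eqn{\AA} (`direction = "RH_to_D"`). Must be > 0.
#' @param solvent a [SolventModel-class] (default experimental water,
#'   eta = 0.00089 kg/m s, 298 K).
#' @param direction conversion direction.
#' @return \eqn{R_H} in \eqn{\AA}, or D in 1e-9 m^2/s.
#' @examples
#' stokesEinstein(0.62)                       # R_H ~ 3.96 A
#' stokesEinstein(3.96, direction = "RH_to_D")
#' @export
stokesEinstein <- function(value, solvent = solventModel("water"),
                           direction = c("D_to_RH", "RH_to_D")) {
  direction <- match.arg(direction)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("input to stokesEinstein must be positive and finite")
  pref <- .kB * solvent@temperature / (6 * pi * solvent@viscosity) # m^3/s
  if (direction == "D_to_RH") pref / (value * 1e-9) * 1e10
  else pref / (value * 1e-10) / 1e-9
}

#' Finite periodic-box correction to a self-diffusion coefficient
#'
#' Self-diffusion in a periodic cell is retarded by hydrodynamic
#' interaction with the image lattice; the leading correction for a
#' cubic cell of edge \eqn{L} is
#' \eqn{\Delta D = k_B T \xi / (6\pi\eta L)} with the cubic-lattice
#' constant \eqn{\xi = 2.837297}. The correction vanishes as
#' \eqn{L \to \infty} and decreases monotonically with \eqn{L}.
#'
#' @param dPBC diffusion coefficient from the periodic simulation, in
#'   1e-9 m^2/s.
#' @param solvent a [SolventModel-class].
#' @param boxLength cubic box edge in \eqn{\AA}.
#' @return corrected D in 1e-9 m^2/s.
#' @export
finiteBoxCorrection <- function(dPBC, solvent, boxLength) {
  if (any(boxLength <= 0)) stop("boxLength must be > 0")
  xi <- 2.837297
  corr <- .kB * solvent@temperature * xi /
    (6 * pi * solvent@viscosity * boxLength * 1e-10) / 1e-9
  dPBC + corr
}

#' Welch's two-sample t test
#'
#' Two-tailed comparison of two means without assuming equal variances
#' (Welch-Satterthwaite degrees of freedom), the test used for pairwise
#' comparisons of replicate-level estimates. Degenerate zero-variance
#' inputs follow the conventions: equal constant samples give t = 0,
#' p = 1; unequal constant samples give infinite t, p = 0.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return list with `t`, `df` and `p`.
#' @examples
#' welchT(c(0.62, 0.63, 0.61), c(0.70, 0.71, 0.69))
#' @export
welchT <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = Inf, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = Inf, p = 0))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
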