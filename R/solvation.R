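#' Radial distribution function of water oxygens about a solute
#'
#' Histogram of minimum-image distances from the solute center (the
#' unweighted geometric center by default) to all water oxygen atoms,
#' normalized by spherical shell volume and by the bulk water-oxygen
#' number density \eqn{\rho = n_{waters}/V_{box}}, averaged over frames.
#' A Savitzky-Golay-smoothed copy of the curve is kept alongside the raw
#' histogram for stable location of shell extrema.
#'
#' @param traj a [Trajectory-class].
#' @param map a [SystemMap-class] with a nonempty water-oxygen set.
#' @param soluteIndex which solute copy to center on (default 1).
#' @param binWidth histogram bin width in \eqn{\AA} (default 0.05).
#' @param rMax histogram range in \eqn{\AA}; must not exceed half the
#'   smallest box length (default: that bound).
#' @param massWeighted use the mass-weighted center instead of the
#'   geometric center (default FALSE).
#' @param smoothWindow odd Savitzky-Golay window length in bins
#'   (default 11); windows longer than the profile are shortened.
#' @return an [RDFProfile-class].
#' @export
computeRDF <- function(traj, map, soluteIndex = 1, binWidth = 0.05,
                       rMax = NULL, massWeighted = FALSE, smoothWindow = 11) {
  stopifnot(binWidth > 0)
  if (!length(map@waterOxygens)) stop("no water oxygens in the system map")
  halfMin <- min(traj@box) / 2
  if (is.null(rMax)) rMax <- halfMin
  if (rMax > halfMin + 1e-9)
    stop("rMax (", rMax, " A) exceeds half the smallest box length (",
         signif(halfMin, 4), " A)")
  nBins <- floor(rMax / binWidth)
  counts <- numeric(nBins)
  rhoSum <- 0
  g0 <- map@soluteGroups[[soluteIndex]]
  nf <- nFrames(traj)
  for (f in seq_len(nf)) {
    fr <- .frameMatrix(traj@coords, f)
    box <- traj@box[f, ]
    center <- if (massWeighted) centerOfMass(fr, map@masses, g0)
    else colMeans(fr[g0, , drop = FALSE])
    d <- .miDistances(center, fr[map@waterOxygens, , drop = FALSE], box)
    bin <- ceiling(d / binWidth)
    bin <- bin[bin >= 1 & bin <= nBins]
    counts <- counts + tabulate(bin, nBins)
    rhoSum <- rhoSum + length(map@waterOxygens) / prod(box)
  }
  rho <- rhoSum / nf
  edges <- (0:nBins) * binWidth
  shellVol <- 4 / 3 * pi * diff(edges^3)
  g <- counts / (nf * rho * shellVol)
  win <- min(smoothWindow, if (nBins %% 2 == 1) nBins else nBins - 1)
  if (win %% 2 == 0) win <- win - 1
  gS <- if (win >= 5 && nBins >= win) signal::sgolayfilt(g, p = 3, n = win)
  else g
  new("RDFProfile", binCenters = edges[-1] - binWidth / 2, g = g,
      gSmooth = pmax(gS, 0), rho = rho)
}

#' Locate the first solvation shell on an RDF curve
#'
#' Finds the first local maximum of the smoothed g(r) beyond an exclusion
#' radius (the first-shell peak) and the first subsequent local minimum
#' (\eqn{r_{min}}, the bottom of the well between the first and second
#' shells, which bounds the coordination integral).
#'
#' @param profile an [RDFProfile-class].
#' @param exclusionRadius ignore bins below this radius (\eqn{\AA},
#'   default 1), which only probe the excluded volume.
#' @return list with `first_peak_position`, `first_peak_max`,
#'   `first_min_value` and `r_min` (peak height and minimum value are
#'   read off the raw curve at the located bins).
#' @export
firstShellStats <- function(profile, exclusionRadius = 1) {
  r <- profile@binCenters
  y <- profile@gSmooth
  n <- length(y)
  if (n < 5) stop("profile too short to locate a solvation shell")
  start <- which(r > exclusionRadius)[1]
  if (is.na(start)) stop("exclusion radius beyond profile range")
  peak <- NA_integer_
  for (i in max(start, 2):(n - 1)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1] && y[i] > 1e-8) { peak <- i; break }
  }
  if (is.na(peak))
    stop("no interior maximum found: profile is monotone or flat over the ",
         "search range")
  valley <- NA_integer_
  for (i in (peak + 1):(n - 1)) {
    if (y[i] < y[i - 1] && y[i] <= y[i + 1]) { valley <- i; break }
  }
  if (is.na(valley))
    stop("no minimum found after the first peak; increase rMax")
  list(first_peak_position = r[peak], first_peak_max = profile@g[peak],
       first_min_value = profile@g[valley], r_min = r[valley])
}

#' First-shell coordination number N1
#'
#' Integrates \eqn{4\pi\rho\, g(r) r^2} from 0 to \eqn{r_{min}} by
#' trapezoidal quadrature, giving the mean number of water oxygens in
#' the first solvation shell. When `rMin` is not supplied it is located
#' with [firstShellStats].
#'
#' @param profile an [RDFProfile-class].
#' @param rMin upper integration limit in \eqn{\AA} (default: detected).
#' @param useSmoothed integrate the smoothed curve instead of the raw
#'   histogram (default FALSE).
#' @return the coordination number (dimensionless).
#' @export
integrateN1 <- function(profile, rMin = NULL, useSmoothed = FALSE) {
  if (is.null(rMin)) rMin <- firstShellStats(profile)$r_min
  r <- profile@binCenters
  y <- if (useSmoothed) profile@gSmooth else profile@g
  if (rMin > max(r) + 1e-9) stop("rMin beyond profile range")
  keep <- r <= rMin
  xs <- c(0, r[keep])
  ys <- c(0, y[keep])
  if (max(r[keep]) < rMin - 1e-12) {
    yEnd <- approx(r, y, xout = rMin, rule = 2)$y
    xs <- c(xs, rMin)
    ys <- c(ys, yEnd)
  }
  integrand <- 4 * pi * profile@rho * ys * xs^2
  pracma::trapz(xs, integrand)
}

# Kabsch rotation aligning moving onto reference (both centered), internal.
.kabsch <- function(moving, reference) {
  H <- t(moving) %*% reference
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Time-averaged Gaussian-weighted water occupancy grid
#'
#' Deposits, for every frame, a normalized 3-D Gaussian for each water
#' oxygen onto a cubic voxel grid centered on the solute, and averages
#' over frames. Frames are first superposed on the solute (translation
#' to its geometric center and, for solutes with three or more atoms, a
#' rotational least-squares fit to the first frame), so the density maps
#' the solvent structure in the solute frame. Voxel values are
#' probability densities per \eqn{\AA^3}: the deposit of one water
#' integrates to 1 over space, so the voxel sum times the voxel volume
#' approximates the mean number of waters inside the grid.
#'
#' @param traj a [Trajectory-class].
#' @param map a [SystemMap-class] with a nonempty water-oxygen set.
#' @param soluteIndex solute copy to center on (default 1).
#' @param spacing voxel edge in \eqn{\AA} (default 0.25).
#' @param gridEdge cube edge of the grid in \eqn{\AA} (default 25, i.e.
#'   a 100^3 grid at the default spacing).
#' @param sigma Gaussian deposition width in \eqn{\AA} (default 1.0, of
#'   the order of a water-oxygen van der Waals radius).
#' @param align superpose frames on the solute before deposition
#'   (default TRUE).
#' @param truncate kernel truncation radius in units of `sigma`
#'   (default 4).
#' @return an [OccupancyGrid-class]; suggested display isovalues (3.6,
#'   3.8 and 4.0% of maximum) are attached as metadata.
#' @export
occupancyMap <- function(traj, map, soluteIndex = 1, spacing = 0.25,
                         gridEdge = 25, sigma = 1.0, align = TRUE,
                         truncate = 4) {
  if (!length(map@waterOxygens)) stop("no water oxygens in the system map")
  stopifnot(spacing > 0, gridEdge > 0, sigma > 0)
  nSide <- max(2L, round(gridEdge / spacing))
  half <- nSide * spacing / 2
  origin <- rep(-half + spacing / 2, 3)
  axis <- origin[1] + (seq_len(nSide) - 1) * spacing
  acc <- array(0, c(nSide, nSide, nSide))
  g0 <- map@soluteGroups[[soluteIndex]]
  nf <- nFrames(traj)
  refSolute <- NULL
  kHalf <- ceiling(truncate * sigma / spacing)
  for (f in seq_len(nf)) {
    fr <- .frameMatrix(traj@coords, f)
    center <- colMeans(fr[g0, , drop = FALSE])
    sol <- sweep(fr[g0, , drop = FALSE], 2, center)
    R <- diag(3)
    if (align && length(g0) >= 3) {
      if (is.null(refSolute)) refSolute <- sol
      else R <- .kabsch(sol, refSolute)
    }
    w <- sweep(fr[map@waterOxygens, , drop = FALSE], 2, center) %*% t(R)
    for (k in seq_len(nrow(w))) {
      p <- w[k, ]
      if (any(abs(p) > half + truncate * sigma)) next
      idx <- lapply(1:3, function(ax) {
        c0 <- round((p[ax] - origin[ax]) / spacing) + 1
        lo <- max(1, c0 - kHalf)
        hi <- min(nSide, c0 + kHalf)
        if (lo > hi) integer(0) else lo:hi
      })
      if (any(vapply(idx, length, 1L) == 0L)) next
      gx <- exp(-((axis[idx[[1]]] - p[1])^2) / (2 * sigma^2))
      gy <- exp(-((axis[idx[[2]]] - p[2])^2) / (2 * sigma^2))
      gz <- exp(-((axis[idx[[3]]] - p[3])^2) / (2 * sigma^2))
      kern <- outer(outer(gx, gy), gz)
      # normalize against the untruncated discrete Gaussian so each fully
      # contained water deposits unit mass
      norm <- (sum(exp(-((seq(-kHalf, kHalf) * spacing)^2) / (2 * sigma^2))))^3
      acc[idx[[1]], idx[[2]], idx[[3]]] <-
        acc[idx[[1]], idx[[2]], idx[[3]]] + c(kern) / norm / spacing^3
    }
  }
  new("OccupancyGrid", origin = origin, spacing = spacing, values = acc / nf,
      sigma = sigma, isovalues = c(0.036, 0.038, 0.040))
}
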