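msdSeries <- function(lag, msd, per = NULL) {
  new("MSDSeries", lagTimes = as.numeric(lag), msd = as.numeric(msd),
      perReplicate = if (is.null(per)) matrix(numeric(0), length(lag), 0)
      else per)
}

test_that("MSD of stationary and ballistic motion match closed forms", {
  still <- makePointTrajectory(rep(list(rbind(c(3, 3, 3))), 30), c(50, 50, 50))
  s <- computeMSD(still, pointMap(1))
  expect_true(all(s@msd == 0))
  # one solute at x = v t with v = 1 A/ps: msd(t) = t^2
  nf <- 41
  pos <- lapply(0:(nf - 1), function(f) rbind(c(f * 10, 0, 0)))
  # large box so the ballistic path needs no unwrapping
  bal <- makePointTrajectory(pos, c(5000, 5000, 5000))
  s2 <- computeMSD(bal, pointMap(1))
  expect_equal(s2@msd, s2@lagTimes^2, tolerance = 1e-9)
  # single-origin mode agrees for deterministic uniform motion
  s3 <- computeMSD(bal, pointMap(1), multiOrigin = FALSE)
  expect_equal(s3@msd, s3@lagTimes^2, tolerance = 1e-9)
})

test_that("MSD estimator recovers a known Brownian D", {
  sim <- simulateBrownian(brownianSpec(nSolutes = 20, DTrue = 0.62,
                                       nFrames = 1000, seed = 5))
  s <- computeMSD(sim$unwrapped, sim$map)
  est <- fitDiffusion(s)
  # 3 standard errors of the replicate-free fit, dominated by lag correlation:
  # use a generous 15% bound for a single replicate
  expect_lt(abs(est@D - 0.62) / 0.62, 0.15)
})

test_that("wrapped trajectories are detected and refused", {
  sim <- simulateBrownian(brownianSpec(nSolutes = 10, DTrue = 1.0,
                                       nFrames = 400, boxLength = 12,
                                       seed = 6))
  expect_error(computeMSD(sim$trajectory, sim$map), "wrapped")
  expect_silent(computeMSD(unwrapTrajectory(sim$trajectory, sim$map),
                           sim$map))
})

test_that("MSD is invariant under global translation and rotation", {
  sim <- simulateBrownian(brownianSpec(nSolutes = 8, nFrames = 200, seed = 8))
  base <- computeMSD(sim$unwrapped, sim$map)@msd
  shifted <- sim$unwrapped
  shifted@coords <- shifted@coords + 17.3
  expect_equal(computeMSD(shifted, sim$map)@msd, base, tolerance = 1e-9)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- sim$unwrapped
  for (f in seq_len(nFrames(rot))) rot@coords[, , f] <- rot@coords[, , f] %*% t(R)
  expect_equal(computeMSD(rot, sim$map)@msd, base, tolerance = 1e-9)
})

test_that("diffusion fit converts an exact 6 D t line correctly", {
  lag <- 0:100
  est <- fitDiffusion(msdSeries(lag, 6 * 0.1 * lag))
  expect_equal(est@D, 10.0, tolerance = 1e-9)  # 0.1 A^2/ps = 10 x 1e-9 m^2/s
  expect_equal(est@nDimensions, 3L)
  expect_false(est@flagged)
  # linearity: scaling the curve scales D
  est2 <- fitDiffusion(msdSeries(lag, 3 * 6 * 0.1 * lag))
  expect_equal(est2@D, 3 * est@D, tolerance = 1e-9)
})

test_that("noisy MSD stays within the regression CI of the clean slope", {
  set.seed(31)
  lag <- 0:200
  clean <- 6 * 0.05 * lag
  noisy <- clean + rnorm(length(lag), sd = 2)
  noisy[1] <- 0
  est <- fitDiffusion(msdSeries(lag, pmax(noisy, 0)))
  expect_lt(abs(est@D - 5), 3 * est@stderr)
})

test_that("per-replicate curves yield per-replicate estimates", {
  lag <- 0:50
  per <- cbind(6 * 0.1 * lag, 6 * 0.2 * lag)
  est <- fitDiffusion(msdSeries(lag, rowMeans(per), per))
  expect_equal(sort(est@replicateValues), c(10, 20), tolerance = 1e-9)
  expect_equal(est@D, 15, tolerance = 1e-9)
})

test_that("a negative slope is flagged, not silently corrected", {
  lag <- 0:30
  expect_warning(est <- fitDiffusion(msdSeries(lag, c(0, 30 - lag[-1]))),
                 "not physical")
  expect_true(est@flagged)
  expect_lt(est@D, 0)
  expect_error(fitDiffusion(msdSeries(0:30, 0:30 * 6), window = c(40, 50)),
               "window")
})

test_that("Stokes-Einstein conversion round-trips and matches closed forms", {
  w <- solventModel("water")
  d <- 0.62
  expect_equal(stokesEinstein(stokesEinstein(d, w), w, "RH_to_D"), d,
               tolerance = 1e-12)
  # closed-form oracle evaluated independently
  rhOracle <- 1.380649e-23 * 298 / (6 * pi * 0.00089 * 0.62e-9) * 1e10
  expect_equal(stokesEinstein(0.62, w), rhOracle, tolerance = 1e-12)
  expect_equal(round(stokesEinstein(0.62, w), 2), 3.96)
  # concentration effect: D dropping 0.29 -> 0.24 is a 21% R_H increase
  ratio <- stokesEinstein(0.24, w) / stokesEinstein(0.29, w)
  expect_equal(round(100 * (ratio - 1)), 21)
  expect_error(stokesEinstein(-1, w), "positive")
})

test_that("finite-box correction vanishes with box size and is monotone", {
  w <- solventModel("tip5p")
  d0 <- 0.5
  expect_equal(finiteBoxCorrection(d0, w, 1e12), d0, tolerance = 1e-9)
  Ls <- c(40, 60, 87.34, 200)
  corr <- finiteBoxCorrection(d0, w, Ls) - d0
  expect_true(all(diff(corr) < 0))
  # closed-form oracle at the study's box size
  oracle <- 1.380649e-23 * 298 * 2.837297 /
    (6 * pi * 0.0007 * 87.34e-10) / 1e-9
  expect_equal(finiteBoxCorrection(d0, w, 87.34) - d0, oracle,
               tolerance = 1e-12)
})

test_that("Welch's t matches the textbook formula and its symmetries", {
  a <- c(0.63, 0.62, 0.64, 0.61)
  b <- c(0.71, 0.70, 0.73)
  res <- welchT(a, b)
  # direct Welch-Satterthwaite evaluation
  se2 <- var(a) / length(a) + var(b) / length(b)
  tOracle <- (mean(a) - mean(b)) / sqrt(se2)
  dfOracle <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                       (var(b) / length(b))^2 / (length(b) - 1))
  pOracle <- 2 * pt(-abs(tOracle), dfOracle)
  expect_equal(res$t, tOracle, tolerance = 1e-6)
  expect_equal(res$df, dfOracle, tolerance = 1e-6)
  expect_equal(res$p, pOracle, tolerance = 1e-6)
  # antisymmetry
  swap <- welchT(b, a)
  expect_equal(swap$t, -res$t, tolerance = 1e-12)
  expect_equal(swap$p, res$p, tolerance = 1e-12)
  # identical samples
  same <- welchT(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("halved frame sampling leaves the fitted D invariant within noise", {
  sim <- simulateBrownian(brownianSpec(nSolutes = 20, DTrue = 0.62,
                                       nFrames = 1200, seed = 12))
  full <- computeMSD(sim$unwrapped, sim$map)
  dFull <- fitDiffusion(full)@D
  thin <- sim$unwrapped
  keep <- seq(1, 1200, by = 2)
  thin <- Trajectory(thin@coords[, , keep], thin@box[keep, ],
                     thin@times[keep], 20)
  dThin <- fitDiffusion(computeMSD(thin, sim$map))@D
  expect_lt(abs(dThin - dFull) / dFull, 0.1)
})
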