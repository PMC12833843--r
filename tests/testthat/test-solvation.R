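# Multi-reference ideal-gas RDF: average computeRDF over several reference
# solutes to accumulate counting statistics cheaply.
idealGasRDF <- function(nRefs, nWaters, box, nFrames, binWidth, rMax, seed) {
  set.seed(seed)
  n <- nRefs + nWaters
  coords <- array(runif(n * 3 * nFrames, 0, box), c(n, 3, nFrames))
  traj <- Trajectory(coords, rep(box, 3))
  map <- SystemMap(as.list(seq_len(nRefs)),
                   waterOxygens = nRefs + seq_len(nWaters),
                   masses = rep(1, n))
  profs <- lapply(seq_len(nRefs), function(s)
    computeRDF(traj, map, s, binWidth = binWidth, rMax = rMax))
  g <- rowMeans(vapply(profs, function(p) p@g, numeric(
    length(profs[[1]]@g))))
  list(r = profs[[1]]@binCenters, g = g, rho = profs[[1]]@rho)
}

test_that("ideal-gas RDF is flat at 1 within 2%", {
  flat <- idealGasRDF(nRefs = 48, nWaters = 1728, box = 12, nFrames = 100,
                      binWidth = 0.25, rMax = 5.75, seed = 41)
  keep <- flat$r >= 2
  expect_lt(max(abs(flat$g[keep] - 1)), 0.02)
  expect_equal(flat$rho, 1728 / 12^3, tolerance = 1e-12)
})

test_that("coordination number of an ideal gas matches (4/3) pi rho r^3", {
  iv <- generateIdealSolvent(8000, 24, nFrames = 800, seed = 42)
  prof <- computeRDF(iv$trajectory, iv$map, binWidth = 0.05, rMax = 11)
  for (r in c(4, 6, 8)) {
    analytic <- 4 / 3 * pi * prof@rho * r^3
    expect_equal(integrateN1(prof, rMin = r), analytic,
                 tolerance = 0.01)
  }
})

test_that("a single fixed water occupies exactly its distance bin", {
  box <- 20
  center <- rep(10, 3)
  d <- 3.0
  coords <- array(0, c(2, 3, 1))
  coords[1, , 1] <- center
  coords[2, , 1] <- center + c(d, 0, 0)
  traj <- Trajectory(coords, rep(box, 3))
  map <- SystemMap(list(1L), waterOxygens = 2L, masses = c(1, 1))
  prof <- computeRDF(traj, map, binWidth = 0.05, rMax = 8)
  occupied <- which(prof@g > 0)
  expect_length(occupied, 1L)
  expect_equal(prof@binCenters[occupied], 2.975)  # bin (2.95, 3.00]
})

test_that("doubling the water count at fixed box leaves g(r) unchanged", {
  mk <- function(n, seed) {
    iv <- generateIdealSolvent(n, 15, nFrames = 40, seed = seed)
    computeRDF(iv$trajectory, iv$map, binWidth = 0.25, rMax = 7)
  }
  g1 <- mk(1000, 7)
  g2 <- mk(2000, 7)
  keep <- g1@binCenters >= 2
  # same unit plateau despite doubled density (rho normalization)
  expect_equal(mean(g1@g[keep]), mean(g2@g[keep]), tolerance = 0.03)
  expect_equal(g2@rho, 2 * g1@rho, tolerance = 1e-12)
})

test_that("a constructed shell of k waters integrates to N1 = k", {
  box <- 30
  center <- rep(15, 3)
  k <- 12
  set.seed(43)
  # k waters on a sphere of radius 3, a distant crowd beyond r = 6
  dirs <- matrix(rnorm(k * 3), k, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  far <- matrix(runif(600, 0, box), 200, 3)
  far <- far[sqrt(rowSums(sweep(far, 2, center)^2)) > 7, , drop = FALSE]
  coords <- array(0, c(1 + k + nrow(far), 3, 1))
  coords[1, , 1] <- center
  coords[2:(k + 1), , 1] <- sweep(3 * dirs, 2, center, "+")
  coords[(k + 2):(1 + k + nrow(far)), , 1] <- far
  traj <- Trajectory(coords, rep(box, 3))
  map <- SystemMap(list(1L), waterOxygens = 1 + seq_len(k + nrow(far)),
                   masses = rep(1, 1 + k + nrow(far)))
  prof <- computeRDF(traj, map, binWidth = 0.05, rMax = 10)
  expect_equal(integrateN1(prof, rMin = 5), k, tolerance = 1e-2)
  # doubling rho with identical g doubles N1 (linearity in rho)
  prof2 <- prof
  prof2@rho <- 2 * prof@rho
  expect_equal(integrateN1(prof2, rMin = 5), 2 * integrateN1(prof, rMin = 5),
               tolerance = 1e-12)
})

test_that("first-shell statistics find a constructed peak and valley", {
  r <- seq(0.025, 8, by = 0.05)
  bump <- function(c0, h, w) h * exp(-(r - c0)^2 / (2 * w^2))
  # smooth excluded-volume onset followed by two shells
  g <- (1 + bump(4.68, 0.62, 0.35) + bump(7.0, 0.25, 0.4)) /
    (1 + exp(-(r - 2.8) / 0.2))
  prof <- new("RDFProfile", binCenters = r, g = g,
              gSmooth = signal::sgolayfilt(g, p = 3, n = 11), rho = 0.033)
  st <- firstShellStats(prof)
  expect_equal(st$first_peak_position, 4.68, tolerance = 0.05 + 1e-9)
  expect_gt(st$first_peak_max, 1.5)
  expect_true(st$r_min > 4.68 && st$r_min < 7.0)
  expect_lt(st$first_min_value, min(g[abs(r - 4.68) < 0.05]))
  # a flat profile has no shell structure
  flat <- new("RDFProfile", binCenters = r, g = rep(1, length(r)),
              gSmooth = rep(1, length(r)), rho = 0.033)
  expect_error(firstShellStats(flat), "monotone|flat")
})

test_that("RDF is invariant under water relabeling and rigid translation", {
  iv <- generateIdealSolvent(300, 15, nFrames = 5, seed = 44)
  base <- computeRDF(iv$trajectory, iv$map, binWidth = 0.25, rMax = 7)
  # relabel waters
  perm <- sample(waterOxygens(iv$map))
  map2 <- SystemMap(soluteGroups(iv$map), waterOxygens = perm,
                    masses = atomMasses(iv$map))
  expect_equal(computeRDF(iv$trajectory, map2, binWidth = 0.25, rMax = 7)@g,
               base@g, tolerance = 1e-12)
  # rigid translation of the whole system (periodic wrap irrelevant)
  shifted <- iv$trajectory
  shifted@coords <- shifted@coords + 4.2
  expect_equal(computeRDF(shifted, iv$map, binWidth = 0.25, rMax = 7)@g,
               base@g, tolerance = 1e-12)
})

test_that("occupancy map puts a static water's maximum at the grid center", {
  coords <- array(0, c(2, 3, 3))
  for (f in 1:3) {
    coords[1, , f] <- c(10, 10, 10)  # solute defines the grid center
    coords[2, , f] <- c(10, 10, 10)
  }
  traj <- Trajectory(coords, rep(20, 3))
  map <- SystemMap(list(1L), waterOxygens = 2L, masses = c(1, 1))
  grid <- occupancyMap(traj, map, spacing = 0.5, gridEdge = 6, sigma = 0.8)
  d <- dim(grid@values)
  idx <- arrayInd(which.max(grid@values), d)
  expect_equal(as.vector(idx), c(d[1] / 2, d[2] / 2, d[3] / 2),
               tolerance = 1)
  expect_true(all(grid@values >= 0))
})

test_that("deposited Gaussian mass is conserved for interior waters", {
  set.seed(45)
  nW <- 20
  coords <- array(0, c(1 + nW, 3, 2))
  for (f in 1:2) {
    coords[1, , f] <- c(15, 15, 15)
    # waters within a 4 A ball, far from the 16 A grid edge
    coords[2:(1 + nW), , f] <- 15 + matrix(runif(nW * 3, -4, 4), nW, 3)
  }
  traj <- Trajectory(coords, rep(30, 3))
  map <- SystemMap(list(1L), waterOxygens = 1 + seq_len(nW),
                   masses = rep(1, 1 + nW))
  grid <- occupancyMap(traj, map, spacing = 0.5, gridEdge = 16, sigma = 1)
  expect_equal(sum(grid@values) * 0.5^3, nW, tolerance = 1e-3)
})

test_that("translating water and grid together leaves the map unchanged", {
  coords <- array(0, c(2, 3, 1))
  coords[1, , 1] <- c(8, 8, 8)
  coords[2, , 1] <- c(9.3, 8.2, 7.7)
  traj <- Trajectory(coords, rep(40, 3))
  map <- SystemMap(list(1L), waterOxygens = 2L, masses = c(1, 1))
  g1 <- occupancyMap(traj, map, spacing = 0.5, gridEdge = 8, sigma = 1)
  shifted <- traj
  shifted@coords <- shifted@coords + 5.5
  g2 <- occupancyMap(shifted, map, spacing = 0.5, gridEdge = 8, sigma = 1)
  expect_equal(g2@values, g1@values, tolerance = 1e-12)
})
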