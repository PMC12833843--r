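twoSoluteFrame <- function(gap, box = 30) {
  coords <- array(0, c(4, 3, 1))
  coords[1, , 1] <- c(5, 5, 5)
  coords[2, , 1] <- c(6, 5, 5)
  coords[3, , 1] <- c(6 + gap, 5, 5)
  coords[4, , 1] <- c(7 + gap, 5, 5)
  list(traj = Trajectory(coords, rep(box, 3)),
       map = SystemMap(list(1:2, 3:4), masses = rep(1, 4)))
}

test_that("contacts follow the nearest-atom cutoff", {
  near <- twoSoluteFrame(2.0)
  expect_equal(nrow(detectContacts(near$traj, near$map)@edges), 1L)
  far <- twoSoluteFrame(3.0)
  expect_equal(nrow(detectContacts(far$traj, far$map)@edges), 0L)
  # exactly at the cutoff counts as a contact (<=)
  at <- twoSoluteFrame(2.85)
  expect_equal(nrow(detectContacts(at$traj, at$map)@edges), 1L)
})

test_that("contact edges match a brute-force all-pairs all-images scan", {
  set.seed(51)
  box <- 14
  nSol <- 14
  atomsPer <- 3
  for (rep in 1:6) {
    centers <- matrix(runif(nSol * 3, 0, box), nSol, 3)
    coords <- array(0, c(nSol * atomsPer, 3, 1))
    groups <- list()
    for (s in seq_len(nSol)) {
      rows <- (s - 1) * atomsPer + seq_len(atomsPer)
      coords[rows, , 1] <- sweep(matrix(rnorm(atomsPer * 3, sd = 0.6),
                                        atomsPer, 3), 2, centers[s, ], "+")
      groups[[s]] <- rows
    }
    traj <- Trajectory(coords, rep(box, 3))
    map <- SystemMap(groups, masses = rep(1, nSol * atomsPer))
    got <- detectContacts(traj, map)@edges
    want <- matrix(integer(0), 0, 2)
    fr <- coords[, , 1]
    for (i in 1:(nSol - 1)) for (j in (i + 1):nSol) {
      d <- bruteForceGroupDistance(fr[groups[[i]], , drop = FALSE],
                                   fr[groups[[j]], , drop = FALSE],
                                   rep(box, 3))
      if (d <= 2.85) want <- rbind(want, c(i, j))
    }
    expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
                 matrix(as.integer(want), ncol = 2))
  }
})

test_that("raising the cutoff never removes edges", {
  set.seed(52)
  coords <- array(runif(20 * 3, 0, 12), c(20, 3, 1))
  traj <- Trajectory(coords, rep(12, 3))
  map <- pointMap(20)
  prev <- 0L
  for (cutoff in c(1, 2, 3, 4.5, 6)) {
    n <- nrow(detectContacts(traj, map, cutoff = cutoff)@edges)
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("clustering is the transitive closure of contacts", {
  g <- new("ContactGraph", frameIndex = 1L,
           edges = matrix(c(1L, 2L, 2L, 3L), 2, 2, byrow = TRUE),
           nSolutes = 5L)
  comps <- clusterFrame(g)
  expect_equal(comps[[1]], 1:3)
  expect_equal(lengths(comps), c(3L, 1L, 1L))
  none <- new("ContactGraph", frameIndex = 1L,
              edges = matrix(integer(0), 0, 2), nSolutes = 20L)
  expect_equal(lengths(clusterFrame(none)), rep(1L, 20))
})

test_that("components agree with a breadth-first reachability oracle", {
  set.seed(53)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    m <- sample(0:12, 1)
    edges <- if (m) {
      e <- t(replicate(m, sort(sample(n, 2))))
      matrix(as.integer(e), ncol = 2)
    } else matrix(integer(0), 0, 2)
    g <- new("ContactGraph", frameIndex = 1L, edges = edges,
             nSolutes = as.integer(n))
    expect_identical(clusterFrame(g), bfsComponents(n, edges))
  }
})

test_that("a persistent dimer yields one event with the exact lifetime", {
  fx <- generateAggregateFixture(2, nFrames = 5, frameInterval = 10)
  st <- aggregateKinetics(fx$trajectory, fx$map)
  expect_equal(nrow(st@sizeTable), 1L)
  expect_equal(st@sizeTable$size, 2L)
  expect_equal(st@sizeTable$nEvents, 1L)
  expect_equal(st@sizeTable$meanLifetime_ns, 0.05)  # 5 frames x 10 ps
  expect_equal(st@meanSize, 2.0)
})

test_that("a single-frame contact is discarded by the persistence rule", {
  pattern <- list(c(FALSE, TRUE, FALSE, FALSE, FALSE))
  fx <- generateAggregateFixture(2, nFrames = 5,
                                 persistencePattern = pattern)
  st <- aggregateKinetics(fx$trajectory, fx$map)
  expect_equal(nrow(st@sizeTable), 0L)
  expect_equal(st@maxSize, 1L)
  # two consecutive frames survive
  pattern2 <- list(c(FALSE, TRUE, TRUE, FALSE, FALSE))
  fx2 <- generateAggregateFixture(2, nFrames = 5,
                                  persistencePattern = pattern2)
  st2 <- aggregateKinetics(fx2$trajectory, fx2$map)
  expect_equal(st2@sizeTable$nEvents, 1L)
  expect_equal(st2@sizeTable$meanLifetime_ns, 0.02)
})

test_that("constructed mixtures are recovered exactly, sizes and counts", {
  fx <- generateAggregateFixture(c(2, 3, 1), nFrames = 6, boxLength = 70)
  st <- aggregateKinetics(fx$trajectory, fx$map)
  expect_equal(st@sizeTable$size, c(2L, 3L))
  expect_equal(st@sizeTable$meanCountPerFrame, c(1, 1))
  expect_equal(st@meanSize, 2.5)
  expect_equal(st@maxSize, 3L)
  # the lone monomer is free in every frame
  expect_equal(st@freeMonomer_mM, concentrationMM(1, 70^3),
               tolerance = 1e-12)
})

test_that("an all-monomer 50 mM box reports the nominal free concentration", {
  box <- 664424^(1 / 3)
  # 20 stationary points on a grid, all pairwise gaps > 7 A (incl. images)
  pts <- cbind(as.matrix(expand.grid(seq(5, 85, 20), seq(5, 65, 20))), 5)
  coords <- array(0, c(20, 3, 3))
  for (f in 1:3) coords[, , f] <- pts
  traj <- Trajectory(coords, rep(box, 3))
  st <- aggregateKinetics(traj, pointMap(20))
  expect_equal(st@freeMonomer_mM, concentrationMM(20, 664424),
               tolerance = 1e-9)
  expect_equal(signif(st@freeMonomer_mM, 2), 50)
  expect_equal(nrow(st@sizeTable), 0L)
})

test_that("per-frame solute conservation holds through the pipeline", {
  pattern <- list(c(TRUE, TRUE, FALSE, TRUE, TRUE),
                  c(FALSE, TRUE, TRUE, TRUE, FALSE))
  fx <- generateAggregateFixture(c(2, 4), nFrames = 5, boxLength = 80,
                                 persistencePattern = pattern)
  for (f in 1:5) {
    comps <- clusterFrame(detectContacts(fx$trajectory, fx$map, f))
    expect_equal(sum(lengths(comps)), 6L)
  }
  # membership change splits events: cluster 2 contributes one 3-frame event
  st <- aggregateKinetics(fx$trajectory, fx$map)
  expect_equal(st@sizeTable$size, c(2L, 4L))
  expect_equal(st@sizeTable$nEvents, c(2L, 1L))
  expect_equal(st@sizeTable$meanLifetime_ns, c(0.02, 0.03))
})
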