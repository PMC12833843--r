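# Run code with a locally seeded RNG, restoring global state afterwards.
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Simulate independent Brownian solutes in a periodic box
#'
#' Generates a trajectory of single-pseudo-atom solutes, each performing
#' an independent Gaussian random walk with per-dimension step variance
#' \eqn{2 D \Delta t} (the exact increment law of free diffusion), wrapped
#' into a cubic periodic box. The generator is a pure function of its
#' seed. It provides ground truth for validating the MSD estimator
#' without molecular dynamics: the defaults emulate the reference study
#' conditions (20 copies, 87.34 \eqn{\AA} box = 50 mM, 10 ps frames).
#'
#' @param spec a [BrownianSpec-class] from [brownianSpec()].
#' @return list with elements `trajectory` (wrapped coordinates),
#'   `unwrapped` (the same walk before wrapping) and `map`
#'   ([SystemMap-class], unit masses).
#' @examples
#' sim <- simulateBrownian(brownianSpec(nSolutes = 5, nFrames = 50))
#' sim$trajectory
#' @export
simulateBrownian <- function(spec = brownianSpec()) {
  stopifnot(is(spec, "BrownianSpec"))
  validObject(spec)
  dtA2ps <- spec@DTrue / .A2PS_PER_1E9M2S
  stepSd <- sqrt(2 * dtA2ps * spec@frameInterval)
  if (stepSd >= spec@boxLength / 4)
    stop("per-frame step std (", signif(stepSd, 3),
         " A) >= box/4; unwrapping would be ambiguous")
  n <- spec@nSolutes
  nf <- spec@nFrames
  coords <- .withSeed(spec@seed, {
    start <- matrix(runif(n * 3, 0, spec@boxLength), n, 3)
    steps <- array(rnorm(n * 3 * (nf - 1), sd = stepSd), c(n, 3, nf - 1))
    out <- array(0, c(n, 3, nf))
    out[, , 1] <- start
    for (f in 2:nf) out[, , f] <- out[, , f - 1] + steps[, , f - 1]
    out
  })
  times <- (seq_len(nf) - 1) * spec@frameInterval
  unwrapped <- Trajectory(coords, rep(spec@boxLength, 3), times,
                          spec@frameInterval)
  map <- SystemMap(as.list(seq_len(n)), masses = rep(1, n))
  list(trajectory = wrapTrajectory(unwrapped), unwrapped = unwrapped,
       map = map)
}

#' Generate an ideal-gas solvent configuration
#'
#' Uniform i.i.d. water-oxygen positions in a cubic box, the null model
#' for which the radial distribution function is identically 1 and the
#' coordination number grows as \eqn{(4/3)\pi\rho r^3}. A reference
#' pseudo-atom fixed at the box center is included as a single "solute"
#' so the RDF machinery can be pointed at it directly.
#'
#' @param nWaters number of water oxygens per frame (> 0).
#' @param boxLength cubic box edge in \eqn{\AA}.
#' @param nFrames number of independent frames (default 1).
#' @param seed RNG seed.
#' @param referenceAtom include the central reference atom (default TRUE).
#' @return list with `trajectory` and `map`.
#' @export
generateIdealSolvent <- function(nWaters, boxLength, nFrames = 1, seed = 1,
                                 referenceAtom = TRUE) {
  stopifnot(nWaters > 0, boxLength > 0, nFrames >= 1)
  nRef <- as.integer(referenceAtom)
  n <- nWaters + nRef
  coords <- .withSeed(seed, {
    out <- array(0, c(n, 3, nFrames))
    for (f in seq_len(nFrames)) {
      if (referenceAtom) out[1, , f] <- rep(boxLength / 2, 3)
      out[(nRef + 1):n, , f] <- matrix(runif(nWaters * 3, 0, boxLength),
                                       nWaters, 3)
    }
    out
  })
  traj <- Trajectory(coords, rep(boxLength, 3))
  map <- SystemMap(if (referenceAtom) list(1L) else list(),
                   waterOxygens = (nRef + 1):n, masses = rep(1, n))
  list(trajectory = traj, map = map)
}

#' Construct an aggregation fixture with known cluster structure
#'
#' Builds a trajectory of two-atom rigid solutes arranged into clusters
#' with exactly controlled geometry: within a cluster, consecutive
#' solutes' nearest atoms sit exactly `contactDistance` apart (below the
#' 2.85 \eqn{\AA} contact cutoff); distinct clusters and dispersed
#' monomers are kept at least `separation` apart (above it). A
#' persistence pattern selects the frames in which each cluster is
#' assembled; in other frames its members are parked on a well-separated
#' monomer grid. This provides an exact oracle for the aggregation
#' pipeline: size distribution, lifetimes and free-monomer concentration
#' are known by construction.
#'
#' @param clusterSizes integer vector of cluster sizes (>= 1); a size of
#'   1 is a permanent monomer.
#' @param contactDistance intra-cluster nearest-atom distance in
#'   \eqn{\AA}; must be < 2.85.
#' @param separation minimum inter-cluster/monomer distance in \eqn{\AA};
#'   must be > 2.85.
#' @param boxLength cubic box edge in \eqn{\AA}.
#' @param nFrames number of frames.
#' @param persistencePattern optional list of logical vectors (one per
#'   cluster, length `nFrames`): `TRUE` where the cluster is assembled.
#'   Default: assembled in every frame.
#' @param frameInterval ps between frames (default 10).
#' @param seed accepted for interface symmetry; the construction is
#'   deterministic.
#' @return list with `trajectory` and `map`.
#' @export
generateAggregateFixture <- function(clusterSizes, contactDistance = 2.5,
                                     separation = 6, boxLength = 80,
                                     nFrames = 5, persistencePattern = NULL,
                                     frameInterval = 10, seed = 1) {
  stopifnot(length(clusterSizes) >= 1, all(clusterSizes >= 1))
  if (!(contactDistance < 2.85))
    stop("contactDistance must be < 2.85 A (the contact cutoff)")
  if (!(separation > 2.85))
    stop("separation must be > 2.85 A (the contact cutoff)")
  nClusters <- length(clusterSizes)
  if (is.null(persistencePattern))
    persistencePattern <- rep(list(rep(TRUE, nFrames)), nClusters)
  stopifnot(length(persistencePattern) == nClusters,
            all(vapply(persistencePattern, length, 1L) == nFrames))
  bond <- 1.0  # intra-solute atom spacing
  nSol <- sum(clusterSizes)
  rowY <- separation + 2 * bond
  # assembled chain: solute j occupies x in [xj, xj + bond]
  pitch <- bond + contactDistance
  margin <- 2
  chainExtent <- function(s) (s - 1) * pitch + bond
  monoPitch <- separation + bond + 1
  monoExtent <- function(s) (s - 1) * monoPitch + bond
  maxExtent <- max(vapply(clusterSizes, function(s)
    max(chainExtent(s), monoExtent(s)), 1))
  if (margin + maxExtent + separation > boxLength)
    stop("infeasible packing: cluster extent ", round(maxExtent, 2),
         " A does not fit in a ", boxLength, " A box at separation ",
         separation)
  if (nClusters * rowY + separation > boxLength)
    stop("infeasible packing: ", nClusters, " cluster rows do not fit in a ",
         boxLength, " A box")
  groups <- list()
  atom <- 0L
  solOfCluster <- list()
  for (c in seq_len(nClusters)) {
    ids <- integer(clusterSizes[c])
    for (j in seq_len(clusterSizes[c])) {
      groups[[length(groups) + 1L]] <- atom + 1:2
      ids[j] <- length(groups)
      atom <- atom + 2L
    }
    solOfCluster[[c]] <- ids
  }
  nAtomsTot <- atom
  coords <- array(0, c(nAtomsTot, 3, nFrames))
  z <- margin
  for (f in seq_len(nFrames)) {
    for (c in seq_len(nClusters)) {
      y <- margin + (c - 1) * rowY
      assembled <- persistencePattern[[c]][f]
      p <- if (assembled) pitch else monoPitch
      for (j in seq_along(solOfCluster[[c]])) {
        x0 <- margin + (j - 1) * p
        g <- groups[[solOfCluster[[c]][j]]]
        coords[g[1], , f] <- c(x0, y, z)
        coords[g[2], , f] <- c(x0 + bond, y, z)
      }
    }
  }
  traj <- Trajectory(coords, rep(boxLength, 3),
                     frameInterval = frameInterval)
  map <- SystemMap(groups, masses = rep(1, nAtomsTot))
  list(trajectory = traj, map = map)
}

#' Rigid body with analytically known radius of gyration
#'
#' Packages a point set with its radius of gyration evaluated by the
#' direct mass-weighted sum, for use as an oracle against trajectory-based
#' estimators.
#'
#' @param points numeric `n x 3` matrix of positions (\eqn{\AA}).
#' @param masses per-point masses (default unit).
#' @return list with `coords`, `masses` and `rg` (the analytic
#'   \eqn{R_g = \sqrt{\sum m_i |r_i - r_{com}|^2 / \sum m_i}}).
#' @examples
#' rigidBody(rbind(c(-1, 0, 0), c(1, 0, 0)))$rg # 1
#' @export
rigidBody <- function(points, masses = NULL) {
  points <- rbind(points)
  if (nrow(points) < 1L) stop("at least one point required")
  if (is.null(masses)) masses <- rep(1, nrow(points))
  com <- colSums(points * masses) / sum(masses)
  d2 <- rowSums(sweep(points, 2, com)^2)
  list(coords = points, masses = masses,
       rg = sqrt(sum(masses * d2) / sum(masses)))
}
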