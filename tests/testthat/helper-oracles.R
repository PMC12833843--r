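# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: brute-force image enumeration, breadth-first
# reachability, direct formula evaluation.

# Shortest displacement a - b by explicit scan over the 27 periodic image
# translations of b (orthorhombic box).
bruteForceMinimumImage <- function(a, b, box) {
  best <- NULL
  bestN <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- a - (b + c(ix, iy, iz) * box)
    n <- sum(d * d)
    if (n < bestN) { bestN <- n; best <- d }
  }
  best
}

# Minimum distance between two atom sets by all-pairs, all-images scan.
bruteForceGroupDistance <- function(coordsA, coordsB, box) {
  best <- Inf
  for (i in seq_len(nrow(coordsA))) for (j in seq_len(nrow(coordsB))) {
    for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
      d <- coordsA[i, ] - (coordsB[j, ] + c(ix, iy, iz) * box)
      best <- min(best, sqrt(sum(d * d)))
    }
  }
  best
}

# Connected components by breadth-first search over an edge list.
bfsComponents <- function(nVertices, edges) {
  adj <- vector("list", nVertices)
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- rep(FALSE, nVertices)
  comps <- list()
  for (v in seq_len(nVertices)) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      members <- c(members, u)
      for (w in adj[[u]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps[order(vapply(comps, min, 1L))]
}

# A trajectory of single-atom solutes at given per-frame positions.
# positions: list of nSolutes x 3 matrices, one per frame.
makePointTrajectory <- function(positions, box, frameInterval = 10) {
  coords <- array(0, c(nrow(positions[[1]]), 3, length(positions)))
  for (f in seq_along(positions)) coords[, , f] <- positions[[f]]
  Trajectory(coords, box, frameInterval = frameInterval)
}

pointMap <- function(nSolutes, nWaters = 0) {
  SystemMap(as.list(seq_len(nSolutes)),
            waterOxygens = if (nWaters) nSolutes + seq_len(nWaters)
            else integer(0),
            masses = rep(1, nSolutes + nWaters))
}
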