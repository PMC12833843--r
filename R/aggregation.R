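# Minimum-image nearest-atom distance between two atom groups (internal).
.minGroupDistance <- function(fr, g1, g2, box) {
  a <- fr[g1, , drop = FALSE]
  b <- fr[g2, , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- .minimumImageMat(sweep(b, 2, a[i, ], "-"), box)
    best <- min(best, min(rowSums(d * d)))
  }
  sqrt(best)
}

#' Detect solute-solute contacts in one frame
#'
#' Two solute copies are in contact when the minimum-image distance
#' between their nearest atoms does not exceed the cutoff. The default
#' cutoff of 2.85 \eqn{\AA} is the minimum oxygen-oxygen distance in
#' liquid methanol, a natural scale for a hydrogen-bond-mediated
#' carbohydrate contact. All atoms are considered; `heavyOnly` restricts
#' the search to atoms heavier than 1.2 amu.
#'
#' @param traj a [Trajectory-class].
#' @param map a [SystemMap-class] with at least 2 solute groups.
#' @param frame frame index (default 1).
#' @param cutoff contact distance in \eqn{\AA} (default 2.85).
#' @param heavyOnly exclude hydrogens (mass <= 1.2 amu) from the
#'   distance evaluation (default FALSE).
#' @return a [ContactGraph-class].
#' @export
detectContacts <- function(traj, map, frame = 1, cutoff = 2.85,
                           heavyOnly = FALSE) {
  ns <- length(map@soluteGroups)
  if (ns < 2L) stop("at least 2 solute groups required")
  fr <- .frameMatrix(traj@coords, frame)
  box <- traj@box[frame, ]
  groups <- map@soluteGroups
  if (heavyOnly)
    groups <- lapply(groups, function(g) {
      h <- g[map@masses[g] > 1.2]
      if (length(h)) h else g
    })
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      if (.minGroupDistance(fr, groups[[i]], groups[[j]], box) <= cutoff)
        edges <- rbind(edges, c(i, j))
    }
  }
  new("ContactGraph", frameIndex = as.integer(frame),
      edges = matrix(as.integer(edges), ncol = 2), nSolutes = as.integer(ns))
}

#' Connected components of a contact graph
#'
#' An aggregate is the transitive closure of pairwise contacts: the
#' connected component of the contact graph. Singleton components are
#' free monomers.
#'
#' @param graph a [ContactGraph-class].
#' @return list of integer vectors, one per component (a partition of
#'   the solute indices), each sorted; components ordered by smallest
#'   member.
#' @export
clusterFrame <- function(graph) {
  g <- igraph::make_graph(edges = as.vector(t(graph@edges)),
                          n = graph@nSolutes, directed = FALSE)
  memb <- igraph::components(g)$membership
  comps <- unname(split(seq_len(graph@nSolutes), memb))
  comps <- lapply(comps, function(v) as.integer(sort(v)))
  comps[order(vapply(comps, min, 1L))]
}

#' Aggregate kinetics: sizes, lifetimes and concentrations
#'
#' Tracks contact-connected aggregates through a trajectory. An
#' aggregate event is a maximal run of consecutive frames over which an
#' identical solute-membership set is a connected component; any change
#' of membership terminates the event. Events shorter than
#' `minPersistenceFrames` (default 2, the persistence floor applied to
#' transient collisions) are discarded from the aggregate statistics.
#' Free-monomer concentrations are computed from raw per-frame singleton
#' counts, so the per-frame conservation (free monomers + aggregate
#' members = total solutes) holds exactly and independently of the
#' persistence filter.
#'
#' @param traj a [Trajectory-class].
#' @param map a [SystemMap-class].
#' @param cutoff contact distance in \eqn{\AA} (default 2.85).
#' @param minPersistenceFrames minimum event length in frames
#'   (default 2).
#' @param heavyOnly see [detectContacts].
#' @return an [AggregateStats-class]. Lifetimes are reported in ns
#'   (event length x frame interval); concentrations in mM via
#'   [concentrationMM] with the mean box volume.
#' @export
aggregateKinetics <- function(traj, map, cutoff = 2.85,
                              minPersistenceFrames = 2, heavyOnly = FALSE) {
  nf <- nFrames(traj)
  if (nf < minPersistenceFrames)
    stop("need at least ", minPersistenceFrames, " frames")
  dt <- traj@frameInterval
  if (!is.finite(dt) || dt <= 0) stop("frame interval unknown or invalid")
  ns <- length(map@soluteGroups)
  freeCounts <- integer(nf)
  frameKeys <- vector("list", nf)
  keySize <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    comps <- clusterFrame(detectContacts(traj, map, f, cutoff, heavyOnly))
    sizes <- lengths(comps)
    stopifnot(sum(sizes) == ns)  # partition conservation, every frame
    freeCounts[f] <- sum(sizes == 1L)
    agg <- comps[sizes >= 2L]
    keys <- vapply(agg, paste, "", collapse = ",")
    for (k in seq_along(keys)) assign(keys[k], sizes[sizes >= 2L][k], keySize)
    frameKeys[[f]] <- keys
  }
  # maximal runs of identical membership sets
  events <- list()
  active <- list()  # key -> run length
  for (f in seq_len(nf)) {
    keys <- frameKeys[[f]]
    for (key in names(active)) {
      if (!(key %in% keys)) {
        events[[length(events) + 1L]] <- c(get(key, keySize), active[[key]])
        active[[key]] <- NULL
      }
    }
    for (key in keys)
      active[[key]] <- if (is.null(active[[key]])) 1L else active[[key]] + 1L
  }
  for (key in names(active))
    events[[length(events) + 1L]] <- c(get(key, keySize), active[[key]])
  ev <- if (length(events)) do.call(rbind, events) else
    matrix(integer(0), 0, 2)
  colnames(ev) <- c("size", "frames")
  ev <- ev[ev[, "frames"] >= minPersistenceFrames, , drop = FALSE]
  meanVol <- mean(apply(traj@box, 1, prod))
  if (nrow(ev)) {
    bySize <- split(seq_len(nrow(ev)), ev[, "size"])
    sizeTable <- do.call(rbind, lapply(names(bySize), function(s) {
      rows <- bySize[[s]]
      cnt <- sum(ev[rows, "frames"]) / nf
      data.frame(size = as.integer(s), nEvents = length(rows),
                 meanCountPerFrame = cnt,
                 concentration_mM = concentrationMM(cnt, meanVol),
                 meanLifetime_ns = mean(ev[rows, "frames"]) * dt / 1000)
    }))
    meanSize <- sum(ev[, "size"] * ev[, "frames"]) / sum(ev[, "frames"])
    maxSize <- max(ev[, "size"])
  } else {
    sizeTable <- data.frame(size = integer(0), nEvents = integer(0),
                            meanCountPerFrame = numeric(0),
                            concentration_mM = numeric(0),
                            meanLifetime_ns = numeric(0))
    meanSize <- NaN
    maxSize <- 1L
  }
  new("AggregateStats", sizeTable = sizeTable, meanSize = meanSize,
      freeMonomer_mM = concentrationMM(mean(freeCounts), meanVol),
      maxSize = as.integer(maxSize), nFrames = as.integer(nf),
      frameInterval = dt)
}
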