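#' Minimum-image displacement between two points
#'
#' Displacement `a - b` wrapped into the primary image of an orthorhombic
#' periodic cell: each component of the result lies in
#' \eqn{[-L/2, L/2)}. This is the displacement to the nearest periodic
#' image of `b`, the convention under which all interatomic distances
#' (e.g. the 2.85 \eqn{\AA} contact rule) are evaluated.
#'
#' @param a,b numeric length-3 positions in \eqn{\AA}.
#' @param box numeric length-3 box edge lengths in \eqn{\AA}, all > 0.
#' @return numeric length-3 minimum-image displacement.
#' @examples
#' minimumImage(c(9.5, 0, 0), c(0.5, 0, 0), c(10, 10, 10)) # x = -1
#' @export
minimumImage <- function(a, b, box) {
  if (!all(is.finite(a)) || !all(is.finite(b)) || !all(is.finite(box)))
    stop("non-finite input to minimumImage")
  if (any(box <= 0)) stop("box lengths must be > 0")
  d <- a - b
  d - box * floor(d / box + 0.5)
}

# Frame f of a coordinate array as an nAtoms x 3 matrix, robust to
# single-atom systems where plain indexing would drop dimensions.
.frameMatrix <- function(coords, f) matrix(coords[, , f], ncol = 3)

# Row-wise minimum image of a displacement matrix (internal).
.minimumImageMat <- function(d, box) {
  d - sweep(floor(sweep(d, 2, box, "/") + 0.5), 2, box, "*")
}

# Minimum-image distances from one point to rows of a matrix (internal).
.miDistances <- function(point, coords, box) {
  d <- .minimumImageMat(sweep(coords, 2, point, "-"), box)
  sqrt(rowSums(d * d))
}

#' Mass-weighted center of mass
#'
#' @param coords numeric `n x 3` coordinate matrix (\eqn{\AA}).
#' @param masses numeric per-atom masses (amu), positive.
#' @param subset optional integer vector of atom indices; defaults to all.
#' @return numeric length-3 center of mass.
#' @examples
#' centerOfMass(rbind(c(0, 0, 0), c(2, 0, 0)), c(1, 1)) # (1, 0, 0)
#' @export
centerOfMass <- function(coords, masses, subset = NULL) {
  if (!is.null(subset)) {
    if (length(subset) == 0L) stop("empty atom subset")
    coords <- coords[subset, , drop = FALSE]
    masses <- masses[subset]
  }
  if (nrow(coords) == 0L) stop("empty atom subset")
  if (any(masses <= 0)) stop("masses must be positive")
  colSums(coords * masses) / sum(masses)
}

#' Unwrap a periodic trajectory into continuous coordinates
#'
#' Removes box-crossing jumps so that every atom (and hence every solute
#' center of mass) follows a continuous path, as required before
#' mean-squared-displacement analysis. Each consecutive displacement is
#' replaced by its minimum image and accumulated from the first frame.
#' This presumes frames are saved fast enough that no true displacement
#' reaches half a box length between frames.
#'
#' @param traj a [Trajectory-class] with wrapped coordinates.
#' @param map a [SystemMap-class]; solute-group center-of-mass jumps are
#'   checked against half the box as a sampling guard.
#' @return a [Trajectory-class] with continuous coordinates. Re-wrapping
#'   modulo the box recovers the input.
#' @export
unwrapTrajectory <- function(traj, map = NULL) {
  nf <- nFrames(traj)
  out <- traj@coords
  if (nf < 2L) return(traj)
  for (f in 2:nf) {
    box <- traj@box[f, ]
    d <- .minimumImageMat(.frameMatrix(traj@coords, f) -
                            .frameMatrix(traj@coords, f - 1), box)
    out[, , f] <- .frameMatrix(out, f - 1) + d
    if (!is.null(map)) {
      for (s in seq_along(map@soluteGroups)) {
        g <- map@soluteGroups[[s]]
        jump <- centerOfMass(.frameMatrix(out, f), map@masses, g) -
          centerOfMass(.frameMatrix(out, f - 1), map@masses, g)
        if (any(abs(jump) >= box / 2))
          stop("solute ", s, " moved >= half box between frames ",
               f - 1, " and ", f, "; frames are too sparse to unwrap")
      }
    }
  }
  new("Trajectory", coords = out, box = traj@box, times = traj@times,
      frameInterval = traj@frameInterval)
}

#' Wrap coordinates into the primary periodic cell
#'
#' @param traj a [Trajectory-class].
#' @return a [Trajectory-class] with all coordinates in `[0, L)` per
#'   dimension.
#' @export
wrapTrajectory <- function(traj) {
  out <- traj@coords
  for (f in seq_len(nFrames(traj))) {
    box <- traj@box[f, ]
    out[, , f] <- sweep(.frameMatrix(out, f), 2, box,
                        function(x, L) x - L * floor(x / L))
  }
  new("Trajectory", coords = out, box = traj@box, times = traj@times,
      frameInterval = traj@frameInterval)
}

# Per-frame solute center-of-mass paths: nSolutes x 3 x nFrames (internal).
.comPaths <- function(traj, map) {
  ns <- length(map@soluteGroups)
  nf <- nFrames(traj)
  out <- array(0, c(ns, 3, nf))
  for (f in seq_len(nf)) {
    fr <- .frameMatrix(traj@coords, f)
    for (s in seq_len(ns))
      out[s, , f] <- centerOfMass(fr, map@masses, map@soluteGroups[[s]])
  }
  out
}
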