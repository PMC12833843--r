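#' Accessors for Trajectory objects
#'
#' @param x a [Trajectory-class].
#' @param i frame index.
#' @return `nFrames`/`nAtoms`: integer counts. `frameCoords`: `nAtoms x 3`
#'   matrix (\eqn{\AA}). `boxLengths`: length-3 vector (or `nFrames x 3`
#'   matrix when `i` is missing). `frameTimes`: numeric vector (ps).
#'   `frameInterval`: scalar (ps).
#' @name Trajectory-accessors
NULL

#' @rdname Trajectory-accessors
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' @rdname Trajectory-accessors
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])

#' @rdname Trajectory-accessors
setMethod("frameCoords", "Trajectory", function(x, i) x@coords[, , i, drop = TRUE])

#' @rdname Trajectory-accessors
setMethod("boxLengths", "Trajectory", function(x, i) {
  if (missing(i)) x@box else x@box[i, ]
})

#' @rdname Trajectory-accessors
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname Trajectory-accessors
setMethod("frameInterval", "Trajectory", function(x) x@frameInterval)

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nAtoms(object), "atoms,", nFrames(object), "frames\n")
  cat("  time span:", object@times[1], "-", object@times[length(object@times)],
      "ps (interval", object@frameInterval, "ps)\n")
  b <- object@box[1, ]
  cat(sprintf("  box (frame 1): %.2f x %.2f x %.2f A\n", b[1], b[2], b[3]))
})

#' Accessors for SystemMap objects
#'
#' @param x a [SystemMap-class].
#' @return `soluteGroups`: list of integer vectors. `nSolutes`: integer.
#'   `waterOxygens`: integer vector. `atomMasses`: numeric vector (amu).
#' @name SystemMap-accessors
NULL

#' @rdname SystemMap-accessors
setMethod("soluteGroups", "SystemMap", function(x) x@soluteGroups)

#' @rdname SystemMap-accessors
setMethod("nSolutes", "SystemMap", function(x) length(x@soluteGroups))

#' @rdname SystemMap-accessors
setMethod("waterOxygens", "SystemMap", function(x) x@waterOxygens)

#' @rdname SystemMap-accessors
setMethod("atomMasses", "SystemMap", function(x) x@masses)

#' @rdname SystemMap-accessors
setMethod("nAtoms", "SystemMap", function(x) length(x@masses))

setMethod("show", "SystemMap", function(object) {
  cat("SystemMap:", length(object@masses), "atoms,",
      length(object@soluteGroups), "solute copies,",
      length(object@waterOxygens), "water oxygens\n")
})

setMethod("show", "SolventModel", function(object) {
  cat(sprintf("SolventModel '%s': eta = %g kg/m s, T = %g K\n",
              object@name, object@viscosity, object@temperature))
})

setMethod("show", "MSDSeries", function(object) {
  cat("MSDSeries:", length(object@lagTimes), "lags up to",
      max(object@lagTimes), "ps")
  if (ncol(object@perReplicate) > 0)
    cat(",", ncol(object@perReplicate), "replicates")
  cat("\n")
})

setMethod("show", "DiffusionEstimate", function(object) {
  cat(sprintf("DiffusionEstimate: D = %.4f +/- %.4f x 1e-9 m^2/s\n",
              object@D, object@stderr))
  cat(sprintf("  fit window: %.1f - %.1f ps (%d-dimensional)\n",
              object@fitWindow[1], object@fitWindow[2], object@nDimensions))
  if (length(object@replicateValues))
    cat(sprintf("  replicates: n = %d, sd = %.4f\n",
                length(object@replicateValues), sd(object@replicateValues)))
  if (object@flagged)
    cat("  WARNING: nonpositive fitted slope; estimate is not physical\n")
})

setMethod("show", "RDFProfile", function(object) {
  cat("RDFProfile:", length(object@binCenters), "bins up to",
      sprintf("%.2f", max(object@binCenters)), "A, rho =",
      format(object@rho, digits = 4), "waters/A^3\n")
})

setMethod("show", "OccupancyGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("OccupancyGrid: %d x %d x %d voxels, spacing %.3g A, sigma %.3g A\n",
              d[1], d[2], d[3], object@spacing, object@sigma))
})

setMethod("show", "ContactGraph", function(object) {
  cat("ContactGraph: frame", object@frameIndex, "-", nrow(object@edges),
      "contacts among", object@nSolutes, "solutes\n")
})

setMethod("show", "AggregateStats", function(object) {
  cat("AggregateStats over", object@nFrames, "frames:\n")
  cat(sprintf("  mean aggregate size S = %.2f, max size = %d\n",
              object@meanSize, object@maxSize))
  cat(sprintf("  free monomer concentration = %.2f mM\n",
              object@freeMonomer_mM))
  if (nrow(object@sizeTable)) print(object@sizeTable, row.names = FALSE)
})
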