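#' @rdname Trajectory-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("boxLengths", function(x, i) standardGeneric("boxLengths"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname Trajectory-accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname SystemMap-accessors
#' @export
setGeneric("soluteGroups", function(x) standardGeneric("soluteGroups"))

#' @rdname SystemMap-accessors
#' @export
setGeneric("nSolutes", function(x) standardGeneric("nSolutes"))

#' @rdname SystemMap-accessors
#' @export
setGeneric("waterOxygens", function(x) standardGeneric("waterOxygens"))

#' @rdname SystemMap-accessors
#' @export
setGeneric("atomMasses", function(x) standardGeneric("atomMasses"))

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of a set of atoms from their
#' center of mass. For a [Trajectory-class], the value is computed per
#' frame for one solute group and summarized as mean and standard
#' deviation over frames.
#'
#' @param x a numeric `n x 3` coordinate matrix or a [Trajectory-class].
#' @param ... further arguments passed to methods.
#' @return For a matrix: a scalar (\eqn{\AA}). For a trajectory: a list
#'   with `mean`, `sd` and `perFrame` (\eqn{\AA}).
#' @examples
#' radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0))) # 1
#' @export
setGeneric("radiusOfGyration", function(x, ...)
  standardGeneric("radiusOfGyration"))
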