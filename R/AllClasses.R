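#' Trajectory: ordered frames of coordinates in a periodic orthorhombic box
#'
#' Container for a multi-frame solution trajectory. Coordinates are stored
#' as an `nAtoms x 3 x nFrames` array in \eqn{\AA}; each frame carries its
#' own orthorhombic box edge lengths (\eqn{\AA}) and a timestamp (ps).
#' Only orthorhombic cells are supported; triclinic input is rejected at
#' read time.
#'
#' @slot coords numeric array, `nAtoms x 3 x nFrames`, \eqn{\AA}.
#' @slot box numeric matrix, `nFrames x 3`, box edge lengths in \eqn{\AA}.
#' @slot times numeric vector of frame times in ps, strictly increasing.
#' @slot frameInterval numeric scalar, nominal spacing between saved
#'   frames in ps.
#' @export
setClass("Trajectory",
  representation(coords = "array", box = "matrix", times = "numeric",
                 frameInterval = "numeric"),
  validity = function(object) {
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L)
      return("'coords' must be an nAtoms x 3 x nFrames array")
    nf <- d[3]
    if (!all(is.finite(object@coords)))
      return("coordinates must be finite")
    if (nrow(object@box) != nf || ncol(object@box) != 3L)
      return("'box' must be an nFrames x 3 matrix")
    if (!all(is.finite(object@box)) || any(object@box <= 0))
      return("box lengths must be finite and > 0")
    if (length(object@times) != nf)
      return("'times' must have one entry per frame")
    if (nf > 1 && any(diff(object@times) <= 0))
      return("frame times must be strictly increasing")
    if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
      return("'frameInterval' must be a single positive value")
    TRUE
  })

#' Construct a Trajectory
#'
#' @param coords `nAtoms x 3 x nFrames` array (\eqn{\AA}). A single-frame
#'   `nAtoms x 3` matrix is promoted to a one-frame array.
#' @param box per-frame box lengths: a length-3 vector (recycled over
#'   frames) or an `nFrames x 3` matrix, \eqn{\AA}.
#' @param times frame times in ps; defaults to
#'   `(0:(nFrames-1)) * frameInterval`.
#' @param frameInterval saved-frame spacing in ps (default 10, the
#'   spacing at which the reference solution trajectories were saved).
#' @return a [Trajectory-class] object.
#' @export
Trajectory <- function(coords, box, times = NULL, frameInterval = 10) {
  if (is.matrix(coords)) coords <- array(coords, c(dim(coords), 1L))
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (is.null(times)) times <- (seq_len(nf) - 1) * frameInterval
  new("Trajectory", coords = coords, box = box, times = as.numeric(times),
      frameInterval = frameInterval)
}

#' SystemMap: assignment of atoms to solute copies and water oxygens
#'
#' Maps atom indices of a [Trajectory-class] onto solute copies and water
#' oxygen atoms, and carries per-atom masses (amu). Indices are 1-based
#' inside R; the on-disk grouping format uses 0-based indices (see
#' [readSystemMap]).
#'
#' @slot soluteGroups list of integer vectors, one per solute copy;
#'   pairwise disjoint.
#' @slot waterOxygens integer vector of water oxygen atom indices,
#'   disjoint from all solute groups.
#' @slot masses numeric vector of per-atom masses in amu, all > 0; its
#'   length defines the atom count of the system.
#' @export
setClass("SystemMap",
  representation(soluteGroups = "list", waterOxygens = "integer",
                 masses = "numeric"),
  validity = function(object) {
    n <- length(object@masses)
    if (n == 0L) return("'masses' must be nonempty")
    if (any(!is.finite(object@masses)) || any(object@masses <= 0))
      return("masses must be finite and > 0")
    idx <- unlist(object@soluteGroups, use.names = FALSE)
    if (length(object@soluteGroups) &&
        !all(vapply(object@soluteGroups, function(g)
          length(g) > 0 && all(g >= 1L & g <= n), logical(1))))
      return("solute group indices must be nonempty and within atom count")
    if (anyDuplicated(idx))
      return("solute groups must be pairwise disjoint")
    if (length(object@waterOxygens)) {
      if (!all(object@waterOxygens >= 1L & object@waterOxygens <= n))
        return("water oxygen indices out of range")
      if (any(object@waterOxygens %in% idx))
        return("water oxygens must be disjoint from solute groups")
      if (anyDuplicated(object@waterOxygens))
        return("duplicated water oxygen indices")
    }
    TRUE
  })

#' Construct a SystemMap
#'
#' @param soluteGroups list of 1-based integer vectors, one per solute.
#' @param waterOxygens 1-based integer vector of water oxygen indices.
#' @param masses per-atom masses in amu; defaults to unit masses for
#'   `nAtoms` atoms.
#' @param nAtoms atom count, needed only when `masses` is not given.
#' @return a [SystemMap-class] object.
#' @export
SystemMap <- function(soluteGroups, waterOxygens = integer(0), masses = NULL,
                      nAtoms = NULL) {
  soluteGroups <- lapply(soluteGroups, function(g) as.integer(sort(g)))
  waterOxygens <- as.integer(sort(waterOxygens))
  if (is.null(masses)) {
    if (is.null(nAtoms))
      nAtoms <- max(c(unlist(soluteGroups), waterOxygens, 0L))
    masses <- rep(1, nAtoms)
  }
  new("SystemMap", soluteGroups = soluteGroups, waterOxygens = waterOxygens,
      masses = as.numeric(masses))
}

#' SolventModel: viscosity and temperature of the surrounding solvent
#'
#' Holds the solvent viscosity \eqn{\eta} (kg m\eqn{^{-1}} s\eqn{^{-1}})
#' and temperature (K) entering the Stokes-Einstein relation. Built-in
#' models at 298 K: experimental water (\eqn{\eta} = 0.00089), TIP5P
#' (0.0007) and OPC (0.00079) kg/m s.
#'
#' @slot name character label.
#' @slot viscosity numeric, kg m^-1 s^-1, > 0.
#' @slot temperature numeric, K, > 0.
#' @export
setClass("SolventModel",
  representation(name = "character", viscosity = "numeric",
                 temperature = "numeric"),
  validity = function(object) {
    if (length(object@viscosity) != 1L || !is.finite(object@viscosity) ||
        object@viscosity <= 0)
      return("viscosity must be a single positive value")
    if (length(object@temperature) != 1L || !is.finite(object@temperature) ||
        object@temperature <= 0)
      return("temperature must be a single positive value")
    TRUE
  })

#' Construct a SolventModel
#'
#' @param name `"water"` (experimental, eta = 0.00089 kg/m s), `"tip5p"`
#'   (0.0007), `"opc"` (0.00079), all at 298 K, or any label when
#'   `viscosity` is supplied explicitly.
#' @param viscosity viscosity in kg m^-1 s^-1 (overrides the built-in).
#' @param temperature temperature in K (default 298).
#' @return a [SolventModel-class] object.
#' @examples
#' solventModel("water")
#' solventModel("tip3p-like", viscosity = 0.0003)
#' @export
solventModel <- function(name = "water", viscosity = NULL, temperature = 298) {
  builtins <- c(water = 0.00089, tip5p = 0.0007, opc = 0.00079)
  if (is.null(viscosity)) {
    key <- tolower(name)
    if (!key %in% names(builtins))
      stop("unknown solvent model '", name,
           "'; supply 'viscosity' or use one of: ",
           paste(names(builtins), collapse = ", "))
    viscosity <- unname(builtins[key])
  }
  new("SolventModel", name = name, viscosity = viscosity,
      temperature = temperature)
}

#' MSDSeries: mean squared displacement versus lag time
#'
#' @slot lagTimes numeric vector of lag times in ps, starting at 0,
#'   strictly increasing.
#' @slot msd numeric vector of ensemble-mean squared displacements in
#'   \eqn{\AA^2}; `msd[1] == 0` at lag 0.
#' @slot perReplicate numeric matrix (`length(lagTimes)` x nReplicates)
#'   of per-replicate MSD curves, possibly 0-column.
#' @export
setClass("MSDSeries",
  representation(lagTimes = "numeric", msd = "numeric",
                 perReplicate = "matrix"),
  validity = function(object) {
    if (length(object@lagTimes) != length(object@msd))
      return("lagTimes and msd must have equal length")
    if (length(object@lagTimes) && object@lagTimes[1] != 0)
      return("lag times must start at 0")
    if (any(diff(object@lagTimes) <= 0))
      return("lag times must be strictly increasing")
    if (length(object@msd) && abs(object@msd[1]) > 1e-12)
      return("msd at lag 0 must be 0")
    if (any(object@msd < -1e-12))
      return("msd must be nonnegative")
    if (ncol(object@perReplicate) > 0 &&
        nrow(object@perReplicate) != length(object@lagTimes))
      return("perReplicate must have one row per lag")
    TRUE
  })

#' DiffusionEstimate: fitted diffusion coefficient with uncertainty
#'
#' @slot D numeric, diffusion coefficient in 1e-9 m^2/s.
#' @slot stderr numeric, regression standard error of D, same units.
#' @slot fitWindow numeric length-2, lag-time window (ps) used for the fit.
#' @slot nDimensions integer, dimensionality of the displacement (3).
#' @slot replicateValues numeric, per-replicate D values (may be empty).
#' @slot flagged logical, TRUE when the fitted slope was nonpositive.
#' @export
setClass("DiffusionEstimate",
  representation(D = "numeric", stderr = "numeric", fitWindow = "numeric",
                 nDimensions = "integer", replicateValues = "numeric",
                 flagged = "logical"))

#' RDFProfile: radial distribution function of water oxygens about a solute
#'
#' @slot binCenters numeric, bin centers in \eqn{\AA}.
#' @slot g numeric, raw g(r) per bin (>= 0).
#' @slot gSmooth numeric, Savitzky-Golay smoothed g(r) used for locating
#'   shell extrema.
#' @slot rho numeric, bulk water-oxygen number density in \eqn{\AA^{-3}}.
#' @export
setClass("RDFProfile",
  representation(binCenters = "numeric", g = "numeric", gSmooth = "numeric",
                 rho = "numeric"),
  validity = function(object) {
    if (length(object@binCenters) != length(object@g))
      return("binCenters and g must have equal length")
    if (any(object@g < 0)) return("g(r) must be nonnegative")
    if (object@rho <= 0) return("rho must be positive")
    TRUE
  })

#' OccupancyGrid: time-averaged Gaussian-weighted water occupancy density
#'
#' Voxel values are probability densities (\eqn{\AA^{-3}}) for observing a
#' water oxygen, each deposited water contributing a normalized Gaussian.
#'
#' @slot origin numeric length-3, position of the center of voxel
#'   (1,1,1) in \eqn{\AA} (solute-aligned frame).
#' @slot spacing numeric scalar, voxel edge in \eqn{\AA} (default 0.25).
#' @slot values numeric 3-D array of nonnegative densities.
#' @slot sigma numeric, Gaussian deposition width in \eqn{\AA}.
#' @slot isovalues numeric, suggested display isovalues as fractions of
#'   the maximum (metadata only).
#' @export
setClass("OccupancyGrid",
  representation(origin = "numeric", spacing = "numeric", values = "array",
                 sigma = "numeric", isovalues = "numeric"),
  validity = function(object) {
    if (length(object@origin) != 3L) return("origin must have length 3")
    if (object@spacing <= 0) return("spacing must be > 0")
    if (length(dim(object@values)) != 3L)
      return("values must be a 3-D array")
    if (any(!is.finite(object@values)) || any(object@values < -1e-12))
      return("grid values must be finite and nonnegative")
    TRUE
  })

#' ContactGraph: solute-solute contacts in one frame
#'
#' An edge joins two solute copies whose minimum-image nearest-atom
#' distance does not exceed the contact cutoff (default 2.85 \eqn{\AA},
#' the minimum oxygen-oxygen distance in liquid methanol).
#'
#' @slot frameIndex integer, frame the graph was computed from.
#' @slot edges integer matrix with two columns (i, j), i < j, no
#'   self-edges.
#' @slot nSolutes integer, number of solute copies (vertices).
#' @export
setClass("ContactGraph",
  representation(frameIndex = "integer", edges = "matrix",
                 nSolutes = "integer"),
  validity = function(object) {
    e <- object@edges
    if (ncol(e) != 2L) return("edges must have two columns")
    if (nrow(e)) {
      if (any(e[, 1] == e[, 2])) return("self-edges are not allowed")
      if (any(e < 1L) || any(e > object@nSolutes))
        return("edge endpoints out of range")
    }
    TRUE
  })

#' AggregateStats: aggregate sizes, lifetimes and concentrations
#'
#' @slot sizeTable data.frame with one row per aggregate size >= 2 that
#'   survived the persistence filter: `size`, `nEvents`,
#'   `meanCountPerFrame`, `concentration_mM`, `meanLifetime_ns`.
#' @slot meanSize numeric, event-frame-weighted mean aggregate size (S).
#' @slot freeMonomer_mM numeric, mean concentration of solutes that are
#'   singletons in a frame.
#' @slot maxSize integer, largest surviving aggregate (1 if none).
#' @slot nFrames integer, frames analyzed.
#' @slot frameInterval numeric, ps between frames.
#' @export
setClass("AggregateStats",
  representation(sizeTable = "data.frame", meanSize = "numeric",
                 freeMonomer_mM = "numeric", maxSize = "integer",
                 nFrames = "integer", frameInterval = "numeric"))

#' BrownianSpec: parameters of a synthetic Brownian trajectory
#'
#' Defaults reproduce the reference study conditions: 20 solute copies in
#' a cubic cell of 664,424 \eqn{\AA^3} (edge 87.34 \eqn{\AA}, 50 mM),
#' frames saved every 10 ps, 1000 frames (10 ns) per replicate.
#'
#' @slot nSolutes integer, number of independent Brownian solutes.
#' @slot DTrue numeric, ground-truth diffusion coefficient in 1e-9 m^2/s.
#' @slot frameInterval numeric, ps between saved frames.
#' @slot nFrames integer, number of frames (>= 2).
#' @slot boxLength numeric, cubic box edge in \eqn{\AA}.
#' @slot seed integer, RNG seed.
#' @export
setClass("BrownianSpec",
  representation(nSolutes = "integer", DTrue = "numeric",
                 frameInterval = "numeric", nFrames = "integer",
                 boxLength = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@DTrue < 0) return("DTrue must be >= 0")
    if (object@nFrames < 2L) return("nFrames must be >= 2")
    if (object@boxLength <= 0) return("boxLength must be > 0")
    if (object@nSolutes < 1L) return("nSolutes must be >= 1")
    if (object@frameInterval <= 0) return("frameInterval must be > 0")
    TRUE
  })

#' Construct a BrownianSpec
#'
#' @param nSolutes solute copies (default 20).
#' @param DTrue ground-truth D in 1e-9 m^2/s (default 0.62, the
#'   experimental value for glucose at 50 mM).
#' @param frameInterval ps between frames (default 10).
#' @param nFrames frames per replicate (default 1000, i.e. 10 ns).
#' @param boxLength cubic box edge in \eqn{\AA} (default 87.34, a
#'   664,424 \eqn{\AA^3} cell giving 50 mM for 20 copies).
#' @param seed RNG seed.
#' @return a [BrownianSpec-class].
#' @export
brownianSpec <- function(nSolutes = 20, DTrue = 0.62, frameInterval = 10,
                         nFrames = 1000, boxLength = 664424^(1 / 3),
                         seed = 1) {
  new("BrownianSpec", nSolutes = as.integer(nSolutes), DTrue = DTrue,
      frameInterval = frameInterval, nFrames = as.integer(nFrames),
      boxLength = boxLength, seed = as.integer(seed))
}
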