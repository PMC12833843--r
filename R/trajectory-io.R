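#' Read a trajectory from extended-XYZ or multi-MODEL PDB
#'
#' Extended XYZ is the canonical interchange format: per frame, an atom
#' count line, a comment line carrying the orthorhombic cell (either
#' `Lattice="ax 0 0 0 by 0 0 0 cz"` or `box a b c`) and optionally
#' `Time=<ps>`, then one `element x y z` line per atom. PDB files are
#' read via their `CRYST1` record and `MODEL`/`ENDMDL` frames.
#' Triclinic cells are rejected. Malformed records raise errors naming
#' the offending line.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"xyz"` or `"pdb"`.
#' @param frameInterval frame spacing in ps, used when the file carries
#'   no time stamps (default 10).
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, format = c("auto", "xyz", "pdb"),
                           frameInterval = 10) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "xyz"
  }
  if (format == "xyz") .readXYZ(path, frameInterval)
  else .readPDB(path, frameInterval)
}

.parseLattice <- function(comment, path, lineNo) {
  m <- regmatches(comment, regexpr('Lattice="[^"]+"', comment))
  if (length(m) == 1L) {
    vals <- suppressWarnings(as.numeric(strsplit(
      sub('Lattice="([^"]+)"', "\\1", m), "[[:space:]]+")[[1]]))
    vals <- vals[!is.na(vals)]
    if (length(vals) != 9L)
      stop(path, ":", lineNo, ": Lattice must contain 9 numbers")
    M <- matrix(vals, 3, 3, byrow = TRUE)
    off <- M[row(M) != col(M)]
    if (any(abs(off) > 1e-8))
      stop(path, ":", lineNo,
           ": triclinic cells are not supported (off-diagonal lattice terms)")
    return(diag(M))
  }
  m2 <- regmatches(comment,
    regexpr("box[[:space:]]+[-0-9.eE+]+[[:space:]]+[-0-9.eE+]+[[:space:]]+[-0-9.eE+]+",
            comment))
  if (length(m2) == 1L) {
    vals <- as.numeric(strsplit(m2, "[[:space:]]+")[[1]][2:4])
    return(vals)
  }
  stop(path, ":", lineNo, ": missing box record (Lattice=... or box a b c)")
}

.readXYZ <- function(path, frameInterval) {
  lines <- readLines(path)
  i <- 1L
  coordsList <- list()
  boxList <- list()
  times <- numeric(0)
  natoms <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0L)
      stop(path, ":", i, ": expected atom count, got '", lines[i], "'")
    if (is.na(natoms)) natoms <- n
    else if (n != natoms)
      stop(path, ":", i, ": inconsistent atom count (", n, " vs ", natoms, ")")
    if (i + 1L + n > length(lines))
      stop(path, ":", i, ": truncated frame")
    comment <- lines[i + 1L]
    box <- .parseLattice(comment, path, i + 1L)
    tm <- regmatches(comment, regexpr("Time=[-0-9.eE+]+", comment))
    frameTime <- if (length(tm) == 1L) as.numeric(sub("Time=", "", tm)) else NA
    xyz <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      parts <- strsplit(trimws(lines[i + 1L + k]), "[[:space:]]+")[[1]]
      if (length(parts) < 4L)
        stop(path, ":", i + 1L + k, ": unparseable atom line")
      v <- suppressWarnings(as.numeric(parts[2:4]))
      if (any(is.na(v)))
        stop(path, ":", i + 1L + k, ": non-numeric coordinates")
      xyz[k, ] <- v
    }
    coordsList[[length(coordsList) + 1L]] <- xyz
    boxList[[length(boxList) + 1L]] <- box
    times <- c(times, frameTime)
    i <- i + 2L + n
  }
  if (!length(coordsList)) stop(path, ": no frames found")
  if (all(is.na(times))) times <- (seq_along(coordsList) - 1) * frameInterval
  else if (any(is.na(times)))
    stop(path, ": Time= present in some frames but not all")
  nf <- length(coordsList)
  coords <- array(unlist(coordsList), c(natoms, 3, nf))
  if (nf > 1) {
    dts <- diff(times)
    if (all(abs(dts - dts[1]) < 1e-9)) frameInterval <- dts[1]
  }
  Trajectory(coords, do.call(rbind, boxList), times, frameInterval)
}

.readPDB <- function(path, frameInterval) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines)
  if (!length(cr)) stop(path, ": missing CRYST1 record")
  rec <- lines[cr[1]]
  box <- as.numeric(c(substr(rec, 7, 15), substr(rec, 16, 24),
                      substr(rec, 25, 33)))
  ang <- as.numeric(c(substr(rec, 34, 40), substr(rec, 41, 47),
                      substr(rec, 48, 54)))
  if (any(is.na(box)) || any(box <= 0))
    stop(path, ":", cr[1], ": unparseable CRYST1 cell lengths")
  if (any(abs(ang - 90) > 1e-6))
    stop(path, ":", cr[1], ": triclinic cells are not supported")
  atomLines <- grep("^(ATOM  |HETATM)", lines)
  if (!length(atomLines)) stop(path, ": no ATOM/HETATM records")
  modelStarts <- grep("^MODEL", lines)
  frames <- if (length(modelStarts)) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(modelStarts))
      stop(path, ": unbalanced MODEL/ENDMDL records")
    Map(function(a, b) atomLines[atomLines > a & atomLines < b],
        modelStarts, ends)
  } else list(atomLines)
  natoms <- length(frames[[1]])
  coords <- array(NA_real_, c(natoms, 3, length(frames)))
  for (f in seq_along(frames)) {
    idx <- frames[[f]]
    if (length(idx) != natoms)
      stop(path, ": inconsistent atom count in MODEL ", f)
    for (k in seq_along(idx)) {
      ln <- lines[idx[k]]
      v <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
      if (any(is.na(v)))
        stop(path, ":", idx[k], ": unparseable coordinates")
      coords[k, , f] <- v
    }
  }
  Trajectory(coords, box, frameInterval = frameInterval)
}

#' Write a trajectory as extended XYZ
#'
#' @param traj a [Trajectory-class].
#' @param path output path.
#' @param elements optional character vector of element labels (default
#'   `"X"`).
#' @param digits coordinate precision (default 6 decimal places).
#' @return invisibly, `path`.
#' @export
writeTrajectory <- function(traj, path, elements = NULL, digits = 6) {
  n <- nAtoms(traj)
  if (is.null(elements)) elements <- rep("X", n)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (f in seq_len(nFrames(traj))) {
    b <- traj@box[f, ]
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%.6f 0 0 0 %.6f 0 0 0 %.6f" Time=%.6f Properties=species:S:1:pos:R:3',
      b[1], b[2], b[3], traj@times[f]), con)
    xyz <- traj@coords[, , f]
    writeLines(sprintf(fmt, elements, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read or write a solute/water grouping file
#'
#' Plain-text format, one record per line: `SOLUTE i j k ...` (one line
#' per solute copy), a single optional `WATER_O i j k ...` line, and an
#' optional `MASS m1 m2 ...` line with per-atom masses in amu. Atom
#' indices on disk are 0-based; they are converted to R's 1-based
#' indexing on read.
#'
#' @param path file path.
#' @param nAtoms total atom count of the matching trajectory (used for
#'   validation and for default unit masses).
#' @return a [SystemMap-class].
#' @export
readSystemMap <- function(path, nAtoms) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  groups <- list()
  waters <- integer(0)
  masses <- NULL
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    parts <- strsplit(line, "[[:space:]]+")[[1]]
    key <- parts[1]
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(vals)))
      stop(path, ":", ln, ": non-numeric entry in ", key, " record")
    if (key == "SOLUTE") groups[[length(groups) + 1L]] <- as.integer(vals) + 1L
    else if (key == "WATER_O") waters <- as.integer(vals) + 1L
    else if (key == "MASS") masses <- vals
    else stop(path, ":", ln, ": unknown record '", key, "'")
  }
  if (is.null(masses)) masses <- rep(1, nAtoms)
  if (length(masses) != nAtoms)
    stop(path, ": MASS record has ", length(masses), " entries for ",
         nAtoms, " atoms")
  SystemMap(groups, waters, masses)
}

#' @rdname readSystemMap
#' @param map a [SystemMap-class] to serialize.
#' @export
writeSystemMap <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# CarboDiff grouping file; 0-based atom indices", con)
  for (g in map@soluteGroups)
    writeLines(paste("SOLUTE", paste(g - 1L, collapse = " ")), con)
  if (length(map@waterOxygens))
    writeLines(paste("WATER_O", paste(map@waterOxygens - 1L, collapse = " ")),
               con)
  writeLines(paste("MASS", paste(format(map@masses, trim = TRUE),
                                 collapse = " ")), con)
  invisible(path)
}
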