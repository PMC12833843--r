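# Gaussian cube files store lengths in Bohr.
.BOHR_PER_ANGSTROM <- 1.8897259886

#' Write an occupancy grid as Gaussian cube or OpenDX
#'
#' Serializes an [OccupancyGrid-class] so the density can be inspected in
#' standard molecular viewers. Cube files are written in Bohr (the format
#' convention); OpenDX files stay in \eqn{\AA}. Suggested display
#' isovalues are recorded as comments.
#'
#' @param grid an [OccupancyGrid-class].
#' @param path output path.
#' @param format `"cube"` or `"dx"`.
#' @return invisibly, `path`.
#' @export
writeGrid <- function(grid, path, format = c("cube", "dx")) {
  if (is.character(format) && length(format) == 1L &&
      !format %in% c("cube", "dx"))
    stop("unsupported grid format '", format, "'")
  format <- match.arg(format)
  d <- dim(grid@values)
  if (any(d <= 0)) stop("grid dimensions must be positive")
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "cube") {
    writeLines("CarboDiff water occupancy density", con)
    writeLines(paste("isovalues (fraction of max):",
                     paste(grid@isovalues, collapse = " ")), con)
    o <- grid@origin * .BOHR_PER_ANGSTROM
    sp <- grid@spacing * .BOHR_PER_ANGSTROM
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", 1L, o[1], o[2], o[3]), con)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", d[1], sp, 0, 0), con)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", d[2], 0, sp, 0), con)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", d[3], 0, 0, sp), con)
    # one dummy atom at the grid origin
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", 1L, 0, o[1], o[2],
                       o[3]), con)
    # z fastest, then y, then x
    vals <- aperm(grid@values, c(3, 2, 1))
    flat <- as.vector(vals)  # now x slowest
    for (start in seq(1, length(flat), by = 6)) {
      seg <- flat[start:min(start + 5, length(flat))]
      writeLines(paste(sprintf("%13.5e", seg), collapse = " "), con)
    }
  } else {
    writeLines(sprintf("# CarboDiff water occupancy density; isovalues: %s",
                       paste(grid@isovalues, collapse = " ")), con)
    writeLines(sprintf("object 1 class gridpositions counts %d %d %d",
                       d[1], d[2], d[3]), con)
    writeLines(sprintf("origin %g %g %g", grid@origin[1], grid@origin[2],
                       grid@origin[3]), con)
    writeLines(sprintf("delta %g 0 0", grid@spacing), con)
    writeLines(sprintf("delta 0 %g 0", grid@spacing), con)
    writeLines(sprintf("delta 0 0 %g", grid@spacing), con)
    writeLines(sprintf("object 2 class gridconnections counts %d %d %d",
                       d[1], d[2], d[3]), con)
    writeLines(sprintf(
      "object 3 class array type double rank 0 items %d data follows",
      prod(d)), con)
    flat <- as.vector(aperm(grid@values, c(3, 2, 1)))
    for (start in seq(1, length(flat), by = 3)) {
      seg <- flat[start:min(start + 2, length(flat))]
      writeLines(paste(sprintf("%.6e", seg), collapse = " "), con)
    }
    writeLines('attribute "dep" string "positions"', con)
  }
  invisible(path)
}

#' Read an occupancy grid written by [writeGrid]
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"cube"` or `"dx"`.
#' @return an [OccupancyGrid-class].
#' @export
readGrid <- function(path, format = c("auto", "cube", "dx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "dx") "dx" else "cube"
  lines <- readLines(path)
  if (format == "cube") {
    hdr <- lines[3:6]
    nums <- lapply(strsplit(trimws(hdr), "[[:space:]]+"), as.numeric)
    natoms <- nums[[1]][1]
    origin <- nums[[1]][2:4] / .BOHR_PER_ANGSTROM
    d <- c(nums[[2]][1], nums[[3]][1], nums[[4]][1])
    spacing <- nums[[2]][2] / .BOHR_PER_ANGSTROM
    dataStart <- 6 + abs(natoms) + 1
    flat <- as.numeric(unlist(strsplit(trimws(lines[dataStart:length(lines)]),
                                       "[[:space:]]+")))
    vals <- aperm(array(flat, c(d[3], d[2], d[1])), c(3, 2, 1))
    new("OccupancyGrid", origin = origin, spacing = spacing, values = vals,
        sigma = NA_real_, isovalues = numeric(0))
  } else {
    cnt <- grep("gridpositions counts", lines, value = TRUE)[1]
    d <- as.numeric(tail(strsplit(cnt, "[[:space:]]+")[[1]], 3))
    org <- grep("^origin", lines, value = TRUE)[1]
    origin <- as.numeric(strsplit(org, "[[:space:]]+")[[1]][2:4])
    del <- grep("^delta", lines, value = TRUE)[1]
    spacing <- max(as.numeric(strsplit(del, "[[:space:]]+")[[1]][2:4]))
    dataStart <- grep("data follows", lines)[1] + 1
    dataEnd <- grep("^attribute", lines)
    dataEnd <- if (length(dataEnd)) dataEnd[1] - 1 else length(lines)
    flat <- as.numeric(unlist(strsplit(trimws(lines[dataStart:dataEnd]),
                                       "[[:space:]]+")))
    vals <- aperm(array(flat, c(d[3], d[2], d[1])), c(3, 2, 1))
    new("OccupancyGrid", origin = origin, spacing = spacing, values = vals,
        sigma = NA_real_, isovalues = numeric(0))
  }
}
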