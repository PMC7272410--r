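#' Molecular geometry
#'
#' A light container for a molecular structure: element symbols, Cartesian
#' coordinates in Angstrom, and an optional label naming the critical point
#' it represents (e.g. "FC", "PM", "SB", "DB").
#'
#' @param elements character vector of element symbols
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom
#' @param label optional character label
#' @return an object of class `geometry`
#' @export
geometry <- function(elements, coords, label = "") {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3) {
    stop("coords must be a numeric n x 3 matrix")
  }
  if (length(elements) != nrow(coords)) {
    stop("coordinate array length must equal element count")
  }
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  dimnames(coords) <- NULL
  structure(list(elements = as.character(elements), coords = coords,
                 label = as.character(label)[1]),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> %d atoms%s\n", length(x$elements),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Read a geometry from an XYZ file
#'
#' Standard XYZ layout: atom count, comment line (kept as the label), then
#' one `element x y z` line per atom, coordinates in Angstrom.
#'
#' @param path file path
#' @param frame which frame to read from a multi-frame file (default 1)
#' @return a [geometry()]
#' @export
read_xyz <- function(path, frame = 1L) {
  lines <- readLines(path, warn = FALSE)
  pos <- 1L
  for (fr in seq_len(frame)) {
    if (pos > length(lines) || !nzchar(trimws(lines[pos]))) {
      stop(sprintf("XYZ parse error at line %d: expected atom count", pos))
    }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1) {
      stop(sprintf("XYZ parse error at line %d: malformed atom count '%s'",
                   pos, trimws(lines[pos])))
    }
    if (pos + 1L + n > length(lines)) {
      stop(sprintf(
        "XYZ parse error: file declares %d atoms but ends at line %d",
        n, length(lines)))
    }
    label <- trimws(lines[pos + 1L])
    body <- lines[pos + 1L + seq_len(n)]
    if (fr == frame) {
      elements <- character(n)
      coords <- matrix(NA_real_, n, 3)
      for (i in seq_len(n)) {
        tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
        lineno <- pos + 1L + i
        if (length(tok) < 4) {
          stop(sprintf("XYZ parse error at line %d: expected 'element x y z'",
                       lineno))
        }
        xyz <- suppressWarnings(as.numeric(tok[2:4]))
        if (any(is.na(xyz))) {
          stop(sprintf("XYZ parse error at line %d: non-numeric coordinate",
                       lineno))
        }
        elements[i] <- tok[1]
        coords[i, ] <- xyz
      }
      return(geometry(elements, coords, label))
    }
    pos <- pos + 2L + n
  }
  stop(sprintf("XYZ file has fewer than %d frames", frame))
}

#' Write one geometry (or a list of geometries) to an XYZ file
#'
#' @param g a [geometry()] or a list of them (multi-frame XYZ)
#' @param path output path
#' @param digits coordinate precision (decimal places)
#' @export
write_xyz <- function(g, path, digits = 8) {
  frames <- if (inherits(g, "geometry")) list(g) else g
  out <- character(0)
  for (fr in frames) {
    stopifnot(inherits(fr, "geometry"))
    body <- sprintf(paste0("%-3s %", digits + 6, ".", digits, "f %",
                           digits + 6, ".", digits, "f %", digits + 6, ".",
                           digits, "f"),
                    fr$elements, fr$coords[, 1], fr$coords[, 2],
                    fr$coords[, 3])
    out <- c(out, as.character(length(fr$elements)), fr$label, body)
  }
  writeLines(out, path)
  invisible(path)
}
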