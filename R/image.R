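#' Velocity-map image
#'
#' A 2-D grid of electron counts together with the projection centre and
#' acquisition metadata.  Pixel (0,0) is the top-left corner, x runs
#' rightward (columns), y downward (rows); the laser polarisation axis is the
#' image vertical.  The centre is stored in fractional pixel coordinates and
#' must lie inside the grid.  Counts are real-valued for noiseless
#' expectation images and non-negative integers after sampling.
#'
#' @param counts numeric matrix (rows = y, columns = x)
#' @param centre length-2 numeric `c(cx, cy)` in pixel coordinates
#' @param delay_fs pump-probe delay in fs (metadata)
#' @param n_electrons nominal electrons per frame (metadata)
#' @param seed RNG seed used to sample the frame (metadata)
#' @return object of class `vmi_image`
#' @export
vmi_image <- function(counts, centre = (dim(counts) - 1) / 2,
                      delay_fs = NA_real_, n_electrons = NA_real_,
                      seed = NA_real_) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be a numeric matrix")
  if (!all(is.finite(counts))) stop("image contains non-finite values")
  centre <- as.numeric(centre)
  if (length(centre) != 2) stop("centre must be length 2 (cx, cy)")
  if (centre[1] < 0 || centre[1] > ncol(counts) - 1 ||
      centre[2] < 0 || centre[2] > nrow(counts) - 1) {
    stop("stated centre lies outside the image grid")
  }
  storage.mode(counts) <- "double"
  structure(list(counts = counts, centre = centre,
                 meta = list(delay_fs = as.numeric(delay_fs),
                             n_electrons = as.numeric(n_electrons),
                             seed = as.numeric(seed))),
            class = "vmi_image")
}

#' @export
print.vmi_image <- function(x, ...) {
  cat(sprintf(
    "<vmi_image> %d x %d px, centre (%.2f, %.2f), total %.4g counts%s\n",
    ncol(x$counts), nrow(x$counts), x$centre[1], x$centre[2],
    sum(x$counts),
    if (is.finite(x$meta$delay_fs)) sprintf(", delay %g fs", x$meta$delay_fs)
    else ""))
  invisible(x)
}

#' Write a list of velocity-map images to an HDF5 stack
#'
#' Container layout: one group `frame_%04d` per delay holding the dataset
#' `counts` and the attributes `delay_fs`, `seed`, `n_electrons`, `centre`.
#'
#' @param frames list of [vmi_image()]
#' @param path output `.h5` path (overwritten if present)
#' @export
write_image_stack <- function(frames, path) {
  stopifnot(length(frames) >= 1,
            all(vapply(frames, inherits, TRUE, "vmi_image")))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    gname <- sprintf("frame_%04d", i)
    gid <- rhdf5::H5Gcreate(fid, gname)
    rhdf5::h5writeDataset(fr$counts, gid, "counts")
    rhdf5::h5writeAttribute(fr$meta$delay_fs, gid, "delay_fs")
    rhdf5::h5writeAttribute(fr$meta$seed, gid, "seed")
    rhdf5::h5writeAttribute(fr$meta$n_electrons, gid, "n_electrons")
    rhdf5::h5writeAttribute(fr$centre, gid, "centre")
    rhdf5::H5Gclose(gid)
  }
  invisible(path)
}

#' Read a velocity-map image stack written by [write_image_stack()]
#'
#' @param path `.h5` path
#' @return list of [vmi_image()], ordered by frame group name
#' @export
read_image_stack <- function(path) {
  ls <- rhdf5::h5ls(path, recursive = FALSE)
  groups <- sort(ls$name[ls$otype == "H5I_GROUP"])
  if (length(groups) == 0) stop("no frame groups found in ", path)
  frames <- lapply(groups, function(g) {
    counts <- rhdf5::h5read(path, paste0(g, "/counts"))
    at <- rhdf5::h5readAttributes(path, g)
    for (key in c("delay_fs", "seed", "n_electrons", "centre")) {
      if (is.null(at[[key]])) {
        stop(sprintf("frame %s is missing required attribute '%s'", g, key))
      }
    }
    vmi_image(counts, centre = as.numeric(at$centre),
              delay_fs = as.numeric(at$delay_fs),
              n_electrons = as.numeric(at$n_electrons),
              seed = as.numeric(at$seed))
  })
  rhdf5::h5closeAll()
  frames
}
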