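## Frame model and the built-in plain-text trajectory format.
##
## Built-in format, one block per frame:
##   N_atoms box_x box_y box_z
##   species molecule_id x y z        (N_atoms lines)
## Coordinates in Angstrom; orthorhombic boxes only.  Coordinates are kept in
## a box-centered convention: the solute (and the grid) sit at the origin and
## minimum-image conventions wrap into [-L/2, L/2).

#' Construct a single trajectory frame
#'
#' @param xyz numeric matrix (n_atoms x 3), Angstrom.
#' @param box numeric length-3 vector of orthorhombic box lengths, Angstrom.
#' @param index zero-based frame index.
#' @return Object of class `md_frame`.
#' @export
md_frame <- function(xyz, box, index = 0L) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("box lengths must be three strictly positive finite numbers")
  if (any(!is.finite(xyz))) stop("positions must be finite")
  structure(list(xyz = xyz, box = box, index = as.integer(index)),
            class = "md_frame")
}

#' Read frames from the built-in plain-text trajectory format
#'
#' Reads every frame of a trajectory file into a list of [md_frame()]
#' objects.  Alternative formats plug in through the `reader` argument: any
#' function `f(path, topology)` returning a list of `md_frame`s can stand in
#' for the built-in text reader, keeping external trajectory libraries
#' optional.
#'
#' @param path trajectory file.
#' @param topology a [mixture_topology()]; per-frame atom counts are checked
#'   against it.
#' @param reader optional replacement reader function.
#' @return List of `md_frame` objects, in file order.  An empty file yields
#'   an empty list with a warning.
#' @export
read_frames <- function(path, topology, reader = NULL) {
  if (!is.null(reader)) return(reader(path, topology))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty trajectory file: ", path)
    return(list())
  }
  frames <- list()
  i <- 1L; fidx <- 0L
  n_expect <- topology$n_atoms
  while (i <= length(lines)) {
    hdr <- scan(text = lines[i], what = double(), quiet = TRUE)
    if (length(hdr) != 4L)
      stop("missing or malformed box record at frame ", fidx)
    n <- as.integer(hdr[1L]); box <- hdr[2:4]
    if (n != n_expect)
      stop("atom-count mismatch at frame ", fidx, ": file has ", n,
           ", topology has ", n_expect)
    if (i + n > length(lines))
      stop("truncated frame ", fidx, ": expected ", n, " atom lines")
    block <- lines[(i + 1L):(i + n)]
    fields <- strsplit(trimws(block), "[[:space:]]+")
    xyz <- matrix(as.numeric(unlist(lapply(fields, `[`, 3:5))),
                  ncol = 3L, byrow = TRUE)
    if (any(is.na(xyz))) stop("unparseable coordinates at frame ", fidx)
    frames[[fidx + 1L]] <- md_frame(xyz, box, fidx)
    i <- i + n + 1L
    fidx <- fidx + 1L
  }
  frames
}

#' Write frames in the built-in plain-text trajectory format
#'
#' @param frames list of [md_frame()] objects.
#' @param topology the matching [mixture_topology()].
#' @param path output file.
#' @return `path`, invisibly.  Round-trips with [read_frames()] to better
#'   than 1e-6 Angstrom.
#' @export
write_frames <- function(frames, topology, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  sp <- topology$atoms$species
  mol <- topology$atoms$mol
  for (fr in frames) {
    if (nrow(fr$xyz) != topology$n_atoms)
      stop("frame ", fr$index, " atom count does not match topology")
    writeLines(sprintf("%d %.10g %.10g %.10g", nrow(fr$xyz),
                       fr$box[1], fr$box[2], fr$box[3]), con)
    writeLines(sprintf("%s %d %.10g %.10g %.10g", sp, mol,
                       fr$xyz[, 1], fr$xyz[, 2], fr$xyz[, 3]), con)
  }
  invisible(path)
}

#' Representative point of a molecule in a frame
#'
#' Water maps to its designated center atom (the oxygen, GIST convention —
#' not the center of mass); a monoatomic ion to its single atom; the solute
#' to its first atom.
#'
#' @param frame an [md_frame()].
#' @param molecule molecule id.
#' @param topology a [mixture_topology()].
#' @return Numeric length-3 position (Angstrom).
#' @export
molecule_center <- function(frame, molecule, topology) {
  m <- topology$mol[molecule, ]
  if (is.na(m$mol)) stop("no such molecule: ", molecule)
  frame$xyz[m$center_atom, ]
}

## Internal: centers of all molecules at once (n_mol x 3).
.all_centers <- function(frame, topology) {
  frame$xyz[topology$mol$center_atom, , drop = FALSE]
}

#' Minimum-image displacement and distance
#'
#' Wraps a displacement vector (or matrix of row vectors) into
#' `[-L/2, L/2)` per dimension.
#'
#' @param d displacement vector or n x 3 matrix (Angstrom).
#' @param box orthorhombic box lengths.
#' @return Object of the same shape as `d`.
#' @export
min_image <- function(d, box) {
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d
  } else {
    d - box * round(d / box)
  }
}
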