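## Water orientations as unit quaternions.
##
## A water's orientation is the best-fit rigid rotation (about its center
## atom) mapping the fixed reference geometry onto the observed geometry,
## solved by Horn's quaternion method.  q and -q describe the same rotation;
## quaternions are canonicalized so the first nonzero component is positive.

#' Reference water geometry
#'
#' Fixed internal geometry against which orientations are measured: oxygen at
#' the origin, both hydrogens in the xz-plane symmetric about +z (O-H bond
#' 0.9572 Angstrom, H-O-H angle 104.52 degrees, TIP3P-like).
#'
#' @return 3 x 3 matrix with rows O, H1, H2.
#' @export
water_reference_geometry <- function() {
  b <- 0.9572; half <- (104.52 / 2) * pi / 180
  rbind(O  = c(0, 0, 0),
        H1 = c( b * sin(half), 0, b * cos(half)),
        H2 = c(-b * sin(half), 0, b * cos(half)))
}

#' Canonicalize a quaternion's sign
#'
#' Resolves the q / -q double cover: flips the sign so that the first
#' component exceeding 1e-12 in magnitude is positive.
#'
#' @param q length-4 quaternion (w, x, y, z) or n x 4 matrix.
#' @return Same shape, canonical sign.
#' @export
quat_canonical <- function(q) {
  if (is.matrix(q)) return(t(apply(q, 1L, quat_canonical)))
  i <- which(abs(q) > 1e-12)[1L]
  if (!is.na(i) && q[i] < 0) q <- -q
  q
}

#' Rotation quaternion to rotation matrix
#'
#' @param q unit quaternion (w, x, y, z).
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L, byrow = TRUE)
}

#' Quaternion product
#'
#' Hamilton product `a * b`, composing rotations (apply `b` first, then `a`).
#'
#' @param a,b quaternions (w, x, y, z).
#' @return Length-4 quaternion.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Rotational distance between two orientations
#'
#' The geodesic rotation angle `2*acos(|q1 . q2|)` in radians; invariant
#' under the q / -q sign ambiguity.  This is the Delta-omega entering the
#' orientational and six-dimensional entropy estimators.
#'
#' @param q1,q2 unit quaternions.
#' @return Angle in radians, in `[0, pi]`.
#' @export
delta_omega <- function(q1, q2) {
  2 * acos(min(1, abs(sum(q1 * q2))))
}

#' Orientation of one water molecule
#'
#' Best-fit rotation (about the center atom) from the reference geometry to
#' the observed geometry, as a canonical unit quaternion.  Uses the center
#' atom and the first two non-center atoms of the molecule.
#'
#' @param frame an [md_frame()].
#' @param molecule molecule id (must be tagged `wat`).
#' @param topology a [mixture_topology()].
#' @return Canonical unit quaternion (w, x, y, z).
#' @export
water_orientation <- function(frame, molecule, topology) {
  m <- topology$mol[molecule, ]
  if (is.na(m$mol) || m$species != "wat")
    stop("molecule ", molecule, " is not tagged wat")
  q <- water_orientations(frame, topology, mols = molecule)
  drop(q)
}

#' Orientations of all (or selected) water molecules in a frame
#'
#' Vectorized form of [water_orientation()].
#'
#' @inheritParams water_orientation
#' @param mols molecule ids to process; default all waters.
#' @return n x 4 matrix of canonical unit quaternions.
#' @export
water_orientations <- function(frame, topology, mols = NULL) {
  if (is.null(mols)) mols <- which(topology$mol$species == "wat")
  if (length(mols) == 0L)
    return(matrix(numeric(0), ncol = 4L))
  mt <- topology$mol[mols, ]
  if (any(mt$species != "wat")) stop("all molecules must be tagged wat")
  cidx <- mt$center_atom
  ## first two non-center atoms per molecule (hydrogens for 3-site water)
  o1 <- integer(nrow(mt)); o2 <- integer(nrow(mt))
  for (i in seq_len(nrow(mt))) {
    others <- setdiff(mt$first[i]:mt$last[i], cidx[i])
    o1[i] <- others[1L]; o2[i] <- others[2L]
  }
  ref <- water_reference_geometry()
  q <- cpp_water_quats(frame$xyz, cidx - 1L, o1 - 1L, o2 - 1L,
                       ref[2, ], ref[3, ])
  quat_canonical(q)
}
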