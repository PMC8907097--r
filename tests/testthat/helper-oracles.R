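## Brute-force oracles and small construction helpers shared across tests.
## Oracles are deliberately independent of the package's accelerated paths:
## plain O(N^2) R loops and closed forms.

## Minimum-image pairwise distance matrix (O(N^2)).
bf_dist_matrix <- function(X, box = NULL) {
  n <- nrow(X)
  D2 <- matrix(0, n, n)
  for (d in 1:3) {
    dx <- outer(X[, d], X[, d], "-")
    if (!is.null(box)) dx <- dx - box[d] * round(dx / box[d])
    D2 <- D2 + dx^2
  }
  sqrt(D2)
}

## Brute-force nearest neighbor distances, translational metric.
bf_nn_trans <- function(X, box = NULL) {
  D <- bf_dist_matrix(X, box)
  diag(D) <- Inf
  apply(D, 1L, min)
}

## Rotational distance matrix from quaternions.
bf_dw_matrix <- function(Q) {
  dot <- abs(Q %*% t(Q))
  dot[dot > 1] <- 1
  2 * acos(dot)
}

bf_nn_orient <- function(Q, groups) {
  out <- rep(NA_real_, nrow(Q))
  for (g in unique(groups[!is.na(groups)])) {
    idx <- which(!is.na(groups) & groups == g)
    if (length(idx) < 2L) next
    DW <- bf_dw_matrix(Q[idx, , drop = FALSE])
    diag(DW) <- Inf
    out[idx] <- apply(DW, 1L, min)
  }
  out
}

bf_nn_six <- function(X, Q, box = NULL) {
  D <- bf_dist_matrix(X, box)
  DW <- bf_dw_matrix(Q)
  S <- sqrt(D^2 + DW^2)
  diag(S) <- Inf
  apply(S, 1L, min)
}

## Brute-force radial histogram of nu -> nu' distances (ordered pairs,
## self excluded), over all frames; returns per-bin counts.
bf_rdf_counts <- function(frames, topology, pair, dd, cutoff) {
  n_bins <- as.integer(ceiling(cutoff / dd - 1e-9))
  acc <- numeric(n_bins)
  c1 <- topology$mol$center_atom[topology$mol$species == pair[1L]]
  c2 <- topology$mol$center_atom[topology$mol$species == pair[2L]]
  same <- identical(pair[1L], pair[2L])
  for (fr in frames) {
    X1 <- fr$xyz[c1, , drop = FALSE]
    X2 <- fr$xyz[c2, , drop = FALSE]
    for (i in seq_len(nrow(X1))) {
      d <- X2 - matrix(X1[i, ], nrow(X2), 3L, byrow = TRUE)
      for (k in 1:3) d[, k] <- d[, k] - fr$box[k] * round(d[, k] / fr$box[k])
      r <- sqrt(rowSums(d^2))
      if (same) r <- r[-i]
      r <- r[r < cutoff]
      if (length(r) > 0L)
        acc <- acc + tabulate(floor(r / dd) + 1L, nbins = n_bins)
    }
  }
  acc
}

## Axis-angle rotation matrix (independent of the quaternion code).
bf_rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3L, 3L, byrow = TRUE)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Tiny two-species topology with explicit nonbonded parameters on each
## molecule, for energy bookkeeping tests.
make_param_topology <- function(n_wat = 2, n_cation = 0, n_anion = 0,
                                wat_charge = 0, wat_sigma = 3.0,
                                wat_epsilon = 0.2) {
  at <- function(name, q, s, e, m)
    data.frame(name = name, charge = q, sigma = s, epsilon = e, mass = m,
               stringsAsFactors = FALSE)
  types <- list(
    SOL = list(atoms = at("S1", 0, 0, 0, 12.0)),
    WAT = list(atoms = rbind(at("O", wat_charge, wat_sigma, wat_epsilon,
                                15.999),
                             at("H1", 0, 0, 0, 1.008),
                             at("H2", 0, 0, 0, 1.008))),
    CAT = list(atoms = at("M", 1, 2.3, 0.1, 22.99)),
    ANI = list(atoms = at("X", -1, 3.8, 0.1, 35.45)))
  blocks <- list(list(type = "SOL", count = 1L))
  if (n_wat > 0) blocks <- c(blocks, list(list(type = "WAT", count = n_wat)))
  if (n_cation > 0)
    blocks <- c(blocks, list(list(type = "CAT", count = n_cation)))
  if (n_anion > 0)
    blocks <- c(blocks, list(list(type = "ANI", count = n_anion)))
  mixture_topology(types, blocks,
                   c(SOL = "solute", WAT = "wat", CAT = "cation",
                     ANI = "anion"))
}

## Place waters (by center + orientation) and ions into a frame for a
## make_param_topology() topology.
make_frame <- function(topology, centers, box, quats = NULL, index = 0L) {
  ref <- water_reference_geometry()
  xyz <- matrix(0, topology$n_atoms, 3L)
  xyz[1L, ] <- c(0, 0, 0)
  mols <- topology$mol[topology$mol$species != "solute", ]
  stopifnot(nrow(mols) == nrow(centers))
  wi <- 0L
  for (i in seq_len(nrow(mols))) {
    m <- mols[i, ]
    if (m$species == "wat") {
      wi <- wi + 1L
      R <- if (is.null(quats)) diag(3L) else quat_to_matrix(quats[wi, ])
      xyz[m$first, ] <- centers[i, ]
      xyz[m$first + 1L, ] <- centers[i, ] + as.numeric(R %*% ref["H1", ])
      xyz[m$first + 2L, ] <- centers[i, ] + as.numeric(R %*% ref["H2", ])
    } else {
      xyz[m$first, ] <- centers[i, ]
    }
  }
  md_frame(xyz, box, index)
}
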