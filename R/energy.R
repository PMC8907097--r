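## Voxelized nonbonded energies and per-species bulk referencing.
##
## Electrostatics are minimum-image truncated Coulomb with a configurable
## cutoff.  GIST decomposes energy into molecule pairs; reciprocal-space
## (Ewald/PME) terms are not pair-decomposable and are out of scope, which is
## a known deviation from typical MD practice and is documented in the
## methods vignette.

#' Nonbonded pair energy of two atoms
#'
#' Lennard-Jones plus Coulomb at the minimum-image distance:
#' `E = 4*eps_ij*((sig_ij/r)^12 - (sig_ij/r)^6) + C*q_i*q_j/r`, with
#' Lorentz-Berthelot combination (arithmetic sigma, geometric epsilon) and
#' `C = 332.0637` kcal*Angstrom/(mol*e^2); zero beyond the cutoff.
#'
#' @param i,j atom indices (must belong to different molecules).
#' @param frame an [md_frame()].
#' @param topology a [mixture_topology()].
#' @param cutoff interaction cutoff (Angstrom, default 10).
#' @param coulomb_constant electrostatic prefactor.
#' @return Energy in kcal/mol.  Symmetric in `i`, `j`.
#' @export
pair_energy <- function(i, j, frame, topology, cutoff = 10,
                        coulomb_constant = .COULOMB) {
  a <- topology$atoms[i, ]; b <- topology$atoms[j, ]
  if (i == j || a$mol == b$mol)
    stop("pair_energy requires atoms of different molecules")
  d <- min_image(frame$xyz[j, ] - frame$xyz[i, ], frame$box)
  r <- sqrt(sum(d^2))
  if (r < 1e-6) stop("overlapping atoms (", i, ", ", j, ")")
  if (r > cutoff) return(0)
  e <- 0
  if (a$charge != 0 && b$charge != 0)
    e <- e + coulomb_constant * a$charge * b$charge / r
  eij <- sqrt(a$epsilon * b$epsilon)
  if (eij != 0) {
    sij <- (a$sigma + b$sigma) / 2
    sr6 <- (sij / r)^6
    e <- e + 4 * eij * (sr6^2 - sr6)
  }
  e
}

#' Accumulate voxelized solute-solvent and solvent-solvent energies
#'
#' Molecule-pair energies (sums of atom-pair energies, minimum image applied
#' once per molecule pair from the molecule centers) are assigned per frame:
#' solute-solvent energy goes wholly to the solvent molecule's voxel
#' (`E_uv`; ion-solute interactions are part of it); solvent-solvent energy
#' is split half/half between both molecules' voxels (`E_vv`).  A pair with
#' one member outside the grid contributes only the in-grid member's half.
#' Final fields are per-frame means (divided by the number of frames).
#'
#' @param frames list of [md_frame()]s.
#' @param topology a [mixture_topology()].
#' @param grid a [gist_grid()].
#' @param cutoff atom-pair interaction cutoff (Angstrom, default 10).
#' @param coulomb_constant electrostatic prefactor.
#' @return Object of class `voxel_energies`: `E_uv`, `E_vv` (numeric vectors
#'   over voxels, kcal/mol per frame), `grid`, `n_frames`, `cutoff`, plus
#'   frame-total diagnostics `total_uv`, `total_vv` (kcal/mol, per-frame
#'   means over all solvent molecules, in-grid or not).
#' @export
accumulate_energies <- function(frames, topology, grid, cutoff = 10,
                                coulomb_constant = .COULOMB) {
  n_f <- length(frames)
  stopifnot(n_f > 0L)
  E_uv <- numeric(grid$n_voxels)
  E_vv <- numeric(grid$n_voxels)
  tot_uv <- 0; tot_vv <- 0
  at <- topology$atoms; ml <- topology$mol
  spcode <- .species_code(topology)
  solv <- .solvent_mols(topology)
  catom <- ml$center_atom
  for (fr in frames) {
    if (any(fr$box < 2 * cutoff))
      stop("box length must be at least twice the cutoff (frame ",
           fr$index, ")")
    en <- cpp_frame_energies(fr$xyz, fr$box, at$charge, at$sigma, at$epsilon,
                             ml$first - 1L, ml$last - 1L, spcode,
                             catom - 1L, cutoff, coulomb_constant)
    vox <- assign_voxel(fr$xyz[catom[solv], , drop = FALSE], grid)
    ok <- !is.na(vox)
    if (any(ok)) {
      E_uv <- E_uv + .bincount(vox[ok], en$E_uv[solv][ok], grid$n_voxels)
      E_vv <- E_vv + .bincount(vox[ok], en$E_vv[solv][ok], grid$n_voxels)
    }
    tot_uv <- tot_uv + sum(en$E_uv)
    tot_vv <- tot_vv + sum(en$E_vv)
  }
  structure(list(E_uv = E_uv / n_f, E_vv = E_vv / n_f, grid = grid,
                 n_frames = n_f, cutoff = cutoff,
                 total_uv = tot_uv / n_f, total_vv = tot_vv / n_f),
            class = "voxel_energies")
}

## Weighted bincount: sum of w by integer bin.
.bincount <- function(bin, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, group = bin)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Fit per-species bulk energies by ordinary least squares
#'
#' In the bulk, the per-voxel solvent-solvent energy is a linear combination
#' of the per-frame molecule counts:
#' `E_vv,k ~ N_k,wat*<E_wat> + N_k,cat*<E_cat> + N_k,an*<E_an>`
#' with no intercept (an empty voxel must have zero reference energy).  The
#' fit runs over voxels whose centers are at least `cutoff` from every
#' solute heavy atom; with no solute every voxel is bulk-like.
#'
#' @param voxels a `voxel_energies` object whose `grid` carries counts
#'   (run [accumulate_counts()] first or pass `counts`).
#' @param counts optional `n_voxels` x 3 count matrix overriding
#'   `voxels$grid$counts`.
#' @param solute_xyz coordinates of the solute heavy atoms (m x 3), or
#'   `NULL` for a solute-free box.
#' @param cutoff bulk-region distance cutoff (Angstrom, default 16).
#' @return Object of class `bulk_energy_model`: named coefficients `E_wat`,
#'   `E_cation`, `E_anion` (kcal/mol per molecule), standard errors, residual
#'   sigma, number of bulk voxels, cutoff.
#' @export
fit_bulk_energy <- function(voxels, counts = NULL, solute_xyz = NULL,
                            cutoff = 16) {
  grid <- voxels$grid
  if (is.null(counts)) counts <- grid$counts
  if (is.null(counts)) stop("no counts available; run accumulate_counts()")
  n_f <- voxels$n_frames
  Nbar <- counts / n_f
  bulk <- .bulk_voxels(grid, solute_xyz, cutoff)
  present <- colSums(counts[bulk, , drop = FALSE]) > 0
  if (!all(present))
    stop("rank-deficient bulk design: species ",
         paste(.SPECIES[!present], collapse = ", "),
         " absent from the bulk region; consider a pure-solvent reference run")
  if (length(bulk) < 10L * sum(present))
    stop("too few bulk voxels (", length(bulk), ") for the fit")
  df <- data.frame(E = voxels$E_vv[bulk],
                   N_wat = Nbar[bulk, 1L], N_cation = Nbar[bulk, 2L],
                   N_anion = Nbar[bulk, 3L])
  fit <- lm(E ~ 0 + N_wat + N_cation + N_anion, data = df)
  if (fit$rank < 3L)
    stop("rank-deficient bulk design; consider a pure-solvent reference run")
  sm <- suppressWarnings(summary(fit))   # exact fits are legitimate here
  cf <- coef(fit)
  structure(list(coefficients = setNames(as.numeric(cf),
                                         c("E_wat", "E_cation", "E_anion")),
                 se = setNames(as.numeric(sm$coefficients[, "Std. Error"]),
                               c("E_wat", "E_cation", "E_anion")),
                 sigma = sm$sigma, n_bulk_voxels = length(bulk),
                 cutoff = cutoff),
            class = "bulk_energy_model")
}

#' @export
print.bulk_energy_model <- function(x, ...) {
  cat("bulk_energy_model (", x$n_bulk_voxels, " bulk voxels, cutoff ",
      x$cutoff, " A):\n", sep = "")
  for (nm in names(x$coefficients))
    cat(sprintf("  <%s> = %.6g +/- %.3g kcal/mol\n", nm,
                x$coefficients[[nm]], x$se[[nm]]))
  invisible(x)
}

## Voxels whose centers are >= cutoff from every solute heavy atom.
.bulk_voxels <- function(grid, solute_xyz, cutoff) {
  if (is.null(solute_xyz) || nrow(as.matrix(solute_xyz)) == 0L)
    return(seq_len(grid$n_voxels))
  cen <- voxel_centers(grid)
  mind <- .min_dist_to_points(cen, as.matrix(solute_xyz))
  which(mind >= cutoff)
}

## Min Euclidean distance from each row of X to any row of P.
.min_dist_to_points <- function(X, P) {
  mind <- rep(Inf, nrow(X))
  for (i in seq_len(nrow(P))) {
    d2 <- (X[, 1] - P[i, 1])^2 + (X[, 2] - P[i, 2])^2 + (X[, 3] - P[i, 3])^2
    mind <- pmin(mind, sqrt(d2))
  }
  mind
}

#' Per-voxel reference energy and referenced solvent-solvent energy
#'
#' Applies the fitted per-species bulk energies to the frame-averaged voxel
#' counts: `E_ref,k = N_k,wat*<E_wat> + N_k,cat*<E_cat> + N_k,an*<E_an>`,
#' and `dE_vv,k = E_vv,k - E_ref,k`.  Empty voxels get zero reference.
#'
#' @param voxels a `voxel_energies` object (with counts on its grid, or pass
#'   `counts`).
#' @param model a [fit_bulk_energy()] result.
#' @param counts optional count matrix override.
#' @return `voxels` with `E_ref` and `dE_vv` fields added.
#' @export
reference_energy <- function(voxels, model, counts = NULL) {
  grid <- voxels$grid
  if (is.null(counts)) counts <- grid$counts
  if (is.null(counts)) stop("no counts available; run accumulate_counts()")
  Nbar <- counts / voxels$n_frames
  E_ref <- as.numeric(Nbar %*% model$coefficients)
  voxels$E_ref <- E_ref
  voxels$dE_vv <- voxels$E_vv - E_ref
  voxels$bulk_model <- model
  voxels
}
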