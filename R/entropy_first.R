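## First-order nearest-neighbor entropies.
##
## Per voxel k and species i, with N_k samples pooled over all frames:
##   S_trans  = R * (gamma + mean ln(N_f * rho0_i * 4*pi*d^3 / 3))
##   S_orient = R * (gamma + mean ln(N_k * dw^3 / (6*pi)))          (water)
##   S_six    = R * (gamma + mean ln(N_f * rho0_i * pi*(dw^2+d^2)^3 / 48))
## d is the translational nearest-neighbor distance (minimum image), dw the
## rotational one, and the six-dimensional metric minimizes
## sqrt(dw^2 + d^2) jointly.  gamma corrects the asymptotic estimator bias.
## These are entropies relative to bulk: for uniform sampling they go to
## zero.  Ions are monoatomic and carry only S_trans.

#' Estimator context for the nearest-neighbor entropies
#'
#' @param n_frames number of trajectory frames pooled.
#' @param rho0 named numeric vector of reference number densities
#'   (1/Angstrom^3) with entries `wat`, `cation`, `anion` (any subset).
#' @param temperature temperature in K (default 300).
#' @return List of class `estimator_context` with `n_frames`, `rho0`,
#'   `temperature`, `R`, `gamma`.
#' @export
estimator_context <- function(n_frames, rho0, temperature = 300) {
  stopifnot(n_frames >= 1, all(rho0 > 0), temperature > 0)
  structure(list(n_frames = n_frames, rho0 = rho0,
                 temperature = temperature, R = .GAS_R, gamma = .GAMMA),
            class = "estimator_context")
}

#' Nearest-neighbor distances among pooled solvent samples
#'
#' For each queried sample, the smallest distance to any other sample of the
#' same species pooled across all frames (the same molecule in other frames
#' counts; only the identical sample is excluded).
#'
#' Metrics: `"trans"` — minimum-image Euclidean distance; `"orient"` —
#' rotational angle `2*acos(|q1.q2|)` restricted to samples sharing a group
#' (voxel); `"six"` — joint `sqrt(dw^2 + d^2)`, minimized jointly.
#'
#' @param positions n x 3 sample positions (Angstrom); ignored for
#'   `"orient"`.
#' @param box periodic box lengths (required when `periodic`).
#' @param metric `"trans"`, `"orient"` or `"six"`.
#' @param quaternions n x 4 unit quaternions (required for `"orient"` and
#'   `"six"`).
#' @param periodic apply minimum image (default `TRUE`).
#' @param query indices of samples to evaluate (default all).
#' @param groups integer group (voxel) per sample for the `"orient"` metric;
#'   samples with `NA` group are skipped.
#' @return Numeric vector of nearest-neighbor distances (`NA` where fewer
#'   than 2 samples are available).
#' @export
nn_search <- function(positions, box = NULL,
                      metric = c("trans", "six", "orient"),
                      quaternions = NULL, periodic = TRUE, query = NULL,
                      groups = NULL) {
  metric <- match.arg(metric)
  if (metric == "orient") {
    stopifnot(!is.null(quaternions), !is.null(groups))
    g <- as.integer(groups) - 1L
    g[is.na(g)] <- -1L
    return(cpp_nn_orient_groups(as.matrix(quaternions), g,
                                max(g, 0L) + 1L))
  }
  positions <- as.matrix(positions)
  if (periodic && is.null(box)) stop("periodic search needs box lengths")
  if (is.null(box)) box <- c(1, 1, 1)
  if (is.null(query)) query <- seq_len(nrow(positions))
  q0 <- as.integer(query) - 1L
  if (metric == "trans")
    cpp_nn_trans(positions, as.numeric(box), periodic, q0)
  else {
    stopifnot(!is.null(quaternions))
    cpp_nn_six(positions, as.matrix(quaternions), as.numeric(box),
               periodic, q0)
  }
}

#' Translational entropy of one voxel
#'
#' @param d translational nearest-neighbor distances of the voxel's samples.
#' @param ctx an [estimator_context()].
#' @param species species name selecting the reference density in
#'   `ctx$rho0`.
#' @return Entropy in kcal/(mol*K) per molecule (relative to bulk), `NA` if
#'   no valid sample.  Multiply by `ctx$temperature` for a TdS.
#' @export
s_trans <- function(d, ctx, species = "wat") {
  d <- d[is.finite(d) & d > 0]
  if (length(d) == 0L) return(NA_real_)
  rho <- ctx$rho0[[species]]
  ctx$R * (ctx$gamma + mean(log(ctx$n_frames * rho * 4 * pi * d^3 / 3)))
}

#' Orientational entropy of one voxel (water)
#'
#' Uses the voxel population inside the logarithm, as the estimator is
#' stated; `orient_norm = "pooled"` replaces it by the expected pooled
#' population `n_frames * rho0 * voxel_volume` instead.
#'
#' @param dw rotational nearest-neighbor angles (radians) of the voxel's
#'   samples.
#' @param n_k voxel sample count entering the estimator.
#' @param ctx an [estimator_context()].
#' @return Entropy in kcal/(mol*K) per molecule, `NA` if no valid sample.
#' @export
s_orient <- function(dw, n_k, ctx) {
  dw <- dw[is.finite(dw) & dw > 0]
  if (length(dw) == 0L || n_k < 2) return(NA_real_)
  ctx$R * (ctx$gamma + mean(log(n_k * dw^3 / (6 * pi))))
}

#' Six-dimensional entropy of one voxel (water)
#'
#' @param six joint nearest-neighbor values `sqrt(dw^2 + d^2)` of the
#'   voxel's samples.
#' @param ctx an [estimator_context()].
#' @param species species name for the reference density.
#' @return Entropy in kcal/(mol*K) per molecule, `NA` if no valid sample.
#' @export
s_six <- function(six, ctx, species = "wat") {
  six <- six[is.finite(six) & six > 0]
  if (length(six) == 0L) return(NA_real_)
  rho <- ctx$rho0[[species]]
  ctx$R * (ctx$gamma + mean(log(ctx$n_frames * rho * pi * six^6 / 48)))
}

#' First-order entropy fields for every species
#'
#' Collects all solvent samples (positions, and orientations for water)
#' across frames, runs the pooled nearest-neighbor searches, and evaluates
#' the per-voxel estimators.  Each voxel carries the per-molecule entropy
#' (`*_norm`, kcal/mol after multiplying by T) and the occupancy-weighted
#' voxel contribution `TdS_* = (N_k / N_f) * T * S_k` (kcal/mol per voxel),
#' whose sum over a region is the region's entropy integral.  Voxels with
#' one sample or fewer hold 0 and are flagged.
#'
#' @param frames list of [md_frame()]s.
#' @param topology a [mixture_topology()].
#' @param grid a [gist_grid()].
#' @param rho0 named reference densities (1/Angstrom^3): `wat`, `cation`,
#'   `anion` as present.
#' @param temperature K (default 300).
#' @param reference_offset_six constant (kcal/mol) subtracted from the
#'   per-molecule water TdS_six before weighting, compensating residual bulk
#'   entropy from finite sampling (default 0).
#' @param orient_norm `"voxel"` (estimator as stated, voxel population in
#'   the log) or `"pooled"` (expected pooled population).
#' @return Object of class `first_order_entropy` with matrices over voxels:
#'   `S_trans_norm` (K x 3), `TdS_trans` (K x 3), water vectors
#'   `S_orient_norm`, `S_six_norm`, `TdS_orient`, `TdS_six`, sample counts
#'   `n_samples` (K x 3), logical `flag` (K x 3), the context and grid.
#' @export
first_order_entropy <- function(frames, topology, grid, rho0,
                                temperature = 300, reference_offset_six = 0,
                                orient_norm = c("voxel", "pooled")) {
  orient_norm <- match.arg(orient_norm)
  n_f <- length(frames)
  stopifnot(n_f > 0L)
  ctx <- estimator_context(n_f, rho0, temperature)
  K <- grid$n_voxels
  box <- frames[[1L]]$box

  S_trans <- matrix(0, K, 3L, dimnames = list(NULL, .SPECIES))
  TdS_trans <- S_trans
  n_samples <- matrix(0L, K, 3L, dimnames = list(NULL, .SPECIES))
  flag <- matrix(TRUE, K, 3L, dimnames = list(NULL, .SPECIES))
  S_orient <- numeric(K); S_six <- numeric(K)
  TdS_orient <- numeric(K); TdS_six <- numeric(K)

  for (s in seq_along(.SPECIES)) {
    spn <- .SPECIES[s]
    mols <- which(topology$mol$species == spn)
    if (length(mols) == 0L || !(spn %in% names(rho0))) next
    catom <- topology$mol$center_atom[mols]
    nm <- length(mols)
    pos <- matrix(0, nm * n_f, 3L)
    vox <- integer(nm * n_f)
    for (f in seq_len(n_f)) {
      rows <- ((f - 1L) * nm + 1L):(f * nm)
      pos[rows, ] <- frames[[f]]$xyz[catom, , drop = FALSE]
      vox[rows] <- assign_voxel(pos[rows, , drop = FALSE], grid)
    }
    ing <- which(!is.na(vox))
    if (length(ing) == 0L) next
    nk <- tabulate(vox[ing], nbins = K)
    n_samples[, s] <- nk
    use <- nk >= 2L        # estimator defined for N_k >= 2
    flag[, s] <- !use

    d <- rep(NA_real_, nrow(pos))
    d[ing] <- nn_search(pos, box, "trans", query = ing)
    lt <- .voxel_log_mean(log(ctx$n_frames * rho0[[spn]] * 4 * pi *
                              pmax(d[ing], 1e-300)^3 / 3),
                          vox[ing], K)
    st <- ctx$R * (ctx$gamma + lt)
    st[!use | !is.finite(st)] <- 0
    S_trans[, s] <- st
    TdS_trans[, s] <- (nk / n_f) * temperature * st

    if (spn == "wat") {
      quat <- matrix(0, nm * n_f, 4L)
      for (f in seq_len(n_f)) {
        rows <- ((f - 1L) * nm + 1L):(f * nm)
        quat[rows, ] <- water_orientations(frames[[f]], topology, mols)
      }
      ## orientational: nearest neighbor within the voxel
      gvox <- vox
      dw <- nn_search(NULL, metric = "orient", quaternions = quat,
                      groups = gvox)
      nk_log <- if (orient_norm == "voxel") nk
                else rep(ctx$n_frames * rho0[[spn]] * grid$voxel_volume, K)
      ok <- ing[is.finite(dw[ing]) & dw[ing] > 0]
      lo <- .voxel_log_mean(log(pmax(dw[ok], 1e-300)^3 / (6 * pi)),
                            vox[ok], K)
      so <- ctx$R * (ctx$gamma + lo + log(pmax(nk_log, 1)))
      so[!use | !is.finite(so)] <- 0
      S_orient <- so
      TdS_orient <- (nk / n_f) * temperature * so

      six <- rep(NA_real_, nrow(pos))
      six[ing] <- nn_search(pos, box, "six", quaternions = quat,
                            query = ing)
      l6 <- .voxel_log_mean(log(ctx$n_frames * rho0[[spn]] * pi *
                                pmax(six[ing], 1e-300)^6 / 48),
                            vox[ing], K)
      s6 <- ctx$R * (ctx$gamma + l6)
      s6[!use | !is.finite(s6)] <- 0
      S_six <- s6
      tds6_norm <- temperature * s6 - reference_offset_six
      tds6_norm[!use] <- 0
      TdS_six <- (nk / n_f) * tds6_norm
    }
  }

  structure(list(S_trans_norm = S_trans, TdS_trans = TdS_trans,
                 S_orient_norm = S_orient, S_six_norm = S_six,
                 TdS_orient = TdS_orient, TdS_six = TdS_six,
                 n_samples = n_samples, flag = flag, ctx = ctx,
                 grid = grid, reference_offset_six = reference_offset_six),
            class = "first_order_entropy")
}

## Mean of log terms per voxel: returns K-vector (0 where no samples).
.voxel_log_mean <- function(lg, vox, K) {
  out <- numeric(K)
  n <- tabulate(vox, nbins = K)
  agg <- rowsum(lg, group = vox)
  idx <- as.integer(rownames(agg))
  out[idx] <- agg[, 1L] / n[idx]
  out
}

#' Total first-order entropy field
#'
#' Voxelwise sum of the per-species contributions (entropy additivity over
#' mixture components): water contributes its six-dimensional (default) or
#' translational+orientational term, ions their translational terms only.
#'
#' @param fo a [first_order_entropy()] object.
#' @param water which water estimate to use: `"six"` (default) or
#'   `"trans_orient"`.
#' @return Numeric vector over voxels: total TdS (kcal/mol per voxel).
#' @export
species_entropy <- function(fo, water = c("six", "trans_orient")) {
  water <- match.arg(water)
  wat <- if (water == "six") fo$TdS_six
         else fo$TdS_trans[, "wat"] + fo$TdS_orient
  wat + fo$TdS_trans[, "cation"] + fo$TdS_trans[, "anion"]
}
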