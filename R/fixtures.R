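## Synthetic trajectory generators with known statistical structure.
##
## Every generator is deterministic under a fixed seed and restores the
## caller's RNG state.  The ideal gas is the null model (all g = 1, all
## entropy and energy fields zero in expectation); the Metropolis
## Monte-Carlo fluid provides nontrivial pair correlations; Gaussian clouds
## and uniform rotations calibrate the entropy estimators directly.
##
## Water stand-ins are rigid three-site molecules: the sampled point
## particle carries the oxygen (and all nonbonded parameters); hydrogens
## are attached in the reference geometry at an independently sampled
## orientation, giving known uniform orientation statistics.

#' Uniformly random unit quaternions
#'
#' Shoemake's subgroup algorithm; canonical sign.
#'
#' @param n number of quaternions.
#' @return n x 4 matrix of unit quaternions, uniform on SO(3).
#' @export
random_quaternions <- function(n) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  q <- cbind(sqrt(1 - u1) * sin(2 * pi * u2),
             sqrt(1 - u1) * cos(2 * pi * u2),
             sqrt(u1) * sin(2 * pi * u3),
             sqrt(u1) * cos(2 * pi * u3))
  quat_canonical(q)
}

## Rotate a fixed vector v by every quaternion row of Q (n x 4) -> n x 3.
.rotate_rows <- function(Q, v) {
  w <- Q[, 1]; x <- Q[, 2]; y <- Q[, 3]; z <- Q[, 4]
  ## v' = v + 2*w*(q_v x v) + 2*q_v x (q_v x v)
  cx <- y * v[3] - z * v[2]
  cy <- z * v[1] - x * v[3]
  cz <- x * v[2] - y * v[1]
  dx <- y * cz - z * cy
  dy <- z * cx - x * cz
  dz <- x * cy - y * cx
  cbind(v[1] + 2 * (w * cx + dx),
        v[2] + 2 * (w * cy + dy),
        v[3] + 2 * (w * cz + dz))
}

## Shared fixture topology: one point solute at the origin plus 3-site
## waters and monoatomic ions.  Nonbonded parameters per species are lists
## with charge/sigma/epsilon (applied to the oxygen for water).
.fixture_topology <- function(n_wat, n_cation, n_anion,
                              wat = list(charge = 0, sigma = 0, epsilon = 0),
                              cation = list(charge = 0, sigma = 0,
                                            epsilon = 0),
                              anion = list(charge = 0, sigma = 0,
                                           epsilon = 0),
                              solute = list(charge = 0, sigma = 0,
                                            epsilon = 0)) {
  at <- function(name, p, mass)
    data.frame(name = name, charge = p$charge, sigma = p$sigma,
               epsilon = p$epsilon, mass = mass, stringsAsFactors = FALSE)
  types <- list(
    SOL = list(atoms = at("S1", solute, 12.0)),
    WAT = list(atoms = rbind(at("O", wat, 15.999),
                             at("H1", list(charge = 0, sigma = 0,
                                           epsilon = 0), 1.008),
                             at("H2", list(charge = 0, sigma = 0,
                                           epsilon = 0), 1.008))),
    CAT = list(atoms = at("M", cation, 22.99)),
    ANI = list(atoms = at("X", anion, 35.45)))
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

## Assemble one frame from point centers: solute at origin, waters dressed
## with hydrogens at the given orientations.
.fixture_frame <- function(centers, quats, n_wat, topology, box, index) {
  ref <- water_reference_geometry()
  xyz <- matrix(0, topology$n_atoms, 3L)
  row <- 1L                      # solute atom at the origin
  xyz[row, ] <- c(0, 0, 0)
  row <- row + 1L
  if (n_wat > 0) {
    O <- centers[seq_len(n_wat), , drop = FALSE]
    H1 <- O + .rotate_rows(quats, ref["H1", ])
    H2 <- O + .rotate_rows(quats, ref["H2", ])
    idx <- row + 3L * (seq_len(n_wat) - 1L)
    xyz[idx, ] <- O
    xyz[idx + 1L, ] <- H1
    xyz[idx + 2L, ] <- H2
    row <- row + 3L * n_wat
  }
  n_ion <- nrow(centers) - n_wat
  if (n_ion > 0)
    xyz[row + seq_len(n_ion) - 1L, ] <- centers[n_wat + seq_len(n_ion), ,
                                                drop = FALSE]
  md_frame(xyz, box, index)
}

#' Ideal-gas fixture
#'
#' Uniform independent positions every frame and uniform random water
#' orientations; all charges and Lennard-Jones epsilons are zero.  The
#' default box holds 500 waters at ambient water density (0.0334 per
#' cubic Angstrom) and 10 + 10 ions, about 1.1 mol/L of salt.
#'
#' @param n_wat,n_cation,n_anion molecule counts (defaults 500, 10, 10).
#' @param box box lengths (Angstrom, default 24.66 cubic).
#' @param n_frames frames to generate (default 2000).
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @return List of class `gist_fixture`: `topology`, `frames`, `spec`.
#' @export
gen_ideal_gas <- function(n_wat = 500, n_cation = 10, n_anion = 10,
                          box = c(24.66, 24.66, 24.66), n_frames = 2000,
                          seed = 1L) {
  stopifnot(n_wat + n_cation + n_anion >= 1, n_frames >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  topo <- .fixture_topology(n_wat, n_cation, n_anion)
  n <- n_wat + n_cation + n_anion
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    centers <- cbind(runif(n, -box[1] / 2, box[1] / 2),
                     runif(n, -box[2] / 2, box[2] / 2),
                     runif(n, -box[3] / 2, box[3] / 2))
    quats <- if (n_wat > 0) random_quaternions(n_wat) else NULL
    frames[[f]] <- .fixture_frame(centers, quats, n_wat, topo, box, f - 1L)
  }
  structure(list(topology = topo, frames = frames,
                 spec = list(kind = "ideal", n_wat = n_wat,
                             n_cation = n_cation, n_anion = n_anion,
                             box = box, n_frames = n_frames, seed = seed)),
            class = "gist_fixture")
}

#' Metropolis Monte-Carlo fluid fixture
#'
#' Equilibrium ensemble of a point-particle fluid under minimum-image
#' Lennard-Jones plus truncated Coulomb, sampled by single-particle
#' displacement moves, optionally around a fixed hard-sphere solute at the
#' origin.  Water stand-ins get dressed with hydrogens at independently
#' uniform orientations when frames are emitted.  Default nonbonded
#' parameters give a dense liquid-like water analog with +1/-1 ions.
#'
#' @param n_wat,n_cation,n_anion molecule counts.
#' @param box box lengths (Angstrom).
#' @param temperature K (default 300).
#' @param wat,cation,anion,solute nonbonded parameter lists
#'   (`charge`, `sigma`, `epsilon`).
#' @param cutoff interaction cutoff (Angstrom, default 10).
#' @param solute_radius hard-sphere exclusion radius at the origin
#'   (Angstrom; 0 disables).
#' @param n_equil_sweeps equilibration sweeps (one sweep = N moves).
#' @param n_frames production frames.
#' @param stride_sweeps sweeps between stored frames.
#' @param max_disp maximal displacement per move (Angstrom).
#' @param seed RNG seed (drives the C++ sampler deterministically).
#' @return List of class `gist_fixture`: `topology`, `frames`, `spec`,
#'   `acceptance`, `frame_energy`.  A warning is raised if the acceptance
#'   rate drops below 1 percent.
#' @export
gen_mc_fluid <- function(n_wat = 280, n_cation = 10, n_anion = 10,
                         box = c(21, 21, 21), temperature = 300,
                         wat = list(charge = 0, sigma = 3.15,
                                    epsilon = 0.15),
                         cation = list(charge = 1, sigma = 2.3,
                                       epsilon = 0.1),
                         anion = list(charge = -1, sigma = 3.8,
                                      epsilon = 0.1),
                         solute = list(charge = 0, sigma = 0, epsilon = 0),
                         cutoff = 10, solute_radius = 0,
                         n_equil_sweeps = 200, n_frames = 100,
                         stride_sweeps = 5, max_disp = 0.9, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  topo <- .fixture_topology(n_wat, n_cation, n_anion, wat, cation, anion,
                            solute)
  n <- n_wat + n_cation + n_anion
  par_of <- function(p, count) list(q = rep(p$charge, count),
                                    s = rep(p$sigma, count),
                                    e = rep(p$epsilon, count))
  pw <- par_of(wat, n_wat); pc <- par_of(cation, n_cation)
  pa <- par_of(anion, n_anion)
  q <- c(pw$q, pc$q, pa$q); s <- c(pw$s, pc$s, pa$s)
  e <- c(pw$e, pc$e, pa$e)
  X0 <- cpp_mc_init(n, box, solute_radius, as.integer(seed) + 7919L)
  beta <- 1 / (.GAS_R * temperature)
  res <- cpp_mc_fluid(X0, box, q, s, e, cutoff, beta, max_disp,
                      as.integer(n_equil_sweeps), as.integer(n_frames),
                      as.integer(stride_sweeps), solute_radius,
                      as.integer(seed))
  if (res$acceptance < 0.01)
    warning("Monte-Carlo acceptance rate below 1%: ",
            signif(100 * res$acceptance, 3), "%")
  frames <- vector("list", res$n_stored)
  arr <- res$frames
  for (f in seq_len(res$n_stored)) {
    off <- (f - 1L) * n * 3L
    centers <- matrix(arr[off + seq_len(n * 3L)], ncol = 3L, byrow = TRUE)
    quats <- if (n_wat > 0) random_quaternions(n_wat) else NULL
    frames[[f]] <- .fixture_frame(centers, quats, n_wat, topo, box, f - 1L)
  }
  structure(list(topology = topo, frames = frames,
                 spec = list(kind = "mc_fluid", n_wat = n_wat,
                             n_cation = n_cation, n_anion = n_anion,
                             box = box, temperature = temperature,
                             cutoff = cutoff, solute_radius = solute_radius,
                             n_equil_sweeps = n_equil_sweeps,
                             n_frames = n_frames,
                             stride_sweeps = stride_sweeps,
                             max_disp = max_disp, seed = seed),
                 acceptance = res$acceptance,
                 frame_energy = res$frame_energy),
            class = "gist_fixture")
}

#' Independent sample sets for estimator calibration
#'
#' Draws i.i.d. samples outside the trajectory machinery, for direct tests
#' of the nearest-neighbor entropy estimators.
#'
#' @param distribution `"uniform-box"` (positions uniform in `box`),
#'   `"gaussian"` (isotropic, standard deviation `sigma`), or
#'   `"uniform-rotation"` (unit quaternions uniform on SO(3)).
#' @param n sample count (>= 2).
#' @param seed RNG seed.
#' @param sigma Gaussian standard deviation (Angstrom).
#' @param box box lengths for the uniform distribution.
#' @return n x 3 position matrix, or n x 4 quaternion matrix for
#'   `"uniform-rotation"`.
#' @export
gen_entropy_samples <- function(distribution = c("uniform-box", "gaussian",
                                                 "uniform-rotation"),
                                n, seed = 1L, sigma = 1,
                                box = c(10, 10, 10)) {
  distribution <- match.arg(distribution)
  stopifnot(n >= 2)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  switch(distribution,
         "uniform-box" = cbind(runif(n, -box[1] / 2, box[1] / 2),
                               runif(n, -box[2] / 2, box[2] / 2),
                               runif(n, -box[3] / 2, box[3] / 2)),
         "gaussian" = matrix(rnorm(3 * n, sd = sigma), ncol = 3L),
         "uniform-rotation" = random_quaternions(n))
}

#' Synthetic free-energy-versus-concentration series
#'
#' `dG_i = intercept + slope * c_i + N(0, noise_sd)`, for Setschenow-fit
#' recovery tests; a slope of `R*T*ln(10)` kcal/(mol*M) corresponds to
#' `K_S = 1` L/mol.
#'
#' @param slope kcal/(mol*M).
#' @param intercept kcal/mol (default 0).
#' @param noise_sd Gaussian noise standard deviation (kcal/mol, default 0).
#' @param concentrations mol/L (default 11 points from 0 to 1).
#' @param seed RNG seed.
#' @return data.frame with columns `concentration`, `dG`.
#' @export
gen_dg_series <- function(slope, intercept = 0, noise_sd = 0,
                          concentrations = seq(0, 1, by = 0.1), seed = 1L) {
  stopifnot(length(concentrations) >= 3L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  dG <- intercept + slope * concentrations +
        rnorm(length(concentrations), sd = noise_sd)
  data.frame(concentration = concentrations, dG = dG)
}

#' Write a fixture to disk
#'
#' Serializes a generated fixture as a topology JSON plus a built-in
#' plain-text trajectory, with the generator spec (including the seed) as
#' JSON metadata.
#'
#' @param fixture a `gist_fixture`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_topology(fixture$topology, file.path(dir, "topology.json"))
  write_frames(fixture$frames, fixture$topology,
               file.path(dir, "trajectory.txt"))
  jsonlite::write_json(fixture$spec, file.path(dir, "fixture.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
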