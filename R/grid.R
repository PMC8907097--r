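## Voxel lattice for GIST accumulation.
##
## Default geometry: 81 x 81 x 81 voxels at 0.5 Angstrom spacing, centered on
## the origin (where the rigid solute sits).  Voxels are half-open boxes
## [lo, lo + spacing) in each dimension — lower edge inclusive, upper edge
## exclusive — so assignment is unambiguous.  Linear voxel indices are
## 1-based with x fastest, matching R array order.

#' Construct a GIST voxel grid
#'
#' @param center grid center (Angstrom), default the origin.
#' @param dims integer 3-vector of voxel counts, default `c(81, 81, 81)`.
#' @param spacing voxel edge length (Angstrom), default 0.5.
#' @return Object of class `gist_grid`: list with `center`, `dims`,
#'   `spacing`, `origin` (lower corner), `n_voxels`, `voxel_volume`, and —
#'   after [accumulate_counts()] — a `counts` matrix (`n_voxels` x 3 species)
#'   and `n_frames`.
#' @export
gist_grid <- function(center = c(0, 0, 0), dims = c(81L, 81L, 81L),
                      spacing = 0.5) {
  dims <- as.integer(dims)
  stopifnot(length(center) == 3L, length(dims) == 3L, all(dims >= 1L),
            spacing > 0)
  origin <- center - dims * spacing / 2
  structure(list(center = as.numeric(center), dims = dims,
                 spacing = spacing, origin = origin,
                 n_voxels = prod(dims), voxel_volume = spacing^3,
                 counts = NULL, n_frames = NULL),
            class = "gist_grid")
}

#' @export
print.gist_grid <- function(x, ...) {
  cat("gist_grid:", paste(x$dims, collapse = " x "), "voxels at",
      x$spacing, "A spacing, center (",
      paste(signif(x$center, 6), collapse = ", "), ")\n")
  if (!is.null(x$counts))
    cat("  counts over", x$n_frames, "frames; occupied voxels:",
        sum(rowSums(x$counts) > 0), "/", x$n_voxels, "\n")
  invisible(x)
}

#' Assign positions to voxels
#'
#' Half-open voxel convention: a position on a voxel's lower face belongs to
#' that voxel; on the upper face, to the next.
#'
#' @param position numeric 3-vector or n x 3 matrix (Angstrom).
#' @param grid a [gist_grid()].
#' @return Integer linear voxel index (1-based, x fastest), or `NA` for
#'   positions outside the grid.  Vectorized over rows.
#' @export
assign_voxel <- function(position, grid) {
  p <- if (is.matrix(position)) position else matrix(position, ncol = 3L)
  ix <- floor((p[, 1] - grid$origin[1]) / grid$spacing)
  iy <- floor((p[, 2] - grid$origin[2]) / grid$spacing)
  iz <- floor((p[, 3] - grid$origin[3]) / grid$spacing)
  ok <- ix >= 0 & ix < grid$dims[1] & iy >= 0 & iy < grid$dims[2] &
        iz >= 0 & iz < grid$dims[3]
  idx <- 1L + as.integer(ix) +
         grid$dims[1] * (as.integer(iy) + grid$dims[2] * as.integer(iz))
  idx[!ok] <- NA_integer_
  idx
}

#' Voxel center coordinates
#'
#' @param grid a [gist_grid()].
#' @param voxels linear indices; default all voxels.
#' @return n x 3 matrix of voxel centers (Angstrom), in linear-index order.
#' @export
voxel_centers <- function(grid, voxels = NULL) {
  if (is.null(voxels)) voxels <- seq_len(grid$n_voxels)
  v0 <- voxels - 1L
  ix <- v0 %% grid$dims[1]
  iy <- (v0 %/% grid$dims[1]) %% grid$dims[2]
  iz <- v0 %/% (grid$dims[1] * grid$dims[2])
  cbind(grid$origin[1] + (ix + 0.5) * grid$spacing,
        grid$origin[2] + (iy + 0.5) * grid$spacing,
        grid$origin[3] + (iz + 0.5) * grid$spacing)
}

#' Accumulate per-voxel, per-species visit counts
#'
#' Every solvent molecule inside the grid increments exactly one voxel's
#' count for its species, in every frame.  Molecules outside the grid are
#' not counted (they still take part in energies and neighbor searches
#' elsewhere in the pipeline).
#'
#' @param frames list of [md_frame()]s.
#' @param topology a [mixture_topology()].
#' @param grid a [gist_grid()].
#' @return The grid with `counts` (`n_voxels` x 3 matrix, columns
#'   `wat`/`cation`/`anion`, raw totals over frames) and `n_frames` set.
#' @export
accumulate_counts <- function(frames, topology, grid) {
  counts <- matrix(0, nrow = grid$n_voxels, ncol = 3L,
                   dimnames = list(NULL, .SPECIES))
  solv <- .solvent_mols(topology)
  sp <- match(topology$mol$species[solv], .SPECIES)
  catom <- topology$mol$center_atom[solv]
  for (fr in frames) {
    vox <- assign_voxel(fr$xyz[catom, , drop = FALSE], grid)
    for (s in 1:3) {
      v <- vox[sp == s & !is.na(vox)]
      if (length(v) > 0L)
        counts[, s] <- counts[, s] + tabulate(v, nbins = grid$n_voxels)
    }
  }
  grid$counts <- counts
  grid$n_frames <- length(frames)
  grid
}

#' Frame-averaged occupancy density on a fine grid
#'
#' Histograms molecule centers of one species on a fine lattice tiling the
#' periodic box exactly, averaged over frames and normalized by a reference
#' density so that homogeneous bulk gives 1.0.  Counts are frame-averaged
#' first, then normalized.
#'
#' @param frames list of [md_frame()]s.
#' @param topology a [mixture_topology()].
#' @param species one of `"wat"`, `"cation"`, `"anion"`.
#' @param rho_ref reference number density (1/Angstrom^3) for normalization.
#' @param spacing requested fine spacing (Angstrom, default 0.25); the actual
#'   per-dimension spacing divides the box length exactly.
#' @return List of class `fine_density`: `values` (numeric array vector, x
#'   fastest), `dims`, `spacing` (per-dim), `origin` (lower corner `-box/2`),
#'   `box`, `species`, `rho_ref`, `n_frames`.
#' @export
fine_density_grid <- function(frames, topology, species, rho_ref,
                              spacing = 0.25) {
  stopifnot(length(frames) > 0L, species %in% .SPECIES)
  box <- frames[[1L]]$box
  dims <- pmax(1L, as.integer(round(box / spacing)))
  sp_actual <- box / dims
  origin <- -box / 2
  acc <- numeric(prod(dims))
  solv <- .solvent_mols(topology)
  catom <- topology$mol$center_atom[solv[topology$mol$species[solv] == species]]
  for (fr in frames)
    cpp_bin_positions(fr$xyz[catom, , drop = FALSE], dims, sp_actual,
                      origin, acc)
  cellvol <- prod(sp_actual)
  vals <- acc / (length(frames) * cellvol * rho_ref)
  structure(list(values = vals, dims = dims, spacing = sp_actual,
                 origin = origin, box = box, species = species,
                 rho_ref = rho_ref, n_frames = length(frames)),
            class = "fine_density")
}

#' Spherical-shell mean densities around voxel centers
#'
#' For every voxel of `grid`, the mean of the fine-grid relative density
#' over fine cells whose centers fall in each radial shell
#' `[l*dd, (l+1)*dd)` around the voxel center.  This is the discretized
#' G_s(r, d) entering the second-order entropy.  A uniform fine grid of
#' density g yields G = g in every populated shell.
#'
#' Shells narrower than the fine spacing can hold very few (or no) cell
#' centers, making their means badly conditioned.  Under-supported shells
#' are therefore pooled adaptively with neighboring shells: the window
#' around a bin grows until the pooled estimate rests on enough fine-grid
#' sampling (`min_support` expected occupancy counts for count-based fine
#' grids; at least one cell otherwise).  The radial profile is smooth on
#' the shell scale, so pooling trades negligible resolution for a large
#' variance reduction.
#'
#' @param fine a [fine_density_grid()] result (or compatible list).
#' @param grid the (coarse) [gist_grid()] whose voxel centers are used.
#' @param dd radial bin width (Angstrom, default 0.125).
#' @param n_bins number of radial bins (default covers 10 Angstrom).
#' @param periodic wrap the fine grid periodically (default `TRUE`); when
#'   `FALSE`, cells beyond the stored fine grid take the bulk value 1.0.
#' @param min_support minimal expected occupancy count (at bulk density)
#'   supporting a shell estimate before pooling stops; 0 (default) pools
#'   only empty shells.  Requires `fine` to carry `rho_ref` and `n_frames`
#'   for the conversion to cell counts.
#' @return Object of class `shell_density`: `G` (`n_voxels` x `n_bins`
#'   matrix of pooled shell means), `support` (matrix of expected occupancy
#'   counts behind each estimate, `NA` if not derivable), `dd`, `n_bins`,
#'   `fine_spacing`, `empty_bins` (logical matrix: pooled beyond the own
#'   bin).
#' @export
shell_density <- function(fine, grid, dd = 0.125,
                          n_bins = as.integer(ceiling(10 / dd)),
                          periodic = TRUE, min_support = 0) {
  if (max(fine$spacing) > dd + 1e-9 && !periodic)
    stop("fine grid spacing must not exceed the radial bin width")
  if (!periodic) {
    reach <- n_bins * dd
    ext <- fine$origin + fine$dims * fine$spacing
    glo <- grid$origin; ghi <- grid$origin + grid$dims * grid$spacing
    if (any(glo - reach < fine$origin - 1e-9) || any(ghi + reach > ext + 1e-9))
      stop("fine grid too small to cover the outermost shell")
  }
  .shell_densities(list(fine), grid, dd, n_bins, periodic,
                   min_support)[[1L]]
}

## Shared implementation: several species' fine grids on one lattice are
## shell-integrated in a single pass.
.shell_densities <- function(fines, grid, dd, n_bins, periodic,
                             min_support) {
  f1 <- fines[[1L]]
  vals <- do.call(cbind, lapply(fines, function(f) {
    stopifnot(identical(f$dims, f1$dims))
    f$values
  }))
  centers <- voxel_centers(grid)
  raw <- cpp_shell_density(vals, f1$dims, f1$spacing, f1$origin, centers,
                           dd, as.integer(n_bins), periodic)
  cellvol <- prod(f1$spacing)
  out <- vector("list", length(fines))
  names(out) <- names(fines)
  for (i in seq_along(fines)) {
    fine <- fines[[i]]
    ## convert the support threshold from occupancy counts to fine cells
    per_cell <- if (!is.null(fine$rho_ref) && !is.null(fine$n_frames))
      fine$rho_ref * cellvol * fine$n_frames else NA_real_
    thr_cells <- if (min_support > 0 && is.finite(per_cell))
      min_support / per_cell else 1.0
    pooled <- cpp_pool_shells(raw$sum[[i]], raw$cnt, thr_cells)
    support <- if (is.finite(per_cell)) pooled$cells * per_cell
               else matrix(NA_real_, nrow(pooled$G), ncol(pooled$G))
    out[[i]] <- structure(
      list(G = pooled$G, support = support, dd = dd,
           n_bins = as.integer(n_bins), fine_spacing = fine$spacing,
           species = fine$species, empty_bins = raw$cnt == 0),
      class = "shell_density")
  }
  out
}
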