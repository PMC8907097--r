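## Reference number densities from the bulk-like region of the analyzed box.
##
## Rather than taking tabulated bulk densities, the reference density of
## every species is recomputed from the region of the box at least a cutoff
## away from the solute (default 12 Angstrom).  This absorbs the small
## composition shift that the solute induces on the rest of the box and
## removes the box-volume dependence of the entropy reference.

#' Bulk reference densities per species
#'
#' Counts molecule centers in the bulk-like region (minimum-image distance
#' of at least `cutoff` from every solute heavy atom), averaged over frames,
#' divided by the region volume.  The region volume is computed by seeded
#' Monte-Carlo integration over the box; with no solute the region is the
#' whole box and the volume is exact.
#'
#' @param frames list of [md_frame()]s.
#' @param topology a [mixture_topology()].
#' @param solute_xyz solute heavy-atom coordinates (m x 3) or `NULL` for a
#'   solute-free box.
#' @param cutoff bulk-region distance cutoff (Angstrom, default 12).
#' @param n_mc Monte-Carlo points for the region volume (default 1e6).
#' @param seed seed for the volume integration (logged in the result).
#' @return Object of class `bulk_reference`: `rho_inf` (named, 1/Angstrom^3),
#'   `concentration` (named, mol/L), `region_volume` (Angstrom^3),
#'   `box_volume`, `cutoff`, `seed`, `mean_counts`.
#' @export
bulk_density <- function(frames, topology, solute_xyz = NULL, cutoff = 12,
                         n_mc = 1e6, seed = 1L) {
  stopifnot(length(frames) > 0L)
  box <- frames[[1L]]$box
  V_box <- prod(box)
  has_solute <- !is.null(solute_xyz) && nrow(as.matrix(solute_xyz)) > 0L
  if (has_solute) {
    if (min(box) / 2 < cutoff)
      stop("box too small for bulk reference: half box ",
           signif(min(box) / 2, 4), " A < cutoff ", cutoff, " A")
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
    P <- cbind(runif(n_mc, -box[1] / 2, box[1] / 2),
               runif(n_mc, -box[2] / 2, box[2] / 2),
               runif(n_mc, -box[3] / 2, box[3] / 2))
    dmin <- .min_image_dist_to_points(P, as.matrix(solute_xyz), box)
    frac <- mean(dmin >= cutoff)
    V_region <- frac * V_box
    if (V_region < 0.1 * V_box)
      stop("box too small for bulk reference: bulk region is ",
           signif(100 * frac, 3), "% of the box")
  } else {
    V_region <- V_box
  }
  mean_counts <- setNames(numeric(3L), .SPECIES)
  for (s in .SPECIES) {
    mols <- which(topology$mol$species == s)
    if (length(mols) == 0L) next
    catom <- topology$mol$center_atom[mols]
    tot <- 0
    for (fr in frames) {
      X <- fr$xyz[catom, , drop = FALSE]
      if (has_solute) {
        dmin <- .min_image_dist_to_points(X, as.matrix(solute_xyz), fr$box)
        tot <- tot + sum(dmin >= cutoff)
      } else {
        tot <- tot + nrow(X)
      }
    }
    mean_counts[s] <- tot / length(frames)
  }
  rho <- mean_counts / V_region
  structure(list(rho_inf = rho, concentration = concentration(rho),
                 region_volume = V_region, box_volume = V_box,
                 cutoff = cutoff, seed = as.integer(seed),
                 mean_counts = mean_counts),
            class = "bulk_reference")
}

#' @export
print.bulk_reference <- function(x, ...) {
  cat("bulk_reference (cutoff", x$cutoff, "A, region",
      signif(x$region_volume, 6), "A^3):\n")
  for (s in names(x$rho_inf))
    cat(sprintf("  %-7s rho_inf = %.6g A^-3  (%.4f mol/L)\n", s,
                x$rho_inf[[s]], x$concentration[[s]]))
  invisible(x)
}

#' Number density to molar concentration
#'
#' `c = rho * 1e27 / N_A` with Avogadro's constant `N_A = 6.02214076e23`;
#' the factor 1e27 converts 1/Angstrom^3 to 1/L.
#'
#' @param rho number density (1/Angstrom^3), vectorized.
#' @return Concentration in mol/L.
#' @examples
#' concentration(6.190e-4)   # about 1.028 mol/L
#' @export
concentration <- function(rho) {
  stopifnot(all(rho >= 0, na.rm = TRUE))
  rho * 1e27 / .N_A
}

#' Salt concentration of a bulk reference
#'
#' The cation and anion concentrations of a finite box are not numerically
#' equal; their arithmetic mean defines the salt concentration used for the
#' Setschenow fit.
#'
#' @param ref a [bulk_density()] result.
#' @return Salt concentration in mol/L.
#' @export
salt_concentration <- function(ref) {
  cc <- ref$concentration[c("cation", "anion")]
  if (any(is.na(cc)) || any(cc <= 0))
    stop("both ion species must be present for a salt concentration")
  mean(cc)
}

## RNG bookkeeping: seeded helpers must not disturb the caller's stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
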