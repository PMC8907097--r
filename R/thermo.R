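## Region integration, free-energy assembly, Setschenow fit.

#' Integrate a voxel field over the solute neighborhood
#'
#' Sums the per-voxel values of all voxels whose centers lie within `cutoff`
#' of any solute heavy atom (voxel membership by center distance, which is
#' deterministic).  With `solute_xyz = NULL` the whole grid is integrated.
#'
#' @param field numeric vector over voxels (e.g. an energy or TdS field in
#'   kcal/mol per voxel).
#' @param grid the [gist_grid()] the field lives on.
#' @param solute_xyz solute heavy-atom coordinates (m x 3) or `NULL`.
#' @param cutoff integration cutoff (Angstrom, default 6; second-order
#'   fields are conventionally integrated to 10).
#' @return The region integral (same units as the field).  Linear in the
#'   field and additive over disjoint regions.
#' @export
integrate_region <- function(field, grid, solute_xyz = NULL, cutoff = 6) {
  stopifnot(length(field) == grid$n_voxels)
  if (is.null(solute_xyz) || nrow(as.matrix(solute_xyz)) == 0L)
    return(sum(field))
  if (cutoff <= 0) return(0)
  cen <- voxel_centers(grid)
  mind <- .min_dist_to_points(cen, as.matrix(solute_xyz))
  sum(field[mind <= cutoff])
}

#' Assemble the solvation free energy from its components
#'
#' Bookkeeping of `dA = dE_uv + dE_vv - sum(TdS terms)`.  Every inclusion
#' is logged term by term so the reported value can be recomputed exactly
#' from the component log.  The optional higher-order water scaling replaces
#' the explicit water-water second-order term by scaling the first-order
#' water entropy with `1 - 0.4 = 0.6` (empirical estimate that second and
#' higher orders amount to about -0.4 times the first-order water entropy);
#' requesting both at once is a double-counting error.
#'
#' @param dE_uv,dE_vv region-integrated energies (kcal/mol).
#' @param TdS_six_wat region-integrated first-order water TdS (kcal/mol).
#' @param TdS_trans_cation,TdS_trans_anion ion first-order TdS (kcal/mol).
#' @param TdS_second named numeric vector of second-order TdS integrals per
#'   ordered pair (e.g. `"wat:cation"`), or `NULL`.
#' @param water_scaling if `TRUE`, scale the water first-order entropy by
#'   0.6 in place of an explicit water-water second-order term.
#' @param scaling_factor the replacement factor (default 0.6).
#' @return Object of class `solvation_summary`: `dA` (kcal/mol), `terms`
#'   (named vector of every logged contribution, where entropy terms enter
#'   `dA` with a minus sign), `options`.
#' @export
assemble_free_energy <- function(dE_uv, dE_vv, TdS_six_wat = 0,
                                 TdS_trans_cation = 0, TdS_trans_anion = 0,
                                 TdS_second = NULL, water_scaling = FALSE,
                                 scaling_factor = 0.6) {
  if (water_scaling && !is.null(TdS_second) &&
      "wat:wat" %in% names(TdS_second))
    stop(paste("double counting: water-water second order and the",
               "higher-order water scaling cannot both be included"))
  f <- if (water_scaling) scaling_factor else 1.0
  terms <- c(dE_uv = dE_uv, dE_vv = dE_vv,
             TdS_six_wat = f * TdS_six_wat,
             TdS_trans_cation = TdS_trans_cation,
             TdS_trans_anion = TdS_trans_anion)
  if (!is.null(TdS_second) && length(TdS_second) > 0L)
    terms <- c(terms, setNames(as.numeric(TdS_second),
                               paste0("TdS2_", names(TdS_second))))
  entropy <- grepl("^TdS", names(terms))
  dA <- sum(terms[!entropy]) - sum(terms[entropy])
  structure(list(dA = dA, terms = terms,
                 options = list(water_scaling = water_scaling,
                                scaling_factor = scaling_factor)),
            class = "solvation_summary")
}

#' @export
print.solvation_summary <- function(x, ...) {
  cat("solvation free energy assembly (kcal/mol):\n")
  for (nm in names(x$terms)) {
    sign <- if (grepl("^TdS", nm)) "-" else "+"
    cat(sprintf("  %s %-18s %10.4f\n", sign, nm, x$terms[[nm]]))
  }
  cat(sprintf("  = dA_solv            %10.4f\n", x$dA))
  if (x$options$water_scaling)
    cat("  (water first-order entropy scaled by",
        x$options$scaling_factor, "in lieu of water-water second order)\n")
  invisible(x)
}

#' Setschenow (salting-out) constant from a concentration series
#'
#' Fits the linear relation
#' `dG_solv(c) = dG0 + R*T*ln(10) * K_S * c` by ordinary least squares and
#' reports `K_S = slope / (R*T*ln 10)` in L/mol (decadic convention), with
#' the standard error of the slope scaled by the same factor.
#'
#' @param concentration salt concentrations (mol/L), at least 3 points with
#'   at least 2 distinct values.
#' @param dG solvation free energies (kcal/mol), same length.
#' @param temperature K (default 300).
#' @return Object of class `setschenow_fit`: `K_S`, `K_S_stderr` (L/mol),
#'   `slope`, `slope_stderr` (kcal/(mol*M)), `intercept` (`dG0`, kcal/mol),
#'   `temperature`, `n`, and the underlying `lm` fit.
#' @export
setschenow_fit <- function(concentration, dG, temperature = 300) {
  if (length(concentration) != length(dG))
    stop("concentration and dG must have equal length")
  if (length(concentration) < 3L)
    stop("need at least 3 points for a Setschenow fit")
  if (length(unique(concentration)) < 2L)
    stop("need at least 2 distinct concentrations")
  fit <- lm(dG ~ concentration)
  sm <- suppressWarnings(summary(fit))   # noise-free series fit exactly
  slope <- coef(fit)[["concentration"]]
  se <- sm$coefficients["concentration", "Std. Error"]
  denom <- .GAS_R * temperature * log(10)
  structure(list(K_S = slope / denom, K_S_stderr = se / denom,
                 slope = slope, slope_stderr = se,
                 intercept = coef(fit)[["(Intercept)"]],
                 temperature = temperature, n = length(dG), fit = fit),
            class = "setschenow_fit")
}

#' @export
print.setschenow_fit <- function(x, ...) {
  cat(sprintf("Setschenow fit (n = %d, T = %g K):\n", x$n, x$temperature))
  cat(sprintf("  K_S  = %.4f +/- %.4f L/mol\n", x$K_S, x$K_S_stderr))
  cat(sprintf("  dG0  = %.4f kcal/mol, slope = %.4f kcal/(mol*M)\n",
              x$intercept, x$slope))
  invisible(x)
}
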