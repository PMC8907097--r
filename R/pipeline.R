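## End-to-end pipeline: counts -> energies -> bulk fit -> reference
## densities -> first-order entropy -> (optional) second order/KSA ->
## region integration -> summary.  Every run writes the fully resolved
## configuration next to its outputs; all randomized steps (the bulk-volume
## Monte Carlo) are seeded from the configuration, so identical config and
## inputs give bit-identical outputs.

#' Build a run configuration
#'
#' Returns the default configuration, with any nested overrides applied.
#' Defaults: 81x81x81 grid at 0.5 Angstrom; energy cutoff 10, bulk-energy
#' region 16, reference-density region 12, rdf cutoff 10, integration
#' region 6 (all Angstrom); temperature 300 K; second-order lattice at 1
#' Angstrom with 0.125 Angstrom radial bins and 0.25 Angstrom fine grid.
#'
#' @param ... nested overrides, e.g. `grid = list(dims = c(25, 25, 25))`.
#' @return Nested list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    paths = list(topology = NULL, trajectory = NULL, out_dir = NULL),
    species = NULL,
    grid = list(center = c(0, 0, 0), dims = c(81L, 81L, 81L),
                spacing = 0.5),
    energy = list(cutoff = 10.0, bulk_cutoff = 16.0,
                  coulomb_constant = 332.0637),
    reference = list(cutoff = 12.0, n_mc = 1e6),
    entropy = list(temperature = 300.0, reference_offset_six = 0.0,
                   orient_norm = "voxel"),
    second_order = list(enabled = TRUE, grid_spacing = 1.0,
                        grid_dims = c(41L, 41L, 41L), bin_width = 0.125,
                        cutoff = 10.0, fine_spacing = 0.25,
                        bulk_cutoff = 12.0, shell_min_support = 25),
    integration = list(cutoff = 6.0, second_order_cutoff = 10.0),
    assembly = list(second_order = "ksa", exclude_pairs = "wat:wat",
                    water_scaling = FALSE),
    output = list(dx_fields = c("E_uv", "dE_vv", "TdS_six_wat")),
    seed = 1L)
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from JSON
#'
#' @param path JSON file of (possibly partial) configuration entries;
#'   missing entries take the [run_config()] defaults.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, doc)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full solvation analysis pipeline
#'
#' Executes every stage on a topology/trajectory pair (from `config$paths`,
#' or passed in memory) and, when `out_dir` is set, writes the per-voxel
#' CSV, OpenDX grids, a summary JSON, the resolved configuration, and a log.
#'
#' @param config a [run_config()].
#' @param topology optional in-memory [mixture_topology()] (otherwise read
#'   from `config$paths$topology`).
#' @param frames optional in-memory frame list (otherwise read from
#'   `config$paths$trajectory`).
#' @return List of class `gist_run`: `grid`, `energies`, `bulk_model`,
#'   `reference`, `entropy1`, `entropy2` (full/KSA/report or `NULL`),
#'   `integrals`, `summary` ([assemble_free_energy()] result), `config`.
#' @export
run_pipeline <- function(config = run_config(), topology = NULL,
                         frames = NULL) {
  cfg <- config
  ## -- validation before any compute
  if (is.null(topology) && is.null(cfg$paths$topology))
    stop("config validation: no topology given")
  if (is.null(frames) && is.null(cfg$paths$trajectory))
    stop("config validation: no trajectory given")
  if (!is.null(cfg$paths$topology) && is.null(topology) &&
      !file.exists(cfg$paths$topology))
    stop("config validation: topology file not found: ",
         cfg$paths$topology)
  if (!is.null(cfg$paths$trajectory) && is.null(frames) &&
      !file.exists(cfg$paths$trajectory))
    stop("config validation: trajectory file not found: ",
         cfg$paths$trajectory)

  if (is.null(topology))
    topology <- .stage("load_topology",
                       load_topology(cfg$paths$topology, cfg$species))
  if (is.null(frames))
    frames <- .stage("read_frames",
                     read_frames(cfg$paths$trajectory, topology))
  if (length(frames) == 0L) stop("pipeline: empty trajectory")
  solute_xyz <- frames[[1L]]$xyz[topology$solute_heavy, , drop = FALSE]

  message("stage counts: ", length(frames), " frames")
  grid <- gist_grid(cfg$grid$center, cfg$grid$dims, cfg$grid$spacing)
  grid <- .stage("counts", accumulate_counts(frames, topology, grid))

  message("stage energies")
  ve <- .stage("energies",
               accumulate_energies(frames, topology, grid,
                                   cutoff = cfg$energy$cutoff,
                                   coulomb_constant =
                                     cfg$energy$coulomb_constant))
  bulk_model <- .stage("bulk_fit",
                       fit_bulk_energy(ve, solute_xyz = solute_xyz,
                                       cutoff = cfg$energy$bulk_cutoff))
  ve <- .stage("reference_energy", reference_energy(ve, bulk_model))

  message("stage reference densities")
  ref <- .stage("reference_density",
                bulk_density(frames, topology, solute_xyz,
                             cutoff = cfg$reference$cutoff,
                             n_mc = cfg$reference$n_mc, seed = cfg$seed))
  rho <- ref$rho_inf[ref$rho_inf > 0]

  message("stage first-order entropy")
  fo <- .stage("first_order_entropy",
               first_order_entropy(frames, topology, grid, rho,
                                   temperature = cfg$entropy$temperature,
                                   reference_offset_six =
                                     cfg$entropy$reference_offset_six,
                                   orient_norm = cfg$entropy$orient_norm))

  so <- NULL
  if (isTRUE(cfg$second_order$enabled)) {
    message("stage second-order entropy")
    so <- .stage("second_order",
                 .run_second_order(frames, topology, cfg, rho, solute_xyz))
  }

  message("stage integration")
  cut1 <- cfg$integration$cutoff
  cut2 <- cfg$integration$second_order_cutoff
  integrals <- list(
    dE_uv = integrate_region(ve$E_uv, grid, solute_xyz, cut1),
    dE_vv = integrate_region(ve$dE_vv, grid, solute_xyz, cut1),
    TdS_six_wat = integrate_region(fo$TdS_six, grid, solute_xyz, cut1),
    TdS_trans_cation = integrate_region(fo$TdS_trans[, "cation"], grid,
                                        solute_xyz, cut1),
    TdS_trans_anion = integrate_region(fo$TdS_trans[, "anion"], grid,
                                       solute_xyz, cut1))
  TdS2 <- NULL
  if (!is.null(so)) {
    sel <- if (cfg$assembly$second_order == "full") so$full else so$ksa
    TdS2 <- vapply(sel$fields, function(f)
      integrate_region(f, so$grid, solute_xyz, cut2), 0.0)
    integrals$TdS_second <- as.list(TdS2)
    if (cfg$assembly$second_order == "none") TdS2 <- NULL
    else TdS2 <- TdS2[setdiff(names(TdS2), cfg$assembly$exclude_pairs)]
  }

  summary <- .stage("assembly",
                    assemble_free_energy(integrals$dE_uv, integrals$dE_vv,
                                         integrals$TdS_six_wat,
                                         integrals$TdS_trans_cation,
                                         integrals$TdS_trans_anion,
                                         TdS_second = TdS2,
                                         water_scaling =
                                           cfg$assembly$water_scaling))

  run <- structure(list(grid = grid, energies = ve,
                        bulk_model = bulk_model, reference = ref,
                        entropy1 = fo, entropy2 = so,
                        integrals = integrals, summary = summary,
                        config = cfg),
                   class = "gist_run")
  if (!is.null(cfg$paths$out_dir)) .write_run(run, topology)
  run
}

## Second-order sub-pipeline on its own coarser lattice.
.run_second_order <- function(frames, topology, cfg, rho, solute_xyz) {
  sc <- cfg$second_order
  cgrid <- gist_grid(cfg$grid$center, sc$grid_dims, sc$grid_spacing)
  cgrid <- accumulate_counts(frames, topology, cgrid)
  species <- names(rho)
  n_bins <- as.integer(ceiling(sc$cutoff / sc$bin_width - 1e-9))
  fines <- lapply(setNames(species, species), function(sp)
    fine_density_grid(frames, topology, sp, rho[[sp]],
                      spacing = sc$fine_spacing))
  shells <- .shell_densities(fines, cgrid, dd = sc$bin_width,
                             n_bins = n_bins, periodic = TRUE,
                             min_support = sc$shell_min_support)
  has_solute <- !is.null(solute_xyz) && nrow(solute_xyz) > 0L
  tables <- list()
  for (nu in species) {
    for (nup in species) {
      nm <- paste0(nu, ":", nup)
      g0 <- bulk_rdf(frames, topology, c(nu, nup), dd = sc$bin_width,
                     cutoff = sc$cutoff,
                     solute_xyz = if (has_solute) solute_xyz else NULL,
                     bulk_cutoff = sc$bulk_cutoff, rho_ref = rho[[nup]])
      tb <- conditional_rdf(frames, topology, cgrid, c(nu, nup),
                            shells[[nup]], rho[[nup]],
                            dd = sc$bin_width, cutoff = sc$cutoff)
      tables[[nm]] <- set_bulk_rdf(tb, g0)
    }
  }
  full <- second_order_entropy(tables, cgrid, rho, mode = "full",
                               temperature = cfg$entropy$temperature)
  ksa <- second_order_entropy(tables, cgrid, rho, mode = "ksa",
                              temperature = cfg$entropy$temperature)
  list(grid = cgrid, tables = tables, full = full, ksa = ksa,
       report = ksa_validity_report(full, ksa))
}

## Output bundle: per-voxel CSV, DX grids, summary + resolved config JSON.
.write_run <- function(run, topology) {
  out <- run$config$paths$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  grid <- run$grid
  counts <- grid$counts / grid$n_frames
  fields <- list(
    N_wat = counts[, "wat"], N_cation = counts[, "cation"],
    N_anion = counts[, "anion"],
    E_uv = run$energies$E_uv, E_vv = run$energies$E_vv,
    E_ref = run$energies$E_ref, dE_vv = run$energies$dE_vv,
    TdS_trans_wat = run$entropy1$TdS_trans[, "wat"],
    TdS_trans_cation = run$entropy1$TdS_trans[, "cation"],
    TdS_trans_anion = run$entropy1$TdS_trans[, "anion"],
    TdS_orient_wat = run$entropy1$TdS_orient,
    TdS_six_wat = run$entropy1$TdS_six)
  write_voxel_csv(fields, grid, file.path(out, "voxels.csv"))
  for (nm in intersect(run$config$output$dx_fields, names(fields)))
    write_dx(fields[[nm]], grid, file.path(out, paste0(nm, ".dx")))
  if (!is.null(run$entropy2)) {
    so <- run$entropy2
    sofields <- c(setNames(so$full$fields,
                           paste0("TdS2_full_", names(so$full$fields))),
                  setNames(so$ksa$fields,
                           paste0("TdS2_ksa_", names(so$ksa$fields))))
    write_voxel_csv(sofields, so$grid, file.path(out, "voxels_second.csv"))
    utils::write.csv(so$report$stats, file.path(out, "ksa_report.csv"),
                     row.names = FALSE)
  }
  summary <- list(
    integrals = run$integrals,
    dA_solv = run$summary$dA,
    terms = as.list(run$summary$terms),
    reference = list(rho_inf = as.list(run$reference$rho_inf),
                     concentration = as.list(run$reference$concentration),
                     region_volume = run$reference$region_volume,
                     seed = run$reference$seed),
    bulk_energy = list(
      coefficients = as.list(run$bulk_model$coefficients),
      se = as.list(run$bulk_model$se),
      n_bulk_voxels = run$bulk_model$n_bulk_voxels),
    topology_counts = as.list(topology$counts),
    n_frames = grid$n_frames)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(run$config), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' @export
print.gist_run <- function(x, ...) {
  cat("gist_run over", x$grid$n_frames, "frames\n")
  cat("  grid:", paste(x$grid$dims, collapse = "x"), "at",
      x$grid$spacing, "A\n")
  for (nm in names(x$integrals)) {
    v <- x$integrals[[nm]]
    if (is.list(v))
      cat("  ", nm, ": ", paste(names(v), signif(unlist(v), 4),
                                sep = "=", collapse = ", "), "\n", sep = "")
    else cat(sprintf("  %-18s %10.4f kcal/mol\n", nm, v))
  }
  cat(sprintf("  dA_solv = %.4f kcal/mol\n", x$summary$dA))
  invisible(x)
}
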