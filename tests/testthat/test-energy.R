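test_that("atom pair energy reproduces closed-form LJ and Coulomb values", {
  topo <- make_param_topology(n_wat = 2, wat_charge = 0, wat_sigma = 3.0,
                              wat_epsilon = 0.2)
  box <- c(40, 40, 40)
  o1 <- topo$mol$center_atom[topo$mol$species == "wat"]
  ## neutral atoms at r = sigma: LJ term vanishes
  fr <- make_frame(topo, rbind(c(0, 0, 0), c(3.0, 0, 0)), box)
  expect_equal(pair_energy(o1[1], o1[2], fr, topo, cutoff = 10), 0,
               tolerance = 1e-12)
  ## r = 2^(1/6) sigma: the LJ minimum, -epsilon
  fr <- make_frame(topo, rbind(c(0, 0, 0), c(2^(1 / 6) * 3.0, 0, 0)), box)
  expect_equal(pair_energy(o1[1], o1[2], fr, topo, cutoff = 10), -0.2,
               tolerance = 1e-12)
  ## +1/-1 charges without LJ at 3.0 A: 332.0637 * (-1) / 3
  topo2 <- make_param_topology(n_wat = 0, n_cation = 1, n_anion = 1)
  ions <- topo2$mol$center_atom[topo2$mol$species != "solute"]
  topo2$atoms$epsilon[ions] <- 0
  fr <- make_frame(topo2, rbind(c(0, 0, 0.5), c(3.0, 0, 0.5)), box)
  e <- pair_energy(ions[1], ions[2], fr, topo2, cutoff = 10)
  expect_equal(e, -110.6879, tolerance = 1e-6)
  ## symmetry is exact
  expect_identical(e, pair_energy(ions[2], ions[1], fr, topo2, cutoff = 10))
  ## beyond the cutoff the energy is zero
  expect_equal(pair_energy(ions[1], ions[2], fr, topo2, cutoff = 2.9), 0)
  ## overlapping atoms are an error
  fr <- make_frame(topo2, rbind(c(1, 1, 1), c(1, 1, 1 + 1e-9)), box)
  expect_error(pair_energy(ions[1], ions[2], fr, topo2), "overlapping")
  ## minimum image: 3 A apart across the boundary
  fr <- make_frame(topo2, rbind(c(-19, 0, 0.5), c(18, 0, 0.5)), box)
  expect_equal(pair_energy(ions[1], ions[2], fr, topo2, cutoff = 10),
               -110.6879, tolerance = 1e-6)
})

test_that("voxel energies follow the GIST assignment rules", {
  box <- c(30, 30, 30)
  g <- gist_grid(dims = c(20, 20, 20), spacing = 1)
  ## solute with LJ + one water: whole pair energy lands in the water voxel
  topo <- make_param_topology(n_wat = 1, wat_sigma = 3.0, wat_epsilon = 0.2)
  sol <- topo$atoms$index[topo$atoms$species == "solute"]
  topo$atoms$sigma[sol] <- 3.0; topo$atoms$epsilon[sol] <- 0.2
  r <- 2^(1 / 6) * 3.0
  fr <- make_frame(topo, rbind(c(r, 0, 0)), box)
  ve <- accumulate_energies(list(fr), topo, g, cutoff = 10)
  vox <- assign_voxel(c(r, 0, 0), g)
  expect_equal(ve$E_uv[vox], -0.2, tolerance = 1e-12)
  expect_equal(sum(ve$E_uv), -0.2, tolerance = 1e-12)
  expect_equal(sum(abs(ve$E_vv)), 0)

  ## two waters, no solute interaction: half/half E_vv split
  topo <- make_param_topology(n_wat = 2, wat_sigma = 3.0, wat_epsilon = 0.2)
  fr <- make_frame(topo, rbind(c(-r / 2 - 3, 0, 0), c(r / 2 - 3, 0, 0)), box)
  ve <- accumulate_energies(list(fr), topo, g, cutoff = 10)
  v1 <- assign_voxel(c(-r / 2 - 3, 0, 0), g)
  v2 <- assign_voxel(c(r / 2 - 3, 0, 0), g)
  expect_equal(ve$E_vv[v1], -0.1, tolerance = 1e-12)
  expect_equal(ve$E_vv[v2], -0.1, tolerance = 1e-12)
  expect_equal(sum(ve$E_uv), 0)

  ## ideal gas fixture (all parameters zero): energy fields identically 0
  fx <- gen_ideal_gas(n_wat = 30, n_cation = 3, n_anion = 3,
                      box = c(21, 21, 21), n_frames = 3, seed = 3)
  ve <- accumulate_energies(fx$frames, fx$topology,
                            gist_grid(dims = c(10, 10, 10), spacing = 1))
  expect_true(all(ve$E_uv == 0) && all(ve$E_vv == 0))
})

test_that("half-contributions conserve the total solvent-solvent energy", {
  fx <- gen_mc_fluid(n_wat = 40, n_cation = 4, n_anion = 4,
                     box = c(21, 21, 21), n_frames = 4,
                     n_equil_sweeps = 30, stride_sweeps = 2, seed = 6)
  topo <- fx$topology
  g <- gist_grid(dims = c(40, 40, 40), spacing = 1)  # covers everything
  ve <- accumulate_energies(fx$frames, topo, g, cutoff = 10)
  ## direct double loop over solvent molecule pairs with pair_energy
  total <- 0
  solv <- which(topo$mol$species != "solute")
  for (fr in fx$frames) {
    for (a in seq_along(solv)) {
      for (b in seq_len(a - 1L)) {
        ma <- topo$mol[solv[a], ]; mb <- topo$mol[solv[b], ]
        for (i in ma$first:ma$last) for (j in mb$first:mb$last)
          total <- total + pair_energy(i, j, fr, topo, cutoff = 10)
      }
    }
  }
  total <- total / length(fx$frames)
  expect_equal(sum(ve$E_vv), total, tolerance = 1e-8)
  expect_equal(ve$total_vv, total, tolerance = 1e-8)
})

test_that("bulk energy fit recovers exact per-species energies", {
  set.seed(41)
  K <- 2000L
  counts <- cbind(wat = rpois(K, 40), cation = rpois(K, 2),
                  anion = rpois(K, 2))
  g <- gist_grid(dims = c(10, 10, 20), spacing = 1)
  g$counts <- counts; g$n_frames <- 1L
  truth <- c(-9.5, -98, -105)
  ve <- structure(list(E_vv = as.numeric(counts %*% truth), grid = g,
                       n_frames = 1L), class = "voxel_energies")
  fit <- fit_bulk_energy(ve, solute_xyz = NULL, cutoff = 16)
  expect_equal(unname(fit$coefficients), truth, tolerance = 1e-10)

  ## with Gaussian noise: recovery within 3 standard errors
  ve$E_vv <- as.numeric(counts %*% truth) + rnorm(K, sd = 0.1)
  fit <- fit_bulk_energy(ve, solute_xyz = NULL, cutoff = 16)
  expect_true(all(abs(fit$coefficients - truth) <= 3 * fit$se))

  ## a species absent everywhere is a rank-deficiency error
  g$counts[, "cation"] <- 0
  ve$grid <- g
  expect_error(fit_bulk_energy(ve, solute_xyz = NULL), "rank-deficient")
})

test_that("reference energy applies the fitted bulk model per voxel", {
  g <- gist_grid(dims = c(4, 4, 4), spacing = 1)
  g$counts <- matrix(0, 64, 3, dimnames = list(NULL,
                                               c("wat", "cation", "anion")))
  g$counts[1, "wat"] <- 2     # two frames -> mean count 1.0
  g$n_frames <- 2L
  model <- structure(list(coefficients = c(E_wat = -9.5, E_cation = -98,
                                           E_anion = -105)),
                     class = "bulk_energy_model")
  ve <- structure(list(E_vv = rep(0.5, 64), grid = g, n_frames = 2L),
                  class = "voxel_energies")
  ve <- reference_energy(ve, model)
  expect_equal(ve$E_ref[1], -9.5)
  expect_equal(ve$dE_vv[1], 0.5 - (-9.5))
  ## empty voxels keep a zero reference
  expect_equal(ve$E_ref[2], 0)
  expect_equal(ve$dE_vv[2], 0.5)
})

test_that("solute-free homogeneous box self-references to near-zero dE_vv", {
  fx <- gen_mc_fluid(n_wat = 60, n_cation = 5, n_anion = 5,
                     box = c(21, 21, 21), n_frames = 30,
                     n_equil_sweeps = 60, stride_sweeps = 2, seed = 13)
  g <- gist_grid(dims = c(20, 20, 20), spacing = 1)
  g <- accumulate_counts(fx$frames, fx$topology, g)
  ve <- accumulate_energies(fx$frames, fx$topology, g, cutoff = 10)
  fit <- fit_bulk_energy(ve, solute_xyz = NULL)
  ve <- reference_energy(ve, fit)
  ## grid mean of the referenced field vanishes within twice the standard
  ## error of the mean reference energy implied by the fit
  ref_se <- sum(fit$se * colMeans(g$counts) / g$n_frames)
  expect_lt(abs(mean(ve$dE_vv)), 2 * ref_se)
})
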