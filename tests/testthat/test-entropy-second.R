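test_that("bulk rdf of an ideal gas is flat and matches brute-force counts", {
  fx <- gen_ideal_gas(n_wat = 60, n_cation = 6, n_anion = 6,
                      box = c(13, 13, 13), n_frames = 25, seed = 16)
  g0 <- bulk_rdf(fx$frames, fx$topology, c("wat", "wat"), dd = 0.25,
                 cutoff = 6)
  ## exact agreement with the O(N^2) pair-count oracle
  oracle <- bf_rdf_counts(fx$frames, fx$topology, c("wat", "wat"),
                          dd = 0.25, cutoff = 6)
  expect_equal(g0$counts, oracle)
  ## flat at 1 within 3 Poisson sigma per bin
  lambda <- pmax(oracle, 1)
  z <- (g0$g0 - 1) / (sqrt(lambda) / lambda)
  expect_true(all(abs(z[oracle > 5]) < 3.5))
  ## cross-species pair, same checks
  gx <- bulk_rdf(fx$frames, fx$topology, c("wat", "cation"), dd = 0.25,
                 cutoff = 6)
  expect_equal(gx$counts,
               bf_rdf_counts(fx$frames, fx$topology, c("wat", "cation"),
                             dd = 0.25, cutoff = 6))
  ## empty species is an error
  fx2 <- gen_ideal_gas(n_wat = 10, n_cation = 0, n_anion = 0,
                       box = c(13, 13, 13), n_frames = 2, seed = 1)
  expect_error(bulk_rdf(fx2$frames, fx2$topology, c("wat", "cation"),
                        dd = 0.25, cutoff = 6), "absent")
})

test_that("repulsive-core fluid shows an excluded-volume hole in g0", {
  fx <- gen_mc_fluid(n_wat = 80, n_cation = 0, n_anion = 0,
                     box = c(16, 16, 16),
                     wat = list(charge = 0, sigma = 3.0, epsilon = 0.3),
                     cutoff = 7, n_equil_sweeps = 150, n_frames = 40,
                     stride_sweeps = 3, seed = 18)
  g0 <- bulk_rdf(fx$frames, fx$topology, c("wat", "wat"), dd = 0.25,
                 cutoff = 7)
  inner <- g0$d < 2.4        # deep inside the repulsive core
  expect_true(all(g0$g0[inner] < 0.05))
  ## and approaches 1 in the outermost 10% of bins
  outer <- g0$d > 0.9 * max(g0$d)
  expect_lt(abs(mean(g0$g0[outer]) - 1), 0.15)
})

test_that("conditional rdf is flat for a homogeneous system", {
  fx <- gen_ideal_gas(n_wat = 80, n_cation = 0, n_anion = 0,
                      box = c(13, 13, 13), n_frames = 60, seed = 19)
  topo <- fx$topology
  rho <- 80 / 13^3
  cg <- gist_grid(dims = c(6, 6, 6), spacing = 1)
  cg <- accumulate_counts(fx$frames, topo, cg)
  fine <- fine_density_grid(fx$frames, topo, "wat", rho, spacing = 0.25)
  sh <- shell_density(fine, cg, dd = 0.25, n_bins = 24, periodic = TRUE)
  tb <- conditional_rdf(fx$frames, topo, cg, c("wat", "wat"), sh, rho,
                        dd = 0.25, cutoff = 6)
  ## populated bins scatter around 1 within 3 Poisson sigma (95% of bins)
  ok <- !is.na(tb$g_inh) & tb$counts >= 10
  mu <- tb$counts[ok] / tb$g_inh[ok]     # the divisor
  z <- (tb$g_inh[ok] - 1) * mu / sqrt(tb$counts[ok])
  expect_gt(mean(abs(z) < 3), 0.93)
  ## pair-count conservation against the brute-force oracle
  oracle_total <- sum(bf_rdf_counts(fx$frames, topo, c("wat", "wat"),
                                    dd = 0.25, cutoff = 6))
  ## oracle counts every reference; restrict to in-grid references
  expect_equal(sum(tb$counts), tb$pair_count)
  expect_lte(tb$pair_count, oracle_total)
  ## voxels never visited are null and contribute nothing
  never <- tb$N_nuk == 0
  if (any(never)) expect_true(all(is.na(tb$g_inh[never, ])))
})

test_that("conditional rdf pair counts conserve exactly on a full-box grid", {
  fx <- gen_ideal_gas(n_wat = 25, n_cation = 4, n_anion = 4,
                      box = c(12, 12, 12), n_frames = 8, seed = 23)
  topo <- fx$topology
  cg <- gist_grid(dims = c(12, 12, 12), spacing = 1)   # covers the box
  cg <- accumulate_counts(fx$frames, topo, cg)
  rho <- 4 / 12^3
  fine <- fine_density_grid(fx$frames, topo, "anion", rho, spacing = 0.25)
  sh <- shell_density(fine, cg, dd = 0.25, n_bins = 24, periodic = TRUE)
  tb <- conditional_rdf(fx$frames, topo, cg, c("wat", "anion"), sh, rho,
                        dd = 0.25, cutoff = 6)
  oracle <- bf_rdf_counts(fx$frames, topo, c("wat", "anion"),
                          dd = 0.25, cutoff = 6)
  expect_equal(sum(tb$counts), sum(oracle))
  expect_equal(unname(colSums(tb$counts)), oracle)
})

test_that("second-order entropy vanishes identically for flat tables", {
  K <- 27L; nb <- 16L
  g <- gist_grid(dims = c(3, 3, 3), spacing = 1)
  g$counts <- matrix(5, K, 3, dimnames = list(NULL,
                                              c("wat", "cation", "anion")))
  g$n_frames <- 5L
  tb <- radial_pair_table(c("wat", "wat"), g_inh = matrix(1, K, nb),
                          g0 = rep(1, nb), G = matrix(1, K, nb), dd = 0.25)
  rho <- c(wat = 0.03, cation = 0.001, anion = 0.001)
  for (mode in c("full", "ksa")) {
    f <- second_order_entropy(list("wat:wat" = tb), g, rho, mode = mode)
    expect_true(all(f$total == 0))
  }
})

test_that("a single-bin table reproduces the hand-evaluated integrand", {
  ## one voxel, one bin: G_s,nu = 1 (counts), G_s,nu' = 2, g_inh = g0 = 2
  g <- gist_grid(dims = c(1, 1, 1), spacing = 1)
  g$counts <- matrix(c(4, 0, 0), 1, 3,
                     dimnames = list(NULL, c("wat", "cation", "anion")))
  g$n_frames <- 2L
  rho_wat <- 2.0   # voxel density 4/(2*1*rho) = 1 -> G_s,nu = 1
  dd <- 0.5
  tb <- radial_pair_table(c("wat", "wat"), g_inh = matrix(2, 1, 1),
                          g0 = 2, G = matrix(2, 1, 1), dd = dd)
  f <- second_order_entropy(list("wat:wat" = tb),
                            g, c(wat = rho_wat), mode = "full",
                            temperature = 300)
  d_l <- 0.5 * dd
  integrand <- 2 * (2 * log(2) - 2 + 1) - (2 * log(2) - 2 + 1)
  expected <- gist_constants()$R * 300 *
    (-0.5) * rho_wat^2 * 1 * 1 * (4 * pi * d_l^2 * dd) * integrand
  expect_equal(unname(f$total[1]), expected, tolerance = 1e-12)
  ## the same table in KSA mode uses (G - 1) * f(g0)
  fk <- second_order_entropy(list("wat:wat" = tb), g, c(wat = rho_wat),
                             mode = "ksa", temperature = 300)
  expected_k <- gist_constants()$R * 300 *
    (-0.5) * rho_wat^2 * 1 * 1 * (4 * pi * d_l^2 * dd) *
    (2 - 1) * (2 * log(2) - 2 + 1)
  expect_equal(unname(fk$total[1]), expected_k, tolerance = 1e-12)
})

test_that("the g -> 0 limit convention gives the finite value 1", {
  expect_equal(saltgist:::.glng(0), 1)
  expect_equal(saltgist:::.glng(1), 0)
  expect_equal(saltgist:::.glng(2), 2 * log(2) - 1)
})

test_that("KSA report summarizes per-pair agreement", {
  g <- gist_grid(dims = c(3, 3, 3), spacing = 1)
  g$counts <- matrix(5, 27, 3, dimnames = list(NULL,
                                               c("wat", "cation", "anion")))
  g$n_frames <- 5L
  set.seed(33)
  gv <- matrix(runif(27 * 8, 0.5, 1.5), 27, 8)
  tb <- radial_pair_table(c("wat", "wat"), g_inh = gv,
                          g0 = runif(8, 0.8, 1.2), G = gv, dd = 0.25)
  full <- second_order_entropy(list("wat:wat" = tb), g, c(wat = 0.03),
                               mode = "full")
  ## identical fields: slope 1, correlation 1
  rep1 <- ksa_validity_report(full, full)
  expect_equal(rep1$stats$slope, 1)
  expect_equal(rep1$stats$correlation, 1)
  ## all-zero KSA: slope 0, correlation undefined
  zero <- full
  zero$fields[["wat:wat"]] <- rep(0, 27)
  rep0 <- ksa_validity_report(full, zero)
  expect_equal(rep0$stats$slope, 0)
  expect_true(is.na(rep0$stats$correlation))
})
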