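test_that("nearest-neighbor search handles the textbook cases", {
  ## three collinear points at x = 0, 1, 3 in a large box
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
  d <- nn_search(X, box = c(100, 100, 100), metric = "trans")
  expect_equal(d, c(1, 1, 2))
  ## two points at x = 0 and 9 in a 10 A periodic box: minimum image
  X <- rbind(c(0, 0, 0), c(9, 0, 0))
  d <- nn_search(X, box = c(10, 10, 10), metric = "trans")
  expect_equal(d, c(1, 1))
  ## rotational distance between identity and 90 degrees about x
  Q <- rbind(c(1, 0, 0, 0), c(cos(pi / 4), sin(pi / 4), 0, 0))
  dw <- nn_search(NULL, metric = "orient", quaternions = Q,
                  groups = c(1L, 1L))
  expect_equal(dw, c(pi / 2, pi / 2), tolerance = 1e-12)
})

test_that("entropy estimators hit their closed-form anchors", {
  ctx <- estimator_context(n_frames = 100, rho0 = c(wat = 0.0334),
                           temperature = 300)
  gam <- gist_constants()$gamma
  R <- gist_constants()$R
  ## all samples with N_f rho 4/3 pi d^3 = exp(-gamma): the log cancels gamma
  d0 <- (exp(-gam) * 3 / (4 * pi * 100 * 0.0334))^(1 / 3)
  expect_equal(s_trans(rep(d0, 7), ctx, "wat"), 0, tolerance = 1e-12)
  ## ... = 1: S = R * gamma
  d1 <- (3 / (4 * pi * 100 * 0.0334))^(1 / 3)
  expect_equal(s_trans(rep(d1, 7), ctx, "wat"), R * gam, tolerance = 1e-12)
  ## orientational anchors with N_k inside the logarithm
  w0 <- (exp(-gam) * 6 * pi / 5)^(1 / 3)
  expect_equal(s_orient(rep(w0, 5), n_k = 5, ctx), 0, tolerance = 1e-12)
  w1 <- (6 * pi / 5)^(1 / 3)
  expect_equal(s_orient(rep(w1, 5), n_k = 5, ctx), R * gam,
               tolerance = 1e-12)
  ## six-dimensional anchors
  s0 <- (exp(-gam) * 48 / (pi * 100 * 0.0334))^(1 / 6)
  expect_equal(s_six(rep(s0, 4), ctx, "wat"), 0, tolerance = 1e-12)
  s1 <- (exp(1) * 48 / (pi * 100 * 0.0334))^(1 / 6)
  expect_equal(s_six(s1, ctx, "wat"), R * (gam + 1), tolerance = 1e-12)
  ## degenerate inputs give a flagged null, never NaN
  expect_true(is.na(s_trans(c(0, 0), ctx, "wat")))
  expect_true(is.na(s_orient(numeric(0), 0, ctx)))
})

test_that("accelerated search equals brute force on all three metrics", {
  set.seed(5)
  n <- 400
  box <- c(8, 8, 8)
  X <- cbind(runif(n, -4, 4), runif(n, -4, 4), runif(n, -4, 4))
  Q <- random_quaternions(n)
  for (per in c(TRUE, FALSE)) {
    expect_equal(nn_search(X, box, "trans", periodic = per),
                 bf_nn_trans(X, if (per) box else NULL), tolerance = 1e-12)
    expect_equal(nn_search(X, box, "six", quaternions = Q, periodic = per),
                 bf_nn_six(X, Q, if (per) box else NULL), tolerance = 1e-12)
  }
  groups <- sample(1:20, n, replace = TRUE)
  expect_equal(nn_search(NULL, metric = "orient", quaternions = Q,
                         groups = groups),
               bf_nn_orient(Q, groups), tolerance = 1e-12)
})

test_that("low-concentration species still get finite neighbor distances", {
  ## 4 ions in a box with a grid of 1000 voxels: far below one per voxel
  fx <- gen_ideal_gas(n_wat = 10, n_cation = 4, n_anion = 0,
                      box = c(12, 12, 12), n_frames = 6, seed = 14)
  topo <- fx$topology
  ca <- topo$mol$center_atom[topo$mol$species == "cation"]
  pos <- do.call(rbind, lapply(fx$frames, function(fr)
    fr$xyz[ca, , drop = FALSE]))
  d <- nn_search(pos, c(12, 12, 12), "trans")
  expect_true(all(is.finite(d) & d > 0))
})

test_that("uniform sampling drives the voxel entropies to zero", {
  fx <- gen_ideal_gas(n_wat = 150, n_cation = 8, n_anion = 8,
                      box = c(14, 14, 14), n_frames = 250, seed = 21)
  V <- prod(fx$spec$box)
  rho <- c(wat = 150 / V, cation = 8 / V, anion = 8 / V)
  g <- gist_grid(dims = c(8, 8, 8), spacing = 1)
  fo <- first_order_entropy(fx$frames, fx$topology, g, rho,
                            temperature = 300)
  ## occupancy-weighted grid means (kcal/mol per voxel) vanish
  expect_lt(abs(mean(fo$TdS_trans[, "wat"])), 0.005)
  expect_lt(abs(mean(fo$TdS_six)), 0.005)
  expect_lt(abs(mean(fo$TdS_orient)), 0.005)
  expect_lt(abs(mean(fo$TdS_trans[, "cation"])), 0.005)
  ## flagged voxels are exactly the underpopulated ones and hold zero
  expect_true(all(fo$S_trans_norm[fo$flag[, "wat"], "wat"] == 0))
})

test_that("species entropies add voxelwise with ions as translation-only", {
  fx <- gen_ideal_gas(n_wat = 40, n_cation = 5, n_anion = 5,
                      box = c(12, 12, 12), n_frames = 30, seed = 2)
  V <- prod(fx$spec$box)
  rho <- c(wat = 40 / V, cation = 5 / V, anion = 5 / V)
  g <- gist_grid(dims = c(6, 6, 6), spacing = 1)
  fo <- first_order_entropy(fx$frames, fx$topology, g, rho)
  tot <- species_entropy(fo)
  expect_equal(tot, fo$TdS_six + fo$TdS_trans[, "cation"] +
                    fo$TdS_trans[, "anion"])
  tot2 <- species_entropy(fo, water = "trans_orient")
  expect_equal(tot2, fo$TdS_trans[, "wat"] + fo$TdS_orient +
                     fo$TdS_trans[, "cation"] + fo$TdS_trans[, "anion"])
})

test_that("the reference entropy offset shifts the field linearly", {
  fx <- gen_ideal_gas(n_wat = 30, n_cation = 0, n_anion = 0,
                      box = c(12, 12, 12), n_frames = 20, seed = 9)
  V <- prod(fx$spec$box)
  g <- gist_grid(dims = c(6, 6, 6), spacing = 1)
  fo0 <- first_order_entropy(fx$frames, fx$topology, g, c(wat = 30 / V),
                             reference_offset_six = 0)
  off <- 0.0024
  fo1 <- first_order_entropy(fx$frames, fx$topology, g, c(wat = 30 / V),
                             reference_offset_six = off)
  w <- fo0$n_samples[, "wat"] / fo0$ctx$n_frames
  populated <- !fo0$flag[, "wat"]
  expect_equal(fo1$TdS_six[populated],
               (fo0$TdS_six - off * w)[populated], tolerance = 1e-12)
})
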