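test_that("voxel assignment follows the half-open convention", {
  g <- gist_grid()   # 81^3 at 0.5 A, centered on the origin
  center_lin <- 1L + 40L + 81L * (40L + 81L * 40L)
  expect_equal(assign_voxel(c(0, 0, 0), g), center_lin)
  ## half-width is 20.25 A: just beyond is outside
  expect_true(is.na(assign_voxel(c(20.26, 0, 0), g)))
  ## lower edge inclusive, upper edge exclusive
  expect_equal(assign_voxel(c(0.25, 0, 0), g), center_lin + 1L)
  expect_equal(assign_voxel(c(0.2499999, 0, 0), g), center_lin)
})

test_that("count accumulation is exact and linear in frames", {
  topo <- make_param_topology(n_wat = 1)
  g <- gist_grid()
  fr <- make_frame(topo, rbind(c(0, 0, 0)), c(50, 50, 50))
  g1 <- accumulate_counts(list(fr), topo, g)
  center_lin <- assign_voxel(c(0, 0, 0), g)
  expect_equal(unname(g1$counts[center_lin, "wat"]), 1)
  expect_equal(sum(g1$counts), 1)
  ## ten identical frames give exactly ten times the counts
  g10 <- accumulate_counts(rep(list(fr), 10L), topo, g)
  expect_equal(g10$counts, 10 * g1$counts)
})

test_that("counts match a brute-force voxel loop", {
  fx <- gen_ideal_gas(n_wat = 20, n_cation = 3, n_anion = 3,
                      box = c(12, 12, 12), n_frames = 5, seed = 8)
  g <- accumulate_counts(fx$frames, fx$topology,
                         gist_grid(dims = c(8, 8, 8), spacing = 1))
  ref <- matrix(0, g$n_voxels, 3L)
  for (fr in fx$frames) {
    for (m in which(fx$topology$mol$species != "solute")) {
      pos <- fr$xyz[fx$topology$mol$center_atom[m], ]
      v <- assign_voxel(pos, g)
      if (!is.na(v)) {
        s <- match(fx$topology$mol$species[m], c("wat", "cation", "anion"))
        ref[v, s] <- ref[v, s] + 1
      }
    }
  }
  expect_equal(unname(g$counts), ref)
})

test_that("ideal-gas occupancy is Poisson around rho * V * N_f", {
  n_wat <- 200; box <- c(12, 12, 12); n_f <- 400
  fx <- gen_ideal_gas(n_wat = n_wat, n_cation = 0, n_anion = 0,
                      box = box, n_frames = n_f, seed = 12)
  g <- accumulate_counts(fx$frames, fx$topology,
                         gist_grid(dims = c(10, 10, 10), spacing = 1))
  lambda <- n_wat / prod(box) * g$voxel_volume * n_f
  z <- (g$counts[, "wat"] - lambda) / sqrt(lambda)
  expect_gt(mean(abs(z) <= 5), 0.99)
})

test_that("shell densities reproduce uniform, step and Gaussian profiles", {
  g <- gist_grid(dims = c(3, 3, 3), spacing = 1)
  ## synthetic fine grid covering a 20 A box
  dims <- c(80L, 80L, 80L)
  sp <- c(0.25, 0.25, 0.25)
  origin <- c(-10, -10, -10)
  cellcen <- function(i) origin + (i - 0.5) * sp   # i = 1-based triple
  ## uniform density 1 -> G = 1 in every bin, exactly
  fine_u <- list(values = rep(1.0, prod(dims)), dims = dims, spacing = sp,
                 origin = origin, species = "wat")
  sh <- shell_density(fine_u, g, dd = 0.25, n_bins = 20, periodic = FALSE)
  expect_lt(max(abs(sh$G - 1)), 1e-12)

  ## step profile: 2.0 inside a 3 A ball around the center voxel's center
  idx <- as.matrix(expand.grid(i = 1:80, j = 1:80, k = 1:80))
  cen <- sweep(sweep(idx, 2L, c(0.5, 0.5, 0.5)), 2L, sp, "*")
  cen <- sweep(cen, 2L, origin, "+")
  r <- sqrt(rowSums(cen^2))
  fine_s <- fine_u
  fine_s$values <- ifelse(r < 3, 2.0, 0.0)
  sh <- shell_density(fine_s, g, dd = 0.25, n_bins = 20, periodic = FALSE)
  kc <- assign_voxel(c(0, 0, 0), g)
  G <- sh$G[kc, ]
  expect_true(all(abs(G[1:10] - 2.0) < 0.05))   # bins fully inside 3 A
  expect_true(all(G[14:20] < 0.05))             # bins fully outside
  expect_true(all(diff(G[10:14]) <= 1e-9))      # monotonic transition

  ## spherically symmetric Gaussian: shell means match 1-D quadrature
  sigma <- 2.0
  fine_g <- fine_u
  fine_g$values <- exp(-r^2 / (2 * sigma^2))
  sh <- shell_density(fine_g, g, dd = 0.25, n_bins = 20, periodic = FALSE)
  G <- sh$G[kc, ]
  for (l in c(4, 8, 12, 16)) {
    lo <- (l - 1) * 0.25; hi <- l * 0.25
    ## volume-weighted shell mean of the Gaussian by quadrature
    f <- function(x) exp(-x^2 / (2 * sigma^2)) * x^2
    expected <- integrate(f, lo, hi)$value / integrate(function(x) x^2,
                                                       lo, hi)$value
    expect_equal(G[l], expected, tolerance = 0.02)
  }
})

test_that("shell densities are invariant under re-binning", {
  fx <- gen_ideal_gas(n_wat = 150, n_cation = 0, n_anion = 0,
                      box = c(14, 14, 14), n_frames = 150, seed = 31)
  g <- gist_grid(dims = c(4, 4, 4), spacing = 1)
  rho <- 150 / 14^3
  fine <- fine_density_grid(fx$frames, fx$topology, "wat", rho,
                            spacing = 0.25)
  sh1 <- shell_density(fine, g, dd = 0.25, n_bins = 24, periodic = TRUE)
  sh2 <- shell_density(fine, g, dd = 0.5, n_bins = 12, periodic = TRUE)
  ## support-weighted merge of 0.25 A bins equals direct 0.5 A binning
  ## (bins that had to be pooled from neighbors are excluded)
  for (k in c(1, 32, 64)) {
    for (l in 1:12) {
      i <- c(2 * l - 1, 2 * l)
      if (any(sh1$empty_bins[k, i]) || sh2$empty_bins[k, l]) next
      merged <- sum(sh1$G[k, i] * sh1$support[k, i]) /
        sum(sh1$support[k, i])
      expect_equal(merged, unname(sh2$G[k, l]), tolerance = 0.01)
    }
  }
})

test_that("fine grid errors when too small for the outermost shell", {
  g <- gist_grid(dims = c(3, 3, 3), spacing = 1)
  fine <- list(values = rep(1.0, 8^3), dims = c(8L, 8L, 8L),
               spacing = c(0.25, 0.25, 0.25), origin = c(-1, -1, -1),
               species = "wat")
  expect_error(shell_density(fine, g, dd = 0.25, n_bins = 20,
                             periodic = FALSE), "too small")
})

test_that("voxel fields export to OpenDX and back", {
  g <- gist_grid(dims = c(5, 4, 3), spacing = 0.5)
  field <- seq_len(g$n_voxels) * 0.1
  path <- tempfile(fileext = ".dx")
  write_dx(field, g, path)
  back <- read_dx(path)
  expect_equal(back$dims, g$dims)
  expect_equal(back$origin, g$origin)
  expect_equal(back$spacing, g$spacing)
  expect_equal(back$field, field, tolerance = 1e-9)
})
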