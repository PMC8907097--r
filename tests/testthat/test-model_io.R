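test_that("topology construction enforces the mixture invariants", {
  topo <- make_param_topology(n_wat = 3, n_cation = 2, n_anion = 1)
  expect_s3_class(topo, "mixture_topology")
  expect_equal(unname(topo$counts),
               c(1L, 3L, 2L, 1L), ignore_attr = TRUE)
  expect_equal(topo$n_atoms, 1L + 9L + 2L + 1L)
  ## water center is the oxygen
  wat1 <- topo$mol[topo$mol$species == "wat", ][1L, ]
  expect_equal(topo$atoms$name[wat1$center_atom], "O")

  ## a two-atom ion violates monoatomicity
  bad <- list(
    SOL = list(atoms = data.frame(name = "S", charge = 0, sigma = 0,
                                  epsilon = 0, mass = 12)),
    CAT = list(atoms = data.frame(name = c("M", "M2"), charge = c(1, 0),
                                  sigma = 0, epsilon = 0, mass = 20)))
  expect_error(
    mixture_topology(bad, list(list(type = "SOL", count = 1),
                               list(type = "CAT", count = 1)),
                     c(SOL = "solute", CAT = "cation")),
    "monoatomic")

  ## unmapped molecule names are refused by name
  expect_error(
    mixture_topology(bad["SOL"], list(list(type = "SOL", count = 1),
                                      list(type = "NA+", count = 1)),
                     c(SOL = "solute")),
    "unmapped species.*NA\\+")
})

test_that("topology JSON round-trips through write/load", {
  topo <- make_param_topology(n_wat = 4, n_cation = 2, n_anion = 2)
  path <- tempfile(fileext = ".json")
  write_topology(topo, path)
  topo2 <- suppressMessages(load_topology(path))
  expect_equal(topo2$counts, topo$counts)
  expect_equal(topo2$atoms$charge, topo$atoms$charge)
  expect_equal(topo2$atoms$sigma, topo$atoms$sigma)
  expect_equal(topo2$mol$center_atom, topo$mol$center_atom)
})

test_that("built-in trajectory format round-trips to 1e-6 A", {
  fx <- gen_ideal_gas(n_wat = 5, n_cation = 2, n_anion = 2,
                      box = c(10, 10, 10), n_frames = 3, seed = 4)
  path <- tempfile(fileext = ".txt")
  write_frames(fx$frames, fx$topology, path)
  frames2 <- read_frames(path, fx$topology)
  expect_length(frames2, 3L)
  expect_equal(frames2[[1L]]$index, 0L)
  expect_equal(frames2[[3L]]$index, 2L)
  for (f in 1:3) {
    expect_lt(max(abs(frames2[[f]]$xyz - fx$frames[[f]]$xyz)), 1e-6)
    expect_equal(frames2[[f]]$box, fx$frames[[f]]$box)
  }
})

test_that("trajectory reader rejects malformed input", {
  topo <- make_param_topology(n_wat = 1)   # 4 atoms
  path <- tempfile(fileext = ".txt")
  ## 3 atoms declared for a 4-atom topology
  writeLines(c("3 10 10 10", "wat 2 0 0 0", "wat 2 1 0 0", "wat 2 0 1 0"),
             path)
  expect_error(read_frames(path, topo), "atom-count mismatch at frame 0")
  ## empty file: empty sequence with a warning
  writeLines(character(0), path)
  expect_warning(frames <- read_frames(path, topo), "empty")
  expect_length(frames, 0L)
  ## missing box record
  writeLines(c("4", "solute 1 0 0 0"), path)
  expect_error(read_frames(path, topo), "box record")
})

test_that("molecule_center returns the oxygen for water, the atom for ions", {
  topo <- make_param_topology(n_wat = 1, n_cation = 1)
  centers <- rbind(c(1, 2, 3), c(0, 0, 5))
  fr <- make_frame(topo, centers, c(20, 20, 20))
  wat_id <- which(topo$mol$species == "wat")
  ion_id <- which(topo$mol$species == "cation")
  expect_equal(molecule_center(fr, wat_id, topo), c(1, 2, 3))
  expect_equal(molecule_center(fr, ion_id, topo), c(0, 0, 5))
})

test_that("water orientations recover known rotations", {
  topo <- make_param_topology(n_wat = 1)
  wat_id <- which(topo$mol$species == "wat")
  ## reference pose -> identity quaternion
  fr <- make_frame(topo, rbind(c(0, 0, 0)), c(20, 20, 20),
                   quats = rbind(c(1, 0, 0, 0)))
  expect_equal(water_orientation(fr, wat_id, topo), c(1, 0, 0, 0),
               tolerance = 1e-9)
  ## 180 degrees about z -> (0,0,0,1) up to sign
  fr <- make_frame(topo, rbind(c(0, 0, 0)), c(20, 20, 20),
                   quats = rbind(c(0, 0, 0, 1)))
  q <- water_orientation(fr, wat_id, topo)
  expect_equal(abs(q), c(0, 0, 0, 1), tolerance = 1e-9)
  ## 90 degrees about x, constructed with the rotation-matrix oracle
  R <- bf_rotation_matrix(c(1, 0, 0), pi / 2)
  ref <- water_reference_geometry()
  xyz <- matrix(0, topo$n_atoms, 3L)
  m <- topo$mol[wat_id, ]
  for (k in 0:2) xyz[m$first + k, ] <- as.numeric(R %*% ref[k + 1L, ])
  fr <- md_frame(xyz, c(20, 20, 20), 0L)
  q <- water_orientation(fr, wat_id, topo)
  expect_equal(q, c(cos(pi / 4), sin(pi / 4), 0, 0), tolerance = 1e-9)
})

test_that("orientation composes with global rotations", {
  topo <- make_param_topology(n_wat = 1)
  wat_id <- which(topo$mol$species == "wat")
  set.seed(71)
  for (i in 1:10) {
    q0 <- drop(random_quaternions(1))
    fr <- make_frame(topo, rbind(c(0, 0, 0)), c(20, 20, 20),
                     quats = rbind(q0))
    axis <- rnorm(3); angle <- runif(1, 0, pi)
    R <- bf_rotation_matrix(axis, angle)
    xyz <- fr$xyz
    m <- topo$mol[wat_id, ]
    for (k in 0:2) xyz[m$first + k, ] <- as.numeric(R %*% xyz[m$first + k, ])
    fr2 <- md_frame(xyz, fr$box, 0L)
    q1 <- water_orientation(fr, wat_id, topo)
    q2 <- water_orientation(fr2, wat_id, topo)
    ## q2 = q_R * q1 up to the double-cover sign
    qR <- quat_canonical(c(cos(angle / 2), sin(angle / 2) *
                             axis / sqrt(sum(axis^2))))
    expect_equal(abs(sum(q2 * quat_multiply(qR, q1))), 1, tolerance = 1e-9)
  }
})

test_that("degenerate collinear water geometry is refused", {
  topo <- make_param_topology(n_wat = 1)
  m <- topo$mol[topo$mol$species == "wat", ][1L, ]
  xyz <- matrix(0, topo$n_atoms, 3L)
  xyz[m$first + 1L, ] <- c(1, 0, 0)
  xyz[m$first + 2L, ] <- c(2, 0, 0)   # both hydrogens on one axis
  fr <- md_frame(xyz, c(20, 20, 20), 0L)
  expect_error(water_orientation(fr, m$mol, topo), "collinear")
})

test_that("quaternion helpers respect the double cover", {
  q <- c(-0.5, 0.5, 0.5, -0.5)
  expect_equal(quat_canonical(q), -q)
  expect_equal(delta_omega(c(1, 0, 0, 0), c(0, 0, 0, 1)), pi)
  expect_equal(delta_omega(c(1, 0, 0, 0), -c(1, 0, 0, 0)), 0)
  ## rotation matrix consistency
  q <- drop(random_quaternions(1))
  R <- quat_to_matrix(q)
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
})
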