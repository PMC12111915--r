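# MM terms, generalized Born, SASA, binding-energy series.

pair_top <- function() {
  topology(tibble::tibble(
    name = c("Q1", "Q2"), element = "O", resname = c("AAA", "BBB"),
    resid = 1:2
  ))
}

test_that("Coulomb and Lennard-Jones closed forms", {
  top <- pair_top()
  p <- energy_parameters(top, charge = c(1, -1), eps = 0.2, sigma = 3.0,
                         born_radius = 2)
  # +-1e at k/100 angstrom gives exactly -100 kcal/mol
  e <- mm_interaction_energy(rbind(c(0, 0, 0), c(3.320637, 0, 0)), 1, 2, p)
  expect_equal(e$E_coulomb, -100, tolerance = 1e-10)
  # LJ: zero at r = sigma, minimum -eps at r = 2^(1/6) sigma
  e1 <- mm_interaction_energy(rbind(c(0, 0, 0), c(3.0, 0, 0)), 1, 2,
                              energy_parameters(top, charge = 0, eps = 0.2,
                                                sigma = 3, born_radius = 2))
  expect_equal(e1$E_lj, 0, tolerance = 1e-12)
  e2 <- mm_interaction_energy(rbind(c(0, 0, 0), c(2^(1 / 6) * 3, 0, 0)), 1, 2,
                              energy_parameters(top, charge = 0, eps = 0.2,
                                                sigma = 3, born_radius = 2))
  expect_equal(e2$E_lj, -0.2, tolerance = 1e-12)
  # missing parameters are reported with the atoms
  pna <- energy_parameters(top, charge = c(1, NA), eps = 0, sigma = 3,
                           born_radius = 2)
  expect_error(mm_interaction_energy(rbind(c(0, 0, 0), c(3, 0, 0)), 1, 2, pna),
               "missing charge")
})

test_that("GB energy reduces to the Born formula for a single charge", {
  g <- gb_energy(matrix(0, 1, 3), charges = 1, born_radii = 2)
  born <- -(332.0637 / 2) * (1 - 1 / 78.5) * 1 / 2
  expect_equal(g, born, tolerance = 1e-6 * abs(born))
  expect_equal(gb_energy(matrix(0, 2, 3) + c(0, 5), c(0, 0), c(2, 2)), 0)
})

test_that("GB at large separation approaches independent Born plus screened cross", {
  r <- 500
  a <- c(2, 3); q <- c(1, -1)
  xyz <- rbind(c(0, 0, 0), c(r, 0, 0))
  g <- gb_energy(xyz, q, a)
  pref <- -(332.0637 / 2) * (1 - 1 / 78.5)
  expected <- pref * (q[1]^2 / a[1] + q[2]^2 / a[2] + 2 * q[1] * q[2] / r)
  expect_equal(g, expected, tolerance = 1e-6)
})

test_that("SASA matches sphere closed forms and converges", {
  one <- assign_radii(topology(tibble::tibble(
    name = "C1", element = "C", resname = "LIG", resid = 1
  )))
  a <- sasa(one, matrix(0, 1, 3))
  expect_equal(as.numeric(a), 4 * pi * 3.1^2, tolerance = 0.005 * 4 * pi * 3.1^2)
  # two fully separated atoms: areas add
  two <- assign_radii(topology(tibble::tibble(
    name = c("C1", "C2"), element = "C", resname = c("AAA", "BBB"), resid = 1:2
  )))
  a2 <- sasa(two, rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(as.numeric(a2), 2 * 4 * pi * 3.1^2, tolerance = 0.01)
  # a tightly caged atom contributes ~ nothing
  centre_plus_cage <- tibble::tibble(
    name = paste0("C", 1:27), element = "C", resname = "LIG", resid = 1:27
  )
  grid <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1)) * 2.0
  cage <- assign_radii(topology(centre_plus_cage))
  acage <- sasa(cage, grid)
  per_atom <- attr(acage, "per_atom")
  centre_idx <- which(rowSums(grid^2) == 0)
  expect_lt(per_atom[[as.character(centre_idx)]], 1e-6)
  # convergence: doubling sphere points moves the answer < 0.5%
  set.seed(2)
  blob <- matrix(rnorm(30, sd = 2), 10, 3)
  blob_top <- assign_radii(topology(tibble::tibble(
    name = paste0("C", 1:10), element = "C", resname = "LIG", resid = 1:10
  )))
  s1 <- as.numeric(sasa(blob_top, blob, n_sphere_points = 960))
  s2 <- as.numeric(sasa(blob_top, blob, n_sphere_points = 1920))
  expect_lt(abs(s1 - s2) / s2, 0.005)
})

toy_complex <- function(n_frames = 3, gap = 6) {
  top <- assign_radii(topology(tibble::tibble(
    name = c("N1", "O1", "C1", "P1"), element = c("N", "O", "C", "P"),
    resname = c("AAA", "AAA", "LIG", "LIG"), resid = c(1, 1, 2, 2)
  )))
  co <- array(0, c(n_frames, 4, 3))
  for (i in seq_len(n_frames)) {
    co[i, , ] <- rbind(c(0, 0, 0), c(1.3, 0, 0), c(gap, 0, 0), c(gap + 1.6, 0, 0))
  }
  trajectory(top, co, dt = 10)
}

test_that("binding energy: non-interacting limit is zero and Coulomb cancels", {
  tr <- toy_complex(gap = 50)
  p0 <- energy_parameters(tr$topology, charge = 0, eps = 0, sigma = 3,
                          born_radius = 2)
  es <- binding_energy_series(tr, 1:2, 3:4, p0, interval = 10)
  expect_equal(es$total, rep(0, nrow(es)), tolerance = 1e-9)

  # the Coulomb component of dG is exactly the receptor-ligand interaction
  p <- energy_parameters(tr$topology, charge = c(0.4, -0.4, 0.3, -0.3),
                         eps = 0.1, sigma = 3, born_radius = 2)
  tr2 <- toy_complex(gap = 6)
  es2 <- binding_energy_series(tr2, 1:2, 3:4, p, interval = 10)
  inter <- mm_interaction_energy(frame_coords(tr2, 1), 1:2, 3:4, p)
  expect_equal(es2$E_coulomb[1], inter$E_coulomb, tolerance = 1e-10)
  expect_equal(es2$E_lj[1], inter$E_lj, tolerance = 1e-10)
  expect_equal(es2$total, es2$E_coulomb + es2$E_lj + es2$G_gb + es2$G_np)
})

test_that("binding energy is invariant under rigid motion of the complex", {
  tr <- toy_complex(n_frames = 1)
  p <- energy_parameters(tr$topology, charge = c(0.4, -0.4, 0.3, -0.3),
                         eps = 0.1, sigma = 3, born_radius = 2)
  g1 <- binding_energy_series(tr, 1:2, 3:4, p, interval = 10)$total
  R <- rotation_about_axis(c(1, 0, 1), 40)
  tr$coords[1, , ] <- sweep(tr$coords[1, , ] %*% t(R), 2, c(7, -2, 3), "+")
  g2 <- binding_energy_series(tr, 1:2, 3:4, p, interval = 10)$total
  # exact up to the SASA discretization error of the nonpolar term
  expect_equal(g1, g2, tolerance = 0.01)
})

test_that("desolvation penalty grows with the exterior dielectric for an ion pair", {
  tr <- toy_complex(n_frames = 1, gap = 4)
  mk <- function(eps_out) {
    p <- energy_parameters(tr$topology, charge = c(1, 0, -1, 0), eps = 0,
                           sigma = 3, born_radius = 2, eps_out = eps_out)
    binding_energy_series(tr, 1:2, 3:4, p, interval = 10)$G_gb
  }
  # stronger solvent screening (larger eps_out) penalises association more
  expect_gt(mk(78.5), mk(10))
  expect_gt(mk(10), mk(2))
})

test_that("snapshots snap to the nearest frame with a warning", {
  tr <- toy_complex(n_frames = 4)  # dt = 10 ns
  p <- energy_parameters(tr$topology, charge = 0, eps = 0, sigma = 3,
                         born_radius = 2)
  expect_warning(binding_energy_series(tr, 1:2, 3:4, p, interval = 13),
                 "nearest")
  es <- binding_energy_series(tr, 1:2, 3:4, p, interval = 10)
  expect_equal(es$time_ns, c(0, 10, 20, 30))
})
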