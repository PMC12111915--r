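# Kabsch superposition, RMSD, Rg, RMSF, distance series.

test_that("Kabsch superposition closed forms and chirality", {
  set.seed(1)
  pts <- matrix(rnorm(30), 10, 3)
  # identical sets: rmsd 0, identity rotation
  sp <- kabsch_superpose(pts, pts)
  expect_lt(sp$rmsd, 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-10)
  # translated set: rmsd 0 after fit, 5 before
  shifted <- sweep(pts, 2, c(3, 4, 0), "+")
  expect_equal(sqrt(mean(rowSums((shifted - pts)^2))), 5, tolerance = 1e-12)
  sp <- kabsch_superpose(shifted, pts)
  expect_lt(sp$rmsd, 1e-12)
  # mirror image: proper rotation enforced, rmsd > 0
  mirror <- pts %*% diag(c(-1, 1, 1))
  sp <- kabsch_superpose(mirror, pts)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  expect_gt(sp$rmsd, 0.1)
  # collinear points are rejected
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear|degenerate")
})

test_that("superposition agrees with an independent reference implementation", {
  set.seed(7)
  for (i in 1:5) {
    a <- matrix(rnorm(60), 20, 3)
    R <- rotation_about_axis(rnorm(3), runif(1, 10, 170))
    b <- sweep(a %*% t(R), 2, rnorm(3), "+") + matrix(rnorm(60, sd = 0.3), 20, 3)
    ours <- kabsch_superpose(b, a)$rmsd
    ref <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)), fit = TRUE)
    expect_equal(ours, ref, tolerance = 1e-3)
  }
})

test_that("RMSD series: static zero, rigid motion removed, translation kept", {
  tr <- gen_rigid_body_protein(30, n_frames = 5, per_residue_noise = 0, seed = 1)
  r <- compute_rmsd_series(tr, 1:30)
  expect_true(all(r$value < 1e-8))

  sched <- c(list(list()), lapply(1:4, function(i) {
    list(rotation = rotation_about_axis(c(0, 1, 0), 20 * i),
         translation = c(i, 0, -i))
  }))
  rigid <- gen_rigid_body_protein(30, sched, per_residue_noise = 0, seed = 1)
  sup <- compute_rmsd_series(rigid, 1:30, superpose = TRUE)
  expect_true(all(sup$value < 1e-8))

  trans <- gen_rigid_body_protein(
    30, c(list(list()), replicate(3, list(translation = c(3, 4, 0)),
                                  simplify = FALSE)),
    per_residue_noise = 0, seed = 1
  )
  raw <- compute_rmsd_series(trans, 1:30, superpose = FALSE)
  expect_equal(raw$value[-1], rep(5, 3), tolerance = 1e-12)
  expect_error(compute_rmsd_series(tr, 1:30, reference_frame = 99), "range")
})

test_that("Rg closed forms, homogeneity, and brute-force agreement", {
  two <- topology(tibble::tibble(name = c("X1", "X2"), element = "C",
                                 resname = "LIG", resid = 1:2, mass = 1))
  co <- array(0, c(1, 2, 3)); co[1, 2, 1] <- 2
  expect_equal(compute_rg_series(trajectory(two, co, dt = 1), 1:2)$value, 1)

  sq <- topology(tibble::tibble(name = paste0("X", 1:4), element = "C",
                                resname = "LIG", resid = 1:4, mass = 1))
  co <- array(0, c(1, 4, 3))
  co[1, , 1] <- c(0, 2, 0, 2); co[1, , 2] <- c(0, 0, 2, 2)
  tr <- trajectory(sq, co, dt = 1)
  expect_equal(compute_rg_series(tr, 1:4)$value, sqrt(2), tolerance = 1e-10)
  # homogeneity: scaling coordinates by s scales Rg by s
  co3 <- co * 3.5
  expect_equal(compute_rg_series(trajectory(sq, co3, dt = 1), 1:4)$value,
               3.5 * sqrt(2), tolerance = 1e-10)
  # brute force on a random 50-atom set, mass-weighted
  set.seed(11)
  top50 <- topology(tibble::tibble(
    name = paste0("X", 1:50), element = "C", resname = "LIG", resid = 1:50,
    mass = runif(50, 1, 30)
  ))
  co50 <- array(rnorm(150), c(1, 50, 3))
  ours <- compute_rg_series(trajectory(top50, co50, dt = 1), 1:50)$value
  expect_equal(ours, oracle_rg(co50[1, , ], top50$mass), tolerance = 1e-10)
})

test_that("Rg is invariant under rigid motion", {
  set.seed(3)
  top <- chain_topology(15)
  co <- array(rnorm(60 * 3), c(1, 60, 3))
  tr1 <- trajectory(top, co, dt = 1)
  R <- rotation_about_axis(c(1, 2, 3), 63)
  co2 <- co
  co2[1, , ] <- sweep(co[1, , ] %*% t(R), 2, c(5, -7, 2), "+")
  tr2 <- trajectory(top, co2, dt = 1)
  expect_equal(compute_rg_series(tr1, 1:60)$value,
               compute_rg_series(tr2, 1:60)$value, tolerance = 1e-10)
})

test_that("RMSF: static zero, alternating atom gives 1, rigid motion removed", {
  tr <- gen_rigid_body_protein(20, n_frames = 6, per_residue_noise = 0, seed = 1)
  r <- compute_rmsf(tr, 1:20)
  expect_true(all(r$rmsf < 1e-8))

  # one atom alternating between (0,0,0) and (2,0,0): RMSF 1. A rigid
  # triangle provides the alignment frame so the fit is well-posed.
  top <- topology(tibble::tibble(
    name = c("C1", "C2", "C3", "C4"), element = "C", resname = "LIG",
    resid = 1:4, mass = 1
  ))
  nf <- 10
  co <- array(0, c(nf, 4, 3))
  co[, 2, 1] <- 10; co[, 3, 2] <- 10  # static triangle with atom 1 at origin
  co[, 4, 1] <- rep(c(0, 2), 5); co[, 4, 2] <- 5; co[, 4, 3] <- 5
  tr <- trajectory(top, co, dt = 1)
  r <- compute_rmsf(tr, 1:4, align_sel = 1:3, by_residue = FALSE)
  expect_equal(r$rmsf[r$index == 4], 1, tolerance = 1e-10)
  expect_true(all(r$rmsf[r$index %in% 1:3] < 1e-10))

  # rigidly moving body after alignment
  sched <- lapply(0:5, function(i) list(
    rotation = rotation_about_axis(c(0, 0, 1), 11 * i),
    translation = c(i, i, 0)
  ))
  rigid <- gen_rigid_body_protein(20, sched, per_residue_noise = 0, seed = 2)
  expect_true(all(compute_rmsf(rigid, 1:20)$rmsf < 1e-8))
})

test_that("isotropic Gaussian noise gives RMSF near sqrt(3) sigma", {
  sigma <- 0.4
  tr <- gen_rigid_body_protein(40, n_frames = 600, per_residue_noise = sigma,
                               seed = 5)
  r <- compute_rmsf(tr, 1:40)
  expect_equal(mean(r$rmsf), sqrt(3) * sigma, tolerance = 0.05)
})

test_that("distance series closed forms", {
  top <- topology(tibble::tibble(
    name = c("C1", "C2", "C3"), element = "C", resname = c("AAA", "AAA", "BBB"),
    resid = c(1, 1, 2)
  ))
  co <- array(0, c(1, 3, 3))
  co[1, 2, ] <- c(10, 0, 0); co[1, 3, ] <- c(4, 0, 0)
  tr <- trajectory(top, co, dt = 1)
  expect_equal(distance_series(tr, 1:2, 3, mode = "min")$value, 4)
  co2 <- array(0, c(1, 2, 3)); co2[1, 2, ] <- c(3, 4, 0)
  tr2 <- trajectory(top[1:2, ] |> tibble::as_tibble() |>
                      dplyr::select(-index) |> topology(), co2, dt = 1)
  expect_equal(distance_series(tr2, 1, 2)$value, 5)
  # pbc: x=1 vs x=9 in box 10 -> 2
  co3 <- array(0, c(1, 2, 3)); co3[1, 1, 1] <- 1; co3[1, 2, 1] <- 9
  tr3 <- trajectory(tr2$topology, co3, dt = 1, box = c(10, 10, 10))
  expect_equal(distance_series(tr3, 1, 2, pbc = TRUE)$value, 2)
  expect_equal(distance_series(tr3, 1, 2, pbc = FALSE)$value, 8)
  expect_error(distance_series(tr3, integer(0), 2), "non-empty")
})

test_that("domain selections take backbone atoms of the named range", {
  top <- chain_topology(600)
  dm <- domain_map()
  ef <- domain_selection(top, dm, "EF-hands")
  expect_equal(sort(unique(top$resid[ef])), 35:145)
  expect_true(all(top$name[ef] %in% c("N", "CA", "C", "O")))
  expect_error(domain_selection(top, dm, "nope"), "unknown domain")
  expect_error(domain_map(a = c(1, 10), b = c(5, 20)), "overlap")
})
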