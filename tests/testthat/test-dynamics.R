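# MSD, diffusion fitting, RDF.

static_traj <- function(n_frames = 20) {
  top <- topology(tibble::tibble(name = "C1", element = "C", resname = "LIG",
                                 resid = 1))
  trajectory(top, array(rep(c(1, 2, 3), each = n_frames),
                        c(n_frames, 1, 3)), dt = 0.1)
}

test_that("MSD closed forms: static is zero, ballistic is tau squared", {
  m <- compute_msd(static_traj(), 1, track_mode = "atoms")
  expect_true(all(m$msd == 0))
  expect_equal(m$msd[1], 0)
  expect_true(all(diff(m$lag_ns) > 0))

  # ballistic motion at 1 A/ns along x
  nf <- 41
  top <- topology(tibble::tibble(name = "C1", element = "C", resname = "LIG",
                                 resid = 1))
  co <- array(0, c(nf, 1, 3))
  co[, 1, 1] <- (0:(nf - 1)) * 0.1  # dt = 0.1 ns, v = 1 A/ns
  tr <- trajectory(top, co, dt = 0.1)
  m <- compute_msd(tr, 1, track_mode = "atoms", max_lag = 2)
  expect_equal(m$msd, m$lag_ns^2, tolerance = 1e-12)
  # n_pairs non-increasing with lag (after lag 0)
  expect_true(all(diff(m$n_pairs[-1]) <= 0))
})

test_that("MSD is invariant under global translation of every frame", {
  tr <- gen_brownian(10, 0.2, 0.1, 100, seed = 5)
  m1 <- compute_msd(tr, 1:10, track_mode = "atoms", max_lag = 2)
  shifted <- tr
  for (k in 1:3) shifted$ucoords[, , k] <- shifted$ucoords[, , k] + 77
  m2 <- compute_msd(shifted, 1:10, track_mode = "atoms", max_lag = 2)
  expect_equal(m1$msd, m2$msd, tolerance = 1e-12)
})

test_that("superposed-mode MSD removes per-frame rigid motion", {
  # rigid body rotating and translating arbitrarily: after superposition on
  # itself the MSD of any atom is ~0
  sched <- lapply(0:19, function(i) {
    list(rotation = rotation_about_axis(c(1, 1, 0), 7 * i),
         translation = c(0.5 * i, -0.2 * i, 0.1 * i))
  })
  tr <- gen_rigid_body_protein(30, sched, per_residue_noise = 0, seed = 2)
  m <- compute_msd(tr, 1:5, align_sel = 1:30, track_mode = "atoms",
                   max_lag = 0.5)
  expect_lt(max(m$msd), 1e-16)
})

test_that("diffusion fitting is exact on synthetic lines", {
  lags <- seq(0, 10, by = 0.1)
  for (case in list(list(slope = 0.6, d = 3), list(slope = 0.4, d = 2),
                    list(slope = 0.2, d = 1))) {
    prof <- tibble::tibble(lag_ns = lags, msd = case$slope * lags)
    fit <- fit_diffusion(prof, d = case$d)
    expect_equal(fit$D, 0.1, tolerance = 1e-12)
    expect_equal(fit$fit_intercept, 0, tolerance = 1e-10)
  }
  expect_error(fit_diffusion(tibble::tibble(lag_ns = c(0, 10), msd = c(0, 1)),
                             fit_range = c(0.1, 0.2)), "degenerate")
  t1 <- tidy(fit_diffusion(tibble::tibble(lag_ns = lags, msd = 0.6 * lags)))
  expect_equal(t1$D, 0.1, tolerance = 1e-12)
  expect_false(t1$negative_fit)
})

test_that("Brownian diffusion is recovered from the MSD slope", {
  tr <- gen_brownian(60, 0.1, 0.1, 2000, seed = 13)
  m <- compute_msd(tr, 1:60, track_mode = "atoms", max_lag = 10,
                   origin_stride = 10)
  fit <- fit_diffusion(m)
  expect_equal(fit$D, 0.1, tolerance = 0.05)
})

test_that("MSD guards: bad lags and wrapped-only coordinates error", {
  tr <- gen_brownian(2, 0.1, 0.1, 50, seed = 1)
  expect_error(compute_msd(tr, 1:2, max_lag = 10), "max_lag")
  wrapped_only <- tr
  wrapped_only$ucoords <- NULL
  expect_error(compute_msd(wrapped_only, 1:2, max_lag = 1), "unwrapped")
  expect_error(compute_msd(tr, integer(0)), "empty")
})

test_that("RDF of an ideal gas is flat at 1 with exact count conservation", {
  tr <- gen_ideal_gas(0.01, c(24, 24, 24), 6, seed = 3)
  all_sel <- seq_len(n_atoms(tr))
  rdf <- compute_rdf(tr, all_sel[1:20], all_sel, r_max = 11, dr = 0.5)
  expect_true(all(rdf$g >= 0))
  expect_equal(mean(rdf$g[rdf$r > 5]), 1, tolerance = 0.05)
  # pair-count conservation against brute force, exact integer equality
  brute <- 0L
  for (i in 1:n_frames(tr)) {
    fr <- frame_coords(tr, i)
    for (c_ in 1:20) {
      d <- sqrt(rowSums(min_image_displacement(
        fr, matrix(fr[c_, ], nrow(fr), 3, byrow = TRUE), tr$box)^2))
      brute <- brute + sum(d < 11) - 1L  # excluding the self pair
    }
  }
  expect_identical(sum(rdf$counts), as.numeric(brute))
})

test_that("hydration-shell RDF peaks at the shell radius with the right count", {
  tr <- gen_hydration_shell(list(c(2.4, 6)), jitter = 0.05, n_frames = 25,
                            seed = 4)
  ion <- select_atoms(tr$topology, "ion")
  wat <- select_atoms(tr$topology, "water and element O")
  rdf <- compute_rdf(tr, ion, wat, r_max = 8, dr = 0.1)
  expect_lt(abs(rdf$r[which.max(rdf$g)] - 2.4), 0.1 + 1e-9)
  expect_equal(shell_count(rdf, 3.5), 6, tolerance = 0.1)
})

test_that("RDF input guards fire", {
  tr <- gen_ideal_gas(0.01, c(20, 20, 20), 2, seed = 1)
  sel <- seq_len(n_atoms(tr))
  expect_error(compute_rdf(tr, sel[1], sel, r_max = 15), "half")
  expect_error(compute_rdf(tr, integer(0), sel, r_max = 8), "empty")
  expect_error(compute_rdf(tr, sel[1], integer(0), r_max = 8), "empty")
  nobox <- gen_ou_tethered(1, 1, dt = 0.1, n_frames = 5, seed = 1)
  expect_error(compute_rdf(nobox, 1, 1, r_max = 3), "box")
})
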