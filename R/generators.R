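# Seeded synthetic-trajectory generators with known ground truth.
#
# Every generator is a pure function of its arguments including the seed.
# Each generator family draws from its own stream derived from the master
# seed, so adding or re-running one generator never perturbs another's
# output. Unwrapped coordinates are stored alongside wrapped ones where
# displacements matter.

stream_offsets <- c(
  brownian = 0L, ou = 1L, gas = 2L, hbond = 3L, shell = 4L,
  rigid = 5L, groups = 6L
)

derive_seed <- function(seed, stream) {
  seed <- as.integer(seed)
  (seed %% 268435456L) * 8L + stream_offsets[[stream]]  # stays < 2^31
}

#' Brownian particles in a periodic box
#'
#' Free isotropic Brownian motion: per-axis step increments are independent
#' normals with mean 0 and variance `2 * D * dt`, so the ensemble MSD grows
#' as `6 * D * t` in three dimensions. Positions are wrapped into the box;
#' unwrapped coordinates are retained for displacement analysis.
#'
#' @param n_particles Number of particles (modelled as water oxygens).
#' @param D Diffusion coefficient, angstrom^2/ns.
#' @param dt Frame spacing, ns.
#' @param n_frames Number of frames.
#' @param box Orthorhombic edge lengths, angstrom.
#' @param seed Integer master seed.
#' @return A [trajectory()] with wrapped and unwrapped coordinates.
#' @export
gen_brownian <- function(n_particles, D, dt, n_frames, box = c(50, 50, 50),
                         seed = 1L) {
  stopifnot(D >= 0, n_particles >= 1, n_frames >= 1)
  set.seed(derive_seed(seed, "brownian"))
  box <- as.numeric(box)
  x0 <- cbind(runif(n_particles, 0, box[1]), runif(n_particles, 0, box[2]),
              runif(n_particles, 0, box[3]))
  u <- array(0, c(n_frames, n_particles, 3L))
  u[1L, , ] <- x0
  if (n_frames > 1L) {
    sdstep <- sqrt(2 * D * dt)
    for (k in 1:3) {
      inc <- matrix(rnorm((n_frames - 1L) * n_particles, sd = sdstep),
                    n_frames - 1L, n_particles)
      walks <- apply(inc, 2L, cumsum)
      if (is.null(dim(walks))) walks <- matrix(walks, nrow = 1L)
      u[, , k] <- rbind(x0[, k], sweep(walks, 2L, x0[, k], "+"))
    }
  }
  w <- u
  for (k in 1:3) w[, , k] <- u[, , k] - box[k] * floor(u[, , k] / box[k])
  top <- topology(tibble(
    name = "OH2", element = "O", resname = "WAT",
    resid = seq_len(n_particles), chain = "W"
  ))
  trajectory(top, w, dt = dt, box = box, ucoords = u)
}

#' Tethered ligand with Ornstein-Uhlenbeck dynamics
#'
#' A bound ligand modelled as particles tethered to a centre with
#' stationary per-axis standard deviation `sigma` and relaxation time
#' `tau_relax`, using the exact OU update
#' `x' = c + (x - c) * rho + sigma * sqrt(1 - rho^2) * xi`,
#' `rho = exp(-dt / tau_relax)`. The ensemble MSD plateaus at
#' `6 * sigma^2` at long lags.
#'
#' @param sigma Stationary per-axis standard deviation, angstrom.
#' @param tau_relax Relaxation time, ns.
#' @param center Tether point, length-3.
#' @param dt,n_frames,seed As in [gen_brownian()].
#' @param n_particles Number of independent tethered particles.
#' @return A [trajectory()] (no box; coordinates are their own unwrapped set).
#' @export
gen_ou_tethered <- function(sigma, tau_relax, center = c(0, 0, 0), dt, n_frames,
                            seed = 1L, n_particles = 1L) {
  stopifnot(sigma >= 0, tau_relax > 0)
  set.seed(derive_seed(seed, "ou"))
  rho <- exp(-dt / tau_relax)
  innov_sd <- sigma * sqrt(1 - rho^2)
  x <- array(0, c(n_frames, n_particles, 3L))
  x[1L, , ] <- rnorm(n_particles * 3L, sd = sigma)
  if (n_frames > 1L) {
    for (t in 2:n_frames) {
      x[t, , ] <- x[t - 1L, , ] * rho +
        rnorm(n_particles * 3L, sd = innov_sd)
    }
  }
  for (k in 1:3) x[, , k] <- x[, , k] + center[k]
  top <- topology(tibble(
    name = "C1", element = "C", resname = "LIG",
    resid = seq_len(n_particles), chain = "L"
  ))
  trajectory(top, x, dt = dt, box = NULL)
}

#' Homogeneous ideal-gas water frames
#'
#' Each frame is an independent uniform draw of `floor(density * V)` water
#' oxygens in the box: the null model whose radial distribution function is
#' identically 1.
#'
#' @param density Number density, angstrom^-3 (bulk water is about 0.0334).
#' @param box Orthorhombic edge lengths.
#' @param n_frames,seed As in [gen_brownian()].
#' @return A [trajectory()] with `dt = 1` ns nominal spacing.
#' @export
gen_ideal_gas <- function(density, box, n_frames, seed = 1L) {
  box <- as.numeric(box)
  n <- floor(density * prod(box))
  stopifnot(n >= 1)
  set.seed(derive_seed(seed, "gas"))
  x <- array(0, c(n_frames, n, 3L))
  for (k in 1:3) x[, , k] <- matrix(runif(n_frames * n, 0, box[k]), n_frames, n)
  top <- topology(tibble(
    name = "OH2", element = "O", resname = "WAT", resid = seq_len(n),
    chain = "W"
  ))
  trajectory(top, x, dt = 1, box = box)
}

#' Exact hydrogen-bond geometry scene
#'
#' Places a donor nitrogen, its hydrogen and an acceptor oxygen so that the
#' donor-acceptor distance and the D-H...A angle (at the hydrogen) equal the
#' requested values exactly. Donor and acceptor sit in different residues
#' (a lysine NZ/HZ1 and a serine OG by default), so the scene exercises both
#' inter- and intramolecular detectors.
#'
#' @param d_DA Donor-acceptor distance, angstrom.
#' @param theta_DHA D-H...A angle at the hydrogen, degrees (180 = linear).
#' @param donor_resid,acceptor_resid Residue ids of the two residues.
#' @return List with `topology` and `coords` (3 x 3 matrix).
#' @export
gen_hbond_scene <- function(d_DA, theta_DHA, donor_resid = 40L,
                            acceptor_resid = 44L) {
  stopifnot(d_DA > 0, theta_DHA >= 0, theta_DHA <= 180)
  bond <- 1.0  # N-H bond length
  th <- theta_DHA * pi / 180
  # D at origin, H on +x; A in the xy-plane at angle th from H->D.
  disc <- cos(th)^2 - 1 + (d_DA / bond)^2
  if (disc < 0) abort("no geometry: d_DA too short for the requested angle")
  r_HA <- bond * (cos(th) + sqrt(disc))
  a_pos <- c(bond - r_HA * cos(th), r_HA * sin(th), 0)
  coords <- rbind(c(0, 0, 0), c(bond, 0, 0), a_pos)
  top <- topology(tibble(
    name = c("NZ", "HZ1", "OG"),
    element = c("N", "H", "O"),
    resname = c("LYS", "LYS", "SER"),
    resid = c(donor_resid, donor_resid, acceptor_resid),
    chain = "A"
  ))
  list(topology = top, coords = coords)
}

#' Ion with discrete hydration shells
#'
#' One central calcium ion at the box centre surrounded by concentric
#' shells of water oxygens: each shell's waters are placed at its radius
#' (plus radial Gaussian jitter) in fresh random directions every frame.
#' Shell membership counts are conserved across frames.
#'
#' @param shells List of `c(radius, count)` pairs (or a 2-column matrix).
#' @param jitter Radial standard deviation, angstrom.
#' @param n_frames,seed As in [gen_brownian()].
#' @param box Orthorhombic box; radii must fit inside the half-box.
#' @param dt Frame spacing, ns.
#' @return A [trajectory()].
#' @export
gen_hydration_shell <- function(shells, jitter = 0, n_frames = 1L, seed = 1L,
                                box = c(30, 30, 30), dt = 1) {
  if (is.list(shells)) shells <- do.call(rbind, shells)
  shells <- matrix(as.numeric(shells), ncol = 2L)
  stopifnot(all(shells[, 1L] > 0), all(shells[, 2L] >= 1), jitter >= 0)
  box <- as.numeric(box)
  if (max(shells[, 1L]) + 4 * jitter >= min(box) / 2) {
    abort("shell radii must fit within the half-box")
  }
  set.seed(derive_seed(seed, "shell"))
  counts <- as.integer(shells[, 2L])
  n_wat <- sum(counts)
  radii0 <- rep(shells[, 1L], counts)
  centre <- box / 2
  x <- array(0, c(n_frames, n_wat + 1L, 3L))
  for (t in seq_len(n_frames)) {
    x[t, 1L, ] <- centre
    dir <- matrix(rnorm(n_wat * 3L), n_wat, 3L)
    dir <- dir / sqrt(rowSums(dir^2))
    r <- radii0 + if (jitter > 0) rnorm(n_wat, sd = jitter) else 0
    x[t, -1L, ] <- sweep(dir * r, 2L, centre, "+")
  }
  top <- topology(tibble(
    name = c("CA", rep("OH2", n_wat)),
    element = c("CA", rep("O", n_wat)),
    resname = c("CA", rep("WAT", n_wat)),
    resid = seq_len(n_wat + 1L),
    chain = c("I", rep("W", n_wat))
  ))
  trajectory(top, x, dt = dt, box = box)
}

#' Rotation matrix about an axis
#'
#' @param axis Length-3 axis (normalised internally).
#' @param angle_deg Rotation angle, degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
}

#' Rigid-body protein trajectory with per-residue noise
#'
#' A C-alpha-only helical chain subjected to a prescribed rigid transform
#' per frame (rotation about the chain centroid, then translation) plus
#' isotropic Gaussian noise per residue. With identity transforms and noise
#' `sigma`, the per-residue RMSF converges to `sqrt(3) * sigma`.
#'
#' @param n_residues Chain length.
#' @param displacement_schedule List with one element per frame, each a list
#'   with `rotation` (3x3 matrix, default identity) and `translation`
#'   (length-3, default zero); `NULL` plus `n_frames` gives all-identity.
#' @param per_residue_noise Isotropic noise standard deviation per axis,
#'   angstrom.
#' @param seed Integer master seed.
#' @param n_frames Used only when `displacement_schedule` is `NULL`.
#' @param dt Frame spacing, ns.
#' @return A [trajectory()].
#' @export
gen_rigid_body_protein <- function(n_residues, displacement_schedule = NULL,
                                   per_residue_noise = 0, seed = 1L,
                                   n_frames = NULL, dt = 0.1) {
  if (is.null(displacement_schedule)) {
    stopifnot(!is.null(n_frames))
    displacement_schedule <- replicate(n_frames, list(), simplify = FALSE)
  }
  nf <- length(displacement_schedule)
  i <- seq_len(n_residues)
  # idealized alpha-helix C-alpha trace: 2.3 A radius, 1.5 A rise, 100 deg turn
  base <- cbind(2.3 * cos(i * 100 * pi / 180), 2.3 * sin(i * 100 * pi / 180),
                1.5 * i)
  cen <- colMeans(base)
  set.seed(derive_seed(seed, "rigid"))
  x <- array(0, c(nf, n_residues, 3L))
  for (t in seq_len(nf)) {
    tr <- displacement_schedule[[t]]
    R <- tr$rotation %||% diag(3)
    tv <- tr$translation %||% c(0, 0, 0)
    pos <- sweep(base, 2L, cen, "-") %*% t(R)
    pos <- sweep(pos, 2L, cen + tv, "+")
    if (per_residue_noise > 0) {
      pos <- pos + matrix(rnorm(n_residues * 3L, sd = per_residue_noise),
                          n_residues, 3L)
    }
    x[t, , ] <- pos
  }
  top <- topology(tibble(
    name = "CA", element = "C", resname = "ALA", resid = i, chain = "A"
  ))
  trajectory(top, x, dt = dt, box = NULL)
}

#' Two-or-more-condition sample sets for hypothesis testing
#'
#' Draws `n_per_group` observations per group from normal (or lognormal)
#' distributions with the given per-group means and standard deviations
#' (meanlog/sdlog for the lognormal family), in tidy long format.
#'
#' @param group_means,group_sds Numeric vectors, one entry per group.
#' @param n_per_group Observations per group.
#' @param family `"normal"` or `"lognormal"`.
#' @param seed Integer master seed.
#' @return Tibble with columns `group` (factor) and `value`.
#' @export
gen_group_samples <- function(group_means, group_sds, n_per_group,
                              family = c("normal", "lognormal"), seed = 1L) {
  family <- match.arg(family)
  k <- length(group_means)
  stopifnot(length(group_sds) == k, all(group_sds >= 0))
  set.seed(derive_seed(seed, "groups"))
  nm <- names(group_means) %||% paste0("g", seq_len(k))
  out <- lapply(seq_len(k), function(g) {
    z <- rnorm(n_per_group, group_means[g], group_sds[g])
    tibble(group = nm[g], value = if (family == "lognormal") exp(z) else z)
  })
  out <- bind_rows(out)
  out$group <- factor(out$group, levels = nm)
  out
}
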