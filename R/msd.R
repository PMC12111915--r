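# Mean-squared displacement and diffusion-coefficient estimation.

#' Mean-squared displacement profile
#'
#' MSD(tau) averaged over tracked particles and multiple time origins:
#' `MSD(tau) = < |r(t + tau) - r(t)|^2 >`. Displacements are taken on
#' unwrapped coordinates (or, with `align_sel`, on coordinates superposed
#' frame-by-frame onto the first frame so that global rigid motion is
#' removed and the MSD reflects motion within the binding site).
#'
#' @param traj A [trajectory()].
#' @param particle_sel Selection of tracked atoms (see [select_atoms()]), or
#'   integer indices.
#' @param align_sel Optional selection (3+ atoms) used to superpose every
#'   frame onto frame 1 before measuring displacements.
#' @param max_lag Largest lag in ns; default half the trajectory length.
#' @param origin_stride Use every `origin_stride`-th frame as a time origin.
#' @param track_mode `"com"` tracks the mass-weighted centre of mass of the
#'   whole selection; `"atoms"` tracks each selected atom.
#' @param n_blocks Contiguous origin blocks for the block-averaged SEM.
#' @return Tibble of class `"msd_profile"` with columns `lag_ns`, `msd`
#'   (angstrom^2), `n_pairs`, `sem`.
#' @export
compute_msd <- function(traj, particle_sel, align_sel = NULL, max_lag = NULL,
                        origin_stride = 1L, track_mode = c("com", "atoms"),
                        n_blocks = 5L) {
  track_mode <- match.arg(track_mode)
  idx <- as.integer(particle_sel)
  if (length(idx) == 0L) abort("particle selection is empty")
  nf <- n_frames(traj)
  max_lag <- max_lag %||% ((nf - 1L) * traj$dt / 2)
  lag_max_frames <- as.integer(round(max_lag / traj$dt))
  if (lag_max_frames >= nf) {
    abort(sprintf("max_lag (%g ns) must be below the trajectory length (%g ns)",
                  max_lag, (nf - 1L) * traj$dt))
  }
  if (lag_max_frames < 1L) abort("max_lag must cover at least one frame")

  if (!is.null(align_sel)) {
    co <- aligned_coords(traj, align_sel)[, idx, , drop = FALSE]
  } else if (!is.null(traj$ucoords)) {
    co <- traj$ucoords[, idx, , drop = FALSE]
  } else if (is.null(traj$box)) {
    co <- traj$coords[, idx, , drop = FALSE]
  } else {
    abort(paste0(
      "trajectory has only wrapped periodic coordinates; displacements need ",
      "unwrapped coordinates (or an align_sel for bounded motion)"
    ))
  }

  if (track_mode == "com") {
    m <- traj$topology$mass[idx]
    X <- matrix(0, nf, 3L)
    for (k in 1:3) {
      mat <- matrix(co[, , k], nf, length(idx))
      X[, k] <- as.numeric(mat %*% m) / sum(m)
    }
    P <- 1L
  } else {
    P <- length(idx)
    X <- matrix(0, nf, 3L * P)
    for (k in 1:3) X[, seq(k, 3L * P, by = 3L)] <- matrix(co[, , k], nf, P)
  }

  lags <- 0:lag_max_frames
  msd <- numeric(length(lags))
  sem <- numeric(length(lags))
  npair <- numeric(length(lags))
  for (j in seq_along(lags)) {
    lag <- lags[j]
    if (lag == 0L) { npair[j] <- length(seq(1L, nf, by = origin_stride)) * P; next }
    origins <- seq(1L, nf - lag, by = origin_stride)
    disp <- X[origins + lag, , drop = FALSE] - X[origins, , drop = FALSE]
    per_origin <- rowSums(disp * disp) / P
    msd[j] <- mean(per_origin)
    npair[j] <- length(origins) * P
    nb <- min(n_blocks, length(origins))
    if (nb >= 2L) {
      blocks <- cut(seq_along(origins), nb, labels = FALSE)
      bm <- vapply(split(per_origin, blocks), mean, numeric(1))
      sem[j] <- sd(bm) / sqrt(nb)
    } else {
      sem[j] <- NA_real_
    }
  }
  out <- tibble(lag_ns = lags * traj$dt, msd = msd, n_pairs = npair, sem = sem)
  class(out) <- c("msd_profile", class(out))
  attr(out, "meta") <- list(
    dt = traj$dt, track_mode = track_mode, origin_stride = origin_stride,
    aligned = !is.null(align_sel), n_blocks = n_blocks,
    n_particles = length(idx)
  )
  out
}

# Superpose every frame onto frame 1 using align_sel; returns the full
# coordinate array with each frame rigidly transformed.
aligned_coords <- function(traj, align_sel) {
  aidx <- as.integer(align_sel)
  if (length(aidx) < 3L) abort("align_sel needs at least 3 atoms")
  ref <- frame_coords(traj, 1L)[aidx, , drop = FALSE]
  w <- traj$topology$mass[aidx]
  out <- traj$coords
  for (i in seq_len(n_frames(traj))) {
    fr <- frame_coords(traj, i)
    sp <- kabsch_superpose(fr[aidx, , drop = FALSE], ref, weights = w)
    out[i, , ] <- apply_superposition(fr, sp)
  }
  out
}

#' Diffusion coefficient from an MSD profile
#'
#' Ordinary least squares on `(lag, msd)` within a fit window given as a
#' fraction of the maximum lag; `D = slope / (2 d)` with `d` the
#' dimensionality. The default 10-50% window avoids the short-lag ballistic
#' and long-lag noise-dominated regimes.
#'
#' @param msd An `"msd_profile"` tibble from [compute_msd()], or any data
#'   frame with `lag_ns` and `msd` columns.
#' @param fit_range Length-2 fractions of the maximum lag, default
#'   `c(0.1, 0.5)`.
#' @param d Dimensionality (1-3), default 3.
#' @return Object of class `"diffusion_fit"`; see [tidy.diffusion_fit()].
#' @export
fit_diffusion <- function(msd, fit_range = c(0.1, 0.5), d = 3L) {
  stopifnot(d %in% 1:3, length(fit_range) == 2L, fit_range[1] < fit_range[2])
  lmax <- max(msd$lag_ns)
  win <- msd$lag_ns >= fit_range[1] * lmax & msd$lag_ns <= fit_range[2] * lmax
  if (sum(win) < 2L) abort("degenerate fit window: fewer than 2 lag points")
  fit <- lm(msd ~ lag_ns, data = msd[win, ])
  slope <- unname(coef(fit)[2L])
  Dhat <- slope / (2 * d)
  sst <- sum((msd$msd[win] - mean(msd$msd[win]))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  structure(
    list(
      D = max(Dhat, 0), fit_slope = slope,
      fit_intercept = unname(coef(fit)[1L]),
      fit_range_ns = range(msd$lag_ns[win]), d = d,
      n_points = sum(win), negative_fit = Dhat < 0,
      r_squared = r2
    ),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "# diffusion fit: D = %.6g A^2/ns (slope %.6g over [%.4g, %.4g] ns, d = %d)%s\n",
    x$D, x$fit_slope, x$fit_range_ns[1], x$fit_range_ns[2], x$d,
    if (x$negative_fit) " [negative fit, clamped to 0]" else ""
  ))
  invisible(x)
}
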