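# Superposition and structural metrics: RMSD, radius of gyration, RMSF,
# named-pair distance series.

new_time_series <- function(times, values, label = "", units = "") {
  out <- tibble(time_ns = times, value = values)
  class(out) <- c("time_series", class(out))
  attr(out, "label") <- label
  attr(out, "units") <- units
  out
}

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation mapping `mobile` onto
#' `reference`, minimising the (optionally weighted) RMSD. Reflections are
#' never returned: the rotation determinant is +1.
#'
#' @param mobile,reference `n x 3` coordinate matrices, equal `n >= 3`,
#'   non-collinear.
#' @param weights Optional per-point weights (e.g. masses).
#' @return List of class `"superposition"` with `rotation` (3x3),
#'   `translation` (length 3) and `rmsd` (angstrom); the fitted coordinates
#'   are `coords %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3L || nrow(reference) != n) {
    abort("superposition needs two equal coordinate sets of >= 3 points")
  }
  w <- weights %||% rep(1, n)
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)
  C <- crossprod(P * w, Q)
  sv <- svd(C)
  # collinearity: the point cloud must span at least a plane
  spreadP <- svd(P * sqrt(w))$d
  if (spreadP[2L] < 1e-8 * max(spreadP[1L], 1e-12)) {
    abort("degenerate input: points are collinear, the rotation is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  structure(
    list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd),
    class = "superposition"
  )
}

#' Apply a superposition to coordinates
#'
#' @param coords `n x 3` matrix.
#' @param sp A `"superposition"` from [kabsch_superpose()].
#' @return Transformed `n x 3` matrix.
#' @export
apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2L, sp$translation, "+")
}

#' RMSD time series against a reference frame
#'
#' Per-frame root-mean-square deviation of the selected atoms from their
#' positions in the reference frame, after optional least-squares
#' superposition on the same selection.
#'
#' @param traj A [trajectory()].
#' @param sel Selection of atoms (backbone atoms for per-domain use).
#' @param reference_frame Frame index of the reference, default 1.
#' @param superpose Superpose each frame onto the reference first?
#' @return A `"time_series"` tibble (`time_ns`, `value` in angstrom).
#' @export
compute_rmsd_series <- function(traj, sel, reference_frame = 1L,
                                superpose = TRUE) {
  idx <- as.integer(sel)
  if (length(idx) == 0L) abort("selection is empty")
  nf <- n_frames(traj)
  if (reference_frame < 1L || reference_frame > nf) {
    abort(sprintf("reference frame %d out of range 1..%d", reference_frame, nf))
  }
  ref <- frame_coords(traj, reference_frame)[idx, , drop = FALSE]
  vals <- vapply(seq_len(nf), function(i) {
    fr <- frame_coords(traj, i)[idx, , drop = FALSE]
    if (superpose) {
      kabsch_superpose(fr, ref)$rmsd
    } else {
      sqrt(mean(rowSums((fr - ref)^2)))
    }
  }, numeric(1))
  new_time_series(traj$times, vals, label = "RMSD", units = "A")
}

#' Radius-of-gyration time series
#'
#' `Rg = sqrt( sum_i w_i |r_i - r_cm|^2 / sum_i w_i )`, a measure of the
#' compactness of the selection.
#'
#' @inheritParams compute_rmsd_series
#' @param mass_weighted Use atomic masses as weights (default); otherwise
#'   unit weights.
#' @return A `"time_series"` tibble in angstrom.
#' @export
compute_rg_series <- function(traj, sel, mass_weighted = TRUE) {
  idx <- as.integer(sel)
  if (length(idx) == 0L) abort("selection is empty")
  w <- if (mass_weighted) traj$topology$mass[idx] else rep(1, length(idx))
  w <- w / sum(w)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    fr <- frame_coords(traj, i)[idx, , drop = FALSE]
    cm <- colSums(fr * w)
    sqrt(sum(w * rowSums(sweep(fr, 2L, cm)^2)))
  }, numeric(1))
  new_time_series(traj$times, vals, label = "Rg", units = "A")
}

#' Per-residue root-mean-square fluctuation
#'
#' Fluctuation of each atom about its time-averaged position after
#' removing global motion: all frames are superposed onto the mean
#' structure using a two-pass fit (align to frame 1, take the mean, re-fit
#' to that mean, take the mean again), then
#' `RMSF_i = sqrt( < |r_i - <r_i>|^2 > )`. Residue values are the
#' mass-weighted mean of their atoms' RMSF.
#'
#' @param traj A [trajectory()] with at least 2 frames.
#' @param sel Atoms to report on.
#' @param align_sel Atoms used for the superposition; defaults to `sel`.
#' @param by_residue Aggregate per residue (default) or report per atom.
#' @param two_pass Use the two-pass mean-structure fit (default); single
#'   pass aligns to frame 1 only, for parity with simpler tools.
#' @return Tibble of class `"rmsf_profile"`: `resid`, `rmsf` (or `index`,
#'   `rmsf` when `by_residue = FALSE`).
#' @export
compute_rmsf <- function(traj, sel, align_sel = NULL, by_residue = TRUE,
                         two_pass = TRUE) {
  idx <- as.integer(sel)
  if (length(idx) == 0L) abort("selection is empty")
  if (n_frames(traj) < 2L) abort("RMSF needs at least 2 frames")
  aidx <- if (is.null(align_sel)) idx else as.integer(align_sel)
  nf <- n_frames(traj)
  w <- traj$topology$mass[aidx]

  fit_all <- function(ref_align) {
    arr <- array(0, c(nf, length(idx), 3L))
    for (i in seq_len(nf)) {
      fr <- frame_coords(traj, i)
      sp <- kabsch_superpose(fr[aidx, , drop = FALSE], ref_align, weights = w)
      arr[i, , ] <- apply_superposition(fr[idx, , drop = FALSE], sp)
    }
    arr
  }
  mean_of <- function(arr, cols) {
    m <- matrix(0, length(cols), 3L)
    for (k in 1:3) m[, k] <- colMeans(matrix(arr[, cols, k], nf))
    m
  }

  al2idx <- match(aidx, idx)
  arr <- fit_all(frame_coords(traj, 1L)[aidx, , drop = FALSE])
  if (two_pass) {
    if (anyNA(al2idx)) {
      # alignment atoms are not a subset of sel: fit their mean separately
      arrA <- fit_all_generic(traj, aidx, aidx, w)
      refA <- apply(arrA, c(2, 3), mean)
      arr <- fit_all(refA)
    } else {
      refA <- mean_of(arr, al2idx)
      arr <- fit_all(refA)
    }
  }
  mean_pos <- apply(arr, c(2, 3), mean)
  dev2 <- 0
  for (k in 1:3) {
    dev2 <- dev2 + sweep(matrix(arr[, , k], nf), 2L, mean_pos[, k])^2
  }
  rmsf_atom <- sqrt(colMeans(dev2))
  if (!by_residue) {
    out <- tibble(index = idx, rmsf = rmsf_atom)
  } else {
    top <- traj$topology[idx, ]
    out <- tibble(resid = top$resid, chain = top$chain, mass = top$mass,
                  rmsf = rmsf_atom) |>
      group_by(.data$chain, .data$resid) |>
      summarise(rmsf = weighted.mean(.data$rmsf, .data$mass),
                .groups = "drop") |>
      select("resid", "rmsf", "chain")
  }
  class(out) <- c("rmsf_profile", class(out))
  out
}

# align-and-extract used when align atoms are not a subset of sel
fit_all_generic <- function(traj, out_idx, align_idx, w) {
  nf <- n_frames(traj)
  ref <- frame_coords(traj, 1L)[align_idx, , drop = FALSE]
  arr <- array(0, c(nf, length(out_idx), 3L))
  for (i in seq_len(nf)) {
    fr <- frame_coords(traj, i)
    sp <- kabsch_superpose(fr[align_idx, , drop = FALSE], ref, weights = w)
    arr[i, , ] <- apply_superposition(fr[out_idx, , drop = FALSE], sp)
  }
  arr
}

#' Distance time series between two selections
#'
#' Per-frame minimum heavy-atom distance (`mode = "min"`, the default used
#' for residue-to-phosphate-oxygen traces) or mass-weighted
#' centre-of-mass distance (`mode = "com"`), under the minimum-image
#' convention when `pbc` and a box are present.
#'
#' @param traj A [trajectory()].
#' @param selA,selB Non-empty selections.
#' @param mode `"min"` or `"com"`.
#' @param pbc Use minimum-image distances when a box is present?
#' @return A `"time_series"` tibble in angstrom.
#' @export
distance_series <- function(traj, selA, selB, mode = c("min", "com"),
                            pbc = TRUE) {
  mode <- match.arg(mode)
  ia <- as.integer(selA); ib <- as.integer(selB)
  if (length(ia) == 0L || length(ib) == 0L) abort("both selections must be non-empty")
  box <- if (pbc) traj$box else NULL
  top <- traj$topology
  if (mode == "min") {
    ia <- ia[!top$is_hydrogen[ia]]
    ib <- ib[!top$is_hydrogen[ib]]
    if (length(ia) == 0L || length(ib) == 0L) {
      abort("no heavy atoms left in a selection for mode = \"min\"")
    }
  }
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    fr <- frame_coords(traj, i)
    if (mode == "min") {
      min(pair_distances(fr[ia, , drop = FALSE], fr[ib, , drop = FALSE], box))
    } else {
      wa <- top$mass[ia] / sum(top$mass[ia])
      wb <- top$mass[ib] / sum(top$mass[ib])
      min_image_distance(colSums(fr[ia, , drop = FALSE] * wa),
                         colSums(fr[ib, , drop = FALSE] * wb), box)
    }
  }, numeric(1))
  new_time_series(traj$times, vals, label = "distance", units = "A")
}

#' Backbone selection for one named domain
#'
#' @param top A [topology()].
#' @param dm A [domain_map()].
#' @param domain Domain name in `dm`.
#' @param backbone Restrict to backbone atoms (N, CA, C, O), the default
#'   for per-domain metrics.
#' @return A selection.
#' @export
domain_selection <- function(top, dm, domain, backbone = TRUE) {
  row <- dm[dm$domain == domain, ]
  if (nrow(row) != 1L) abort(paste0("unknown domain: ", domain))
  expr <- sprintf("resid %d to %d", row$from, row$to)
  if (backbone) expr <- paste0(expr, " and backbone")
  select_atoms(top, expr, label = domain)
}
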