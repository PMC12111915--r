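# Radial distribution function of a target species around centres.

#' Radial distribution function g(r)
#'
#' Histogram of minimum-image centre-target distances, normalised per bin by
#' the ideal-gas expectation `rho_ref * shell volume` with
#' `rho_ref = N_target / V`, averaged over frames and centres. For a
#' homogeneous fluid g(r) is 1 at all r.
#'
#' @param traj A [trajectory()] with a box (the normalisation needs a
#'   reference density).
#' @param center_sel,target_sel Selections (e.g. the ion and the water
#'   oxygens). A target atom identical to a centre atom is skipped.
#' @param r_max Largest distance, must not exceed half the smallest box
#'   edge.
#' @param dr Bin width, angstrom.
#' @return Tibble of class `"rdf_profile"` with columns `r` (bin centres),
#'   `g`, `counts` (raw pair counts over all frames and centres).
#' @export
compute_rdf <- function(traj, center_sel, target_sel, r_max, dr = 0.1) {
  if (is.null(traj$box)) abort("RDF needs a periodic box for the reference density")
  cidx <- as.integer(center_sel); tidx <- as.integer(target_sel)
  if (length(cidx) == 0L) abort("centre selection is empty")
  if (length(tidx) == 0L) abort("target selection is empty")
  half <- min(traj$box) / 2
  if (r_max > half + 1e-9) {
    abort(sprintf("r_max (%g A) exceeds half the smallest box edge (%g A)",
                  r_max, half))
  }
  breaks <- seq(0, r_max, by = dr)
  if (abs(breaks[length(breaks)] - r_max) > 1e-9) breaks <- c(breaks, r_max)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  nf <- n_frames(traj)
  for (i in seq_len(nf)) {
    fr <- frame_coords(traj, i)
    dm <- pair_distances(fr[cidx, , drop = FALSE], fr[tidx, , drop = FALSE],
                         traj$box)
    self <- outer(cidx, tidx, "==")
    d <- dm[!self]
    d <- d[d < r_max]
    if (length(d)) {
      counts <- counts + tabulate(findInterval(d, breaks,
                                               rightmost.closed = FALSE),
                                  nbins = nb)
    }
  }
  vol <- prod(traj$box)
  rho_ref <- length(tidx) / vol
  shell_vol <- 4 / 3 * pi * (breaks[-1L]^3 - breaks[-length(breaks)]^3)
  norm <- nf * length(cidx) * rho_ref * shell_vol
  out <- tibble(
    r = (breaks[-1L] + breaks[-length(breaks)]) / 2,
    g = counts / norm,
    counts = counts
  )
  class(out) <- c("rdf_profile", class(out))
  attr(out, "meta") <- list(
    dr = dr, rho_ref = rho_ref, n_centers = length(cidx),
    n_targets = length(tidx), n_frames = nf, r_max = r_max
  )
  out
}

#' Average neighbour count within a radius
#'
#' Integrates the raw RDF pair counts out to `r_to`, i.e. the mean number of
#' target atoms within that radius of a centre (equivalently
#' `4 pi rho_ref int r^2 g(r) dr` evaluated on the histogram).
#'
#' @param rdf An `"rdf_profile"` from [compute_rdf()].
#' @param r_to Upper integration limit, angstrom.
#' @return Mean neighbour count per centre per frame.
#' @export
shell_count <- function(rdf, r_to) {
  meta <- attr(rdf, "meta")
  if (is.null(meta)) abort("shell_count needs an rdf_profile with metadata")
  upper <- rdf$r + meta$dr / 2
  sum(rdf$counts[upper <= r_to + 1e-9]) / (meta$n_frames * meta$n_centers)
}
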