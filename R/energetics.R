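# Simplified endpoint binding-energy estimator: molecular-mechanics
# interaction energy (Coulomb + Lennard-Jones) plus generalized-Born
# solvation and a surface-area nonpolar term, evaluated at fixed
# snapshot intervals along a trajectory.
#
# This is a self-contained estimator with input Born radii and no entropy
# term - a defined, documented model, not a reimplementation of any MD
# engine's MM-GBSA pipeline.

COULOMB_K <- 332.0637  # kcal * A / (mol * e^2)

#' Per-atom energy parameters
#'
#' Bundles per-atom charges (e), Lennard-Jones `eps` (kcal/mol) and
#' `sigma` (angstrom), and Born radii (angstrom) with the global model
#' constants: interior/exterior dielectrics and the nonpolar
#' surface-tension coefficient applied to the solvent-accessible surface
#' area.
#'
#' @param top A [topology()] the vectors align with.
#' @param charge Per-atom charges; defaults to the topology's (e.g. from a
#'   PQR file).
#' @param eps,sigma Per-atom LJ parameters (scalars are recycled).
#' @param born_radius Per-atom Born radii; defaults to the topology's van
#'   der Waals radii.
#' @param eps_in,eps_out Interior and exterior dielectric constants
#'   (defaults 1 and 78.5).
#' @param gamma Surface tension, kcal/mol/angstrom^2 (default 0.0072).
#' @param sa_offset Constant offset of the nonpolar term, kcal/mol.
#' @return List of class `"energy_parameters"` with an `atoms` tibble and
#'   the global constants.
#' @export
energy_parameters <- function(top, charge = top$charge, eps = 0, sigma = 3.4,
                              born_radius = top$vdw_radius,
                              eps_in = 1, eps_out = 78.5, gamma = 0.0072,
                              sa_offset = 0) {
  n <- nrow(top)
  if (!(eps_out > eps_in && eps_in >= 1)) {
    abort("dielectrics must satisfy eps_out > eps_in >= 1")
  }
  atoms <- tibble(
    index = top$index,
    charge = rep_len(charge, n),
    eps = rep_len(eps, n),
    sigma = rep_len(sigma, n),
    born_radius = rep_len(born_radius, n)
  )
  br <- atoms$born_radius
  if (any(!is.na(br) & br <= 0)) abort("Born radii must be > 0")
  structure(
    list(atoms = atoms, eps_in = eps_in, eps_out = eps_out, gamma = gamma,
         sa_offset = sa_offset, k = COULOMB_K),
    class = "energy_parameters"
  )
}

check_params <- function(params, idx, fields) {
  for (f in fields) {
    bad <- idx[is.na(params$atoms[[f]][idx])]
    if (length(bad)) {
      abort(paste0(
        "missing ", f, " for atoms ", paste(head(bad, 10L), collapse = ", "),
        if (length(bad) > 10L) ", ..." else ""
      ))
    }
  }
}

#' Molecular-mechanics interaction energy between two selections
#'
#' Pairwise sum over all cross pairs: Coulomb
#' `k q_i q_j / (eps_in r_ij)` with `k = 332.0637` kcal A/(mol e^2), and
#' 12-6 Lennard-Jones with Lorentz-Berthelot combining
#' (`sigma_ij = (sigma_i + sigma_j)/2`, `eps_ij = sqrt(eps_i eps_j)`).
#' No cutoff: systems at this scale are summed exactly.
#'
#' @param xyz `n x 3` frame coordinates.
#' @param selA,selB Disjoint selections.
#' @param params An [energy_parameters()].
#' @return Named list `E_coulomb`, `E_lj` (kcal/mol).
#' @export
mm_interaction_energy <- function(xyz, selA, selB, params) {
  ia <- as.integer(selA); ib <- as.integer(selB)
  if (length(intersect(ia, ib))) abort("selections must be disjoint")
  check_params(params, c(ia, ib), c("charge", "eps", "sigma"))
  at <- params$atoms
  r <- pair_distances(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  qq <- outer(at$charge[ia], at$charge[ib])
  e_coul <- params$k * sum(qq / r) / params$eps_in
  epsij <- sqrt(outer(at$eps[ia], at$eps[ib]))
  sigij <- outer(at$sigma[ia], at$sigma[ib], "+") / 2
  sr6 <- (sigij / r)^6
  e_lj <- sum(4 * epsij * (sr6^2 - sr6))
  list(E_coulomb = e_coul, E_lj = e_lj)
}

# internal (within-selection) MM energy over unordered pairs
mm_internal_energy <- function(xyz, sel, params) {
  idx <- as.integer(sel)
  n <- length(idx)
  if (n < 2L) return(list(E_coulomb = 0, E_lj = 0))
  at <- params$atoms
  r <- pair_distances(xyz[idx, , drop = FALSE], xyz[idx, , drop = FALSE])
  ut <- upper.tri(r)
  qq <- outer(at$charge[idx], at$charge[idx])
  e_coul <- params$k * sum(qq[ut] / r[ut]) / params$eps_in
  epsij <- sqrt(outer(at$eps[idx], at$eps[idx]))
  sigij <- outer(at$sigma[idx], at$sigma[idx], "+") / 2
  sr6 <- (sigij[ut] / r[ut])^6
  e_lj <- sum(4 * epsij[ut] * (sr6^2 - sr6))
  list(E_coulomb = e_coul, E_lj = e_lj)
}

#' Generalized-Born solvation energy
#'
#' The classic pairwise form
#' `G = -(k/2) (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB(r_ij)`,
#' `f_GB = sqrt(r^2 + a_i a_j exp(-r^2 / (4 a_i a_j)))`, with the self
#' (i = j) terms included; for a single charge this reduces to the Born
#' formula `-(k/2)(1/eps_in - 1/eps_out) q^2 / a`.
#'
#' @param xyz `n x 3` coordinates.
#' @param charges Per-atom charges (e).
#' @param born_radii Per-atom Born radii (angstrom), all > 0.
#' @param eps_in,eps_out Dielectrics.
#' @return Solvation energy, kcal/mol.
#' @export
gb_energy <- function(xyz, charges, born_radii, eps_in = 1, eps_out = 78.5) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  n <- nrow(xyz)
  stopifnot(length(charges) == n, length(born_radii) == n)
  if (any(is.na(born_radii)) || any(born_radii <= 0)) {
    abort("Born radii must all be present and > 0")
  }
  if (all(charges == 0)) return(0)
  r2 <- pair_distances(xyz, xyz)^2
  aa <- outer(born_radii, born_radii)
  fgb <- sqrt(r2 + aa * exp(-r2 / (4 * aa)))
  qq <- outer(charges, charges)
  -(COULOMB_K / 2) * (1 / eps_in - 1 / eps_out) * sum(qq / fgb)
}

# near-uniform directions on the unit sphere (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA over the non-hydrogen atoms of a selection: test points
#' on each atom's solvent-expanded sphere (radius + probe) are accessible
#' if they fall outside every other expanded sphere; the atom contributes
#' the accessible fraction of its sphere area.
#'
#' @param top A [topology()] with radii assigned.
#' @param xyz `n x 3` frame coordinates.
#' @param sel Selection; hydrogens are excluded.
#' @param probe_radius Probe radius, angstrom (default 1.4, water).
#' @param n_sphere_points Test points per atom (default 960).
#' @return Total SASA in angstrom^2, with per-atom areas in attribute
#'   `"per_atom"`.
#' @export
sasa <- function(top, xyz, sel = seq_len(nrow(top)), probe_radius = 1.4,
                 n_sphere_points = 960L) {
  idx <- as.integer(sel)
  idx <- idx[!top$is_hydrogen[idx]]
  if (length(idx) == 0L) abort("no non-hydrogen atoms in selection")
  rad <- top$vdw_radius[idx]
  if (anyNA(rad)) abort("van der Waals radii missing; run assign_radii() first")
  R <- rad + probe_radius
  pts <- sphere_points(n_sphere_points)
  pos <- xyz[idx, , drop = FALSE]
  n <- length(idx)
  areas <- numeric(n)
  d2 <- pair_distances(pos, pos)^2
  for (i in seq_len(n)) {
    test <- sweep(pts * R[i], 2L, pos[i, ], "+")
    # neighbours whose expanded sphere could occlude points of atom i
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dj <- test[acc, , drop = FALSE]
      dd <- (dj[, 1L] - pos[j, 1L])^2 + (dj[, 2L] - pos[j, 2L])^2 +
        (dj[, 3L] - pos[j, 3L])^2
      acc[acc] <- dd > R[j]^2
      if (!any(acc)) break
    }
    areas[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  structure(sum(areas), per_atom = setNames(areas, idx))
}

species_energy <- function(top, xyz, sel, params) {
  idx <- as.integer(sel)
  at <- params$atoms
  check_params(params, idx, c("charge", "eps", "sigma", "born_radius"))
  mm <- mm_internal_energy(xyz, idx, params)
  gb <- gb_energy(xyz[idx, , drop = FALSE], at$charge[idx],
                  at$born_radius[idx], params$eps_in, params$eps_out)
  np <- params$gamma * sasa(top, xyz, idx) + params$sa_offset
  list(E_coulomb = mm$E_coulomb, E_lj = mm$E_lj, G_gb = gb, G_np = np)
}

#' Endpoint binding-energy series
#'
#' Single-trajectory endpoint estimate evaluated every `interval` ns:
#' `dG = G(complex) - G(receptor) - G(ligand)` where each species energy
#' is its internal Coulomb + Lennard-Jones energy plus generalized-Born
#' solvation plus `gamma * SASA`. Internal terms common to complex and
#' separated species cancel in the difference, so the Coulomb component of
#' `dG` equals the receptor-ligand interaction energy exactly.
#'
#' @param traj A [trajectory()].
#' @param receptor_sel,ligand_sel Disjoint selections.
#' @param params An [energy_parameters()].
#' @param interval Snapshot spacing in ns (default 10); times not on the
#'   frame grid snap to the nearest frame with a warning.
#' @return Tibble of class `"energy_series"`: `time_ns`, `E_coulomb`,
#'   `E_lj`, `G_gb`, `G_np`, `total` (all kcal/mol, binding differences).
#' @export
binding_energy_series <- function(traj, receptor_sel, ligand_sel, params,
                                  interval = 10) {
  ir <- as.integer(receptor_sel); il <- as.integer(ligand_sel)
  if (length(intersect(ir, il))) abort("receptor and ligand selections overlap")
  want <- seq(0, max(traj$times), by = interval)
  snapped <- round(want / traj$dt) + 1L
  snapped <- pmin(pmax(snapped, 1L), n_frames(traj))
  if (any(abs((snapped - 1L) * traj$dt - want) > 1e-9)) {
    warn("snapshot interval is not a multiple of dt; using nearest frames")
  }
  snapped <- unique(snapped)
  both <- sort(c(ir, il))
  top <- traj$topology
  rows <- lapply(snapped, function(i) {
    xyz <- frame_coords(traj, i)
    gc_ <- species_energy(top, xyz, both, params)
    gr <- species_energy(top, xyz, ir, params)
    gl <- species_energy(top, xyz, il, params)
    tibble(
      time_ns = traj$times[i],
      E_coulomb = gc_$E_coulomb - gr$E_coulomb - gl$E_coulomb,
      E_lj = gc_$E_lj - gr$E_lj - gl$E_lj,
      G_gb = gc_$G_gb - gr$G_gb - gl$G_gb,
      G_np = gc_$G_np - gr$G_np - gl$G_np
    )
  })
  out <- bind_rows(rows)
  out$total <- out$E_coulomb + out$E_lj + out$G_gb + out$G_np
  class(out) <- c("energy_series", class(out))
  out
}
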