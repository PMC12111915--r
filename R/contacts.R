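# Three-class intermolecular contact detection (hydrogen bonds, salt
# bridges, van der Waals), intra-domain hydrogen bonds, and ion
# coordination counting.
#
# All cutoffs use strict "<" comparisons; on real-valued coordinates the
# boundary set has measure zero, and a single convention keeps the
# detectors and their brute-force oracles in exact agreement.

#' Contact detection criteria
#'
#' Geometric criteria for the contact detectors, with the defaults used
#' throughout: intermolecular hydrogen bonds at donor-acceptor distance
#' < 3.5 angstrom and D-H...A angle within 70 degrees of linearity
#' (i.e. in \[110, 180\] degrees, evaluated at the hydrogen); salt bridges
#' at anionic-O to cationic-N distance < 4.0 angstrom; van der Waals
#' contacts between non-hydrogen atoms at `|AB| < R(A) + R(B) + 0.5`;
#' intra-domain hydrogen bonds at < 3.0 angstrom and < 20 degrees
#' deviation from linearity; ion coordination within a 3.5 angstrom
#' sphere.
#'
#' @param hbond_da_max,hbond_angle_min Intermolecular H-bond cutoffs
#'   (angstrom; minimum D-H...A angle in degrees).
#' @param angle_at Evaluate the H-bond angle at the `"hydrogen"` (default)
#'   or as the deviation seen from the `"donor"`-H vector extension; both
#'   give the D-H...A angle, the knob records the convention.
#' @param saltbridge_max Salt-bridge distance cutoff, angstrom.
#' @param vdw_slack Slack added to the radius sum, angstrom.
#' @param intra_hbond_da_max,intra_hbond_angle_dev_max Intra-domain H-bond
#'   cutoffs (angstrom; maximum deviation from linearity in degrees).
#' @param coordination_radius Ion coordination sphere radius, angstrom.
#' @param dh_bond_max Donor-hydrogen geometric bond cutoff, angstrom
#'   (covalent bonds are inferred from distance; input files carry no
#'   connectivity).
#' @param donor_elements,acceptor_elements Element sets for donors
#'   (heavy atom carrying the hydrogen) and acceptors.
#' @param anion_atoms Named list, residue name to anionic oxygen names.
#' @param cation_atoms Named list, residue name to cationic nitrogen names.
#' @param protonated_his Residue ids of histidines to treat as cationic
#'   (neutral by default).
#' @param ligand_anion_names,ligand_cation_names Extra atom names (any
#'   residue) counted as anionic/cationic, e.g. ligand phosphate oxygens.
#' @return List of class `"contact_criteria"`.
#' @export
contact_criteria <- function(hbond_da_max = 3.5, hbond_angle_min = 110,
                             angle_at = c("hydrogen", "donor"),
                             saltbridge_max = 4.0, vdw_slack = 0.5,
                             intra_hbond_da_max = 3.0,
                             intra_hbond_angle_dev_max = 20,
                             coordination_radius = 3.5,
                             dh_bond_max = 1.2,
                             donor_elements = c("N", "O", "S"),
                             acceptor_elements = c("N", "O"),
                             anion_atoms = list(
                               ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
                             ),
                             cation_atoms = list(
                               LYS = "NZ", ARG = c("NE", "NH1", "NH2")
                             ),
                             protonated_his = integer(0),
                             ligand_anion_names = character(0),
                             ligand_cation_names = character(0)) {
  cr <- list(
    hbond_da_max = hbond_da_max, hbond_angle_min = hbond_angle_min,
    angle_at = match.arg(angle_at), saltbridge_max = saltbridge_max,
    vdw_slack = vdw_slack, intra_hbond_da_max = intra_hbond_da_max,
    intra_hbond_angle_dev_max = intra_hbond_angle_dev_max,
    coordination_radius = coordination_radius, dh_bond_max = dh_bond_max,
    donor_elements = donor_elements, acceptor_elements = acceptor_elements,
    anion_atoms = anion_atoms, cation_atoms = cation_atoms,
    protonated_his = protonated_his,
    ligand_anion_names = ligand_anion_names,
    ligand_cation_names = ligand_cation_names
  )
  dists <- c(cr$hbond_da_max, cr$saltbridge_max, cr$intra_hbond_da_max,
             cr$coordination_radius, cr$dh_bond_max)
  if (any(dists <= 0)) abort("all criteria distances must be > 0")
  if (cr$hbond_angle_min < 0 || cr$hbond_angle_min > 180 ||
        cr$intra_hbond_angle_dev_max < 0 || cr$intra_hbond_angle_dev_max > 180) {
    abort("angle bounds must lie in [0, 180] degrees")
  }
  structure(cr, class = "contact_criteria")
}

# (donor, hydrogen) pairs inferred geometrically: each hydrogen is bonded
# to the nearest donor-element heavy atom within dh_bond_max.
donor_hydrogen_pairs <- function(top, xyz, criteria, box = NULL) {
  h_idx <- which(top$is_hydrogen)
  d_idx <- which(!top$is_hydrogen & top$element %in% criteria$donor_elements)
  if (length(h_idx) == 0L || length(d_idx) == 0L) {
    return(tibble(donor = integer(), hydrogen = integer()))
  }
  dm <- pair_distances(xyz[h_idx, , drop = FALSE], xyz[d_idx, , drop = FALSE],
                       box)
  nearest <- apply(dm, 1L, which.min)
  dist <- dm[cbind(seq_along(h_idx), nearest)]
  keep <- dist < criteria$dh_bond_max
  tibble(donor = d_idx[nearest[keep]], hydrogen = h_idx[keep])
}

cross_mask <- function(i, j, sel1, sel2) {
  (i %in% sel1 & j %in% sel2) | (i %in% sel2 & j %in% sel1)
}

#' Detect intermolecular hydrogen bonds in one frame
#'
#' One record per (donor, hydrogen, acceptor) triple crossing the two
#' selections with donor-acceptor distance below the cutoff and D-H...A
#' angle within the accepted range; donor and acceptor must belong to
#' different residues.
#'
#' @param top A [topology()] with explicit hydrogens.
#' @param xyz `n x 3` coordinate matrix for the frame.
#' @param sel1,sel2 Selections the bond must cross.
#' @param criteria A [contact_criteria()].
#' @param box Optional box for minimum-image distances.
#' @param mode `"geometric"` (distance + angle, default) or
#'   `"distance_only"` (donor-acceptor distance only, for topologies
#'   without hydrogens).
#' @return Tibble of contact records (`class`, `donor`, `hydrogen`,
#'   `acceptor`, `distance`, `angle`, residue labels).
#' @export
detect_hbonds_inter <- function(top, xyz, sel1, sel2, criteria = contact_criteria(),
                                box = NULL,
                                mode = c("geometric", "distance_only")) {
  mode <- match.arg(mode)
  sel1 <- as.integer(sel1); sel2 <- as.integer(sel2)
  acc_idx <- which(!top$is_hydrogen & top$element %in% criteria$acceptor_elements)
  empty <- tibble(
    class = character(), frame = integer(), donor = integer(),
    hydrogen = integer(), acceptor = integer(), distance = numeric(),
    angle = numeric(), donor_res = character(), acceptor_res = character()
  )
  if (mode == "geometric") {
    dh <- donor_hydrogen_pairs(top, xyz, criteria, box)
    if (nrow(dh) == 0L) {
      if (!any(top$is_hydrogen)) {
        abort(paste0(
          "no hydrogens present in the topology; geometric hydrogen-bond ",
          "detection needs explicit hydrogens - use mode = \"distance_only\" ",
          "for a donor-acceptor distance criterion instead"
        ))
      }
      return(empty)
    }
  } else {
    don_idx <- which(!top$is_hydrogen & top$element %in% criteria$donor_elements)
    dh <- tibble(donor = don_idx, hydrogen = NA_integer_)
  }
  if (length(acc_idx) == 0L || nrow(dh) == 0L) return(empty)
  # candidate (DH, A) combinations
  cand <- tidyr::expand_grid(k = seq_len(nrow(dh)), acceptor = acc_idx)
  cand$donor <- dh$donor[cand$k]
  cand$hydrogen <- dh$hydrogen[cand$k]
  cand <- cand[cand$donor != cand$acceptor, ]
  cand <- cand[cross_mask(cand$donor, cand$acceptor, sel1, sel2), ]
  # different residues
  rk <- residue_key(top)
  cand <- cand[rk[cand$donor] != rk[cand$acceptor], ]
  if (nrow(cand) == 0L) return(empty)
  cand$distance <- min_image_distance(xyz[cand$donor, , drop = FALSE],
                                      xyz[cand$acceptor, , drop = FALSE], box)
  cand <- cand[cand$distance < criteria$hbond_da_max, ]
  if (nrow(cand) == 0L) return(empty)
  if (mode == "geometric") {
    cand$angle <- vapply(seq_len(nrow(cand)), function(r) {
      vertex_angle(xyz[cand$donor[r], ], xyz[cand$hydrogen[r], ],
                   xyz[cand$acceptor[r], ], box)
    }, numeric(1))
    cand <- cand[cand$angle > criteria$hbond_angle_min, ]
  } else {
    cand$angle <- NA_real_
    # without hydrogens the donor/acceptor roles are symmetric for atoms
    # that qualify as both; count each unordered pair once
    lo <- pmin(cand$donor, cand$acceptor)
    hi <- pmax(cand$donor, cand$acceptor)
    cand <- cand[!duplicated(paste(lo, hi)), ]
  }
  if (nrow(cand) == 0L) return(empty)
  tibble(
    class = "hbond", frame = NA_integer_, donor = cand$donor,
    hydrogen = cand$hydrogen, acceptor = cand$acceptor,
    distance = cand$distance, angle = cand$angle,
    donor_res = res_label(top, cand$donor),
    acceptor_res = res_label(top, cand$acceptor)
  )
}

res_label <- function(top, idx) {
  paste0(top$resname[idx], top$resid[idx], ":", top$chain[idx])
}

charged_sets <- function(top, criteria) {
  an <- rep(FALSE, nrow(top)); cat_ <- rep(FALSE, nrow(top))
  for (rn in names(criteria$anion_atoms)) {
    an <- an | (toupper(top$resname) == rn &
                  toupper(top$name) %in% criteria$anion_atoms[[rn]])
  }
  for (rn in names(criteria$cation_atoms)) {
    cat_ <- cat_ | (toupper(top$resname) == rn &
                      toupper(top$name) %in% criteria$cation_atoms[[rn]])
  }
  if (length(criteria$protonated_his)) {
    cat_ <- cat_ | (toupper(top$resname) %in% c("HIS", "HSD", "HSE", "HSP") &
                      top$resid %in% criteria$protonated_his &
                      toupper(top$name) %in% c("ND1", "NE2"))
  }
  if (length(criteria$ligand_anion_names)) {
    an <- an | toupper(top$name) %in% toupper(criteria$ligand_anion_names)
  }
  if (length(criteria$ligand_cation_names)) {
    cat_ <- cat_ | toupper(top$name) %in% toupper(criteria$ligand_cation_names)
  }
  list(anion = which(an & top$element == "O"),
       cation = which(cat_ & top$element == "N"))
}

#' Detect salt bridges in one frame
#'
#' One record per anionic-oxygen / cationic-nitrogen pair crossing the two
#' selections at distance below the cutoff. Charged-group membership comes
#' from the criteria tables (Asp/Glu carboxylate oxygens, Lys/Arg nitrogen
#' groups, optionally protonated histidines, plus any configured ligand
#' phosphate/carboxylate oxygens).
#'
#' @inheritParams detect_hbonds_inter
#' @param group_dedupe Count at most one bridge per residue pair?
#' @return Tibble of contact records.
#' @export
detect_salt_bridges <- function(top, xyz, sel1, sel2,
                                criteria = contact_criteria(), box = NULL,
                                group_dedupe = FALSE) {
  sel1 <- as.integer(sel1); sel2 <- as.integer(sel2)
  cs <- charged_sets(top, criteria)
  empty <- tibble(
    class = character(), frame = integer(), atom1 = integer(),
    atom2 = integer(), distance = numeric(), res1 = character(),
    res2 = character()
  )
  if (length(cs$anion) == 0L || length(cs$cation) == 0L) return(empty)
  grid <- tidyr::expand_grid(atom1 = cs$anion, atom2 = cs$cation)
  grid <- grid[cross_mask(grid$atom1, grid$atom2, sel1, sel2), ]
  if (nrow(grid) == 0L) return(empty)
  grid$distance <- min_image_distance(xyz[grid$atom1, , drop = FALSE],
                                      xyz[grid$atom2, , drop = FALSE], box)
  grid <- grid[grid$distance < criteria$saltbridge_max, ]
  if (nrow(grid) == 0L) return(empty)
  out <- tibble(
    class = "saltbridge", frame = NA_integer_, atom1 = grid$atom1,
    atom2 = grid$atom2, distance = grid$distance,
    res1 = res_label(top, grid$atom1), res2 = res_label(top, grid$atom2)
  )
  if (group_dedupe) {
    out <- out |>
      group_by(.data$res1, .data$res2) |>
      filter(.data$distance == min(.data$distance)) |>
      ungroup()
  }
  out
}

#' Detect van der Waals contacts in one frame
#'
#' One record per non-hydrogen atom pair crossing the selections with
#' `|AB| < R_vdw(A) + R_vdw(B) + slack`. Radii must be assigned (see
#' [assign_radii()]). Pairs already counted as hydrogen bonds or salt
#' bridges are *not* removed (the three classes sum to the total contact
#' count); pass records to [count_contacts()] with `dedupe = TRUE` for the
#' alternative convention.
#'
#' @inheritParams detect_hbonds_inter
#' @return Tibble of contact records.
#' @export
detect_vdw_contacts <- function(top, xyz, sel1, sel2,
                                criteria = contact_criteria(), box = NULL) {
  sel1 <- as.integer(sel1); sel2 <- as.integer(sel2)
  h1 <- sel1[!top$is_hydrogen[sel1]]
  h2 <- sel2[!top$is_hydrogen[sel2]]
  empty <- tibble(
    class = character(), frame = integer(), atom1 = integer(),
    atom2 = integer(), distance = numeric(), res1 = character(),
    res2 = character()
  )
  if (length(h1) == 0L || length(h2) == 0L) return(empty)
  rad <- top$vdw_radius
  need <- unique(c(h1, h2))
  if (anyNA(rad[need])) {
    abort(paste0(
      "van der Waals radii missing for atoms ",
      paste(head(need[is.na(rad[need])], 10L), collapse = ", "),
      "; run assign_radii() first"
    ))
  }
  dm <- pair_distances(xyz[h1, , drop = FALSE], xyz[h2, , drop = FALSE], box)
  thr <- outer(rad[h1], rad[h2], "+") + criteria$vdw_slack
  hit <- which(dm < thr, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  a1 <- h1[hit[, 1L]]; a2 <- h2[hit[, 2L]]
  # drop self pairs and count overlapping selections once
  keep <- a1 != a2
  a1 <- a1[keep]; a2 <- a2[keep]
  d <- dm[hit][keep]
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  dup <- duplicated(paste(lo, hi))
  tibble(
    class = "vdw", frame = NA_integer_, atom1 = lo[!dup], atom2 = hi[!dup],
    distance = d[!dup], res1 = res_label(top, lo[!dup]),
    res2 = res_label(top, hi[!dup])
  )
}

#' Per-frame contact counts over a trajectory
#'
#' Runs the three intermolecular detectors on every frame and returns the
#' per-frame counts per class plus their sum.
#'
#' @param traj A [trajectory()].
#' @param sel1,sel2 Selections the contacts must cross (e.g. protein and
#'   ligand).
#' @param criteria A [contact_criteria()].
#' @param dedupe Remove van der Waals pairs whose atoms already form a
#'   hydrogen bond or salt bridge in the same frame? Default `FALSE`: the
#'   printed total is then exactly the sum of the three class counts.
#' @param hbond_mode Passed to [detect_hbonds_inter()].
#' @return Tibble of class `"contact_counts"`: `frame`, `time_ns`,
#'   `hbond`, `saltbridge`, `vdw`, `total`.
#' @export
count_contacts <- function(traj, sel1, sel2, criteria = contact_criteria(),
                           dedupe = FALSE, hbond_mode = "geometric") {
  top <- traj$topology
  nf <- n_frames(traj)
  out <- matrix(0L, nf, 3L)
  for (i in seq_len(nf)) {
    xyz <- frame_coords(traj, i)
    hb <- detect_hbonds_inter(top, xyz, sel1, sel2, criteria, traj$box,
                              mode = hbond_mode)
    sb <- detect_salt_bridges(top, xyz, sel1, sel2, criteria, traj$box)
    vw <- detect_vdw_contacts(top, xyz, sel1, sel2, criteria, traj$box)
    if (dedupe && nrow(vw)) {
      taken <- c(
        paste(pmin(hb$donor, hb$acceptor), pmax(hb$donor, hb$acceptor)),
        paste(pmin(sb$atom1, sb$atom2), pmax(sb$atom1, sb$atom2))
      )
      vw <- vw[!(paste(vw$atom1, vw$atom2) %in% taken), ]
    }
    out[i, ] <- c(nrow(hb), nrow(sb), nrow(vw))
  }
  res <- tibble(
    frame = seq_len(nf), time_ns = traj$times,
    hbond = out[, 1L], saltbridge = out[, 2L], vdw = out[, 3L],
    total = as.integer(rowSums(out))
  )
  class(res) <- c("contact_counts", class(res))
  res
}

#' Total contacts from per-class inputs
#'
#' The total contact count is the plain sum of the hydrogen-bond,
#' salt-bridge and van der Waals class values - per frame when given a
#' per-frame count table, or of the class means when given a named numeric
#' vector (the printed-arithmetic form, e.g.
#' `total_contacts(c(hbond = 7.6, saltbridge = 0.6, vdw = 58.5))` is 66.7).
#'
#' @param x A `"contact_counts"` tibble or a named numeric vector with
#'   entries `hbond`, `saltbridge`, `vdw`.
#' @return For a vector: the total (numeric scalar). For a count table:
#'   the table with its `total` column recomputed.
#' @export
total_contacts <- function(x) {
  if (is.numeric(x)) {
    need <- c("hbond", "saltbridge", "vdw")
    if (!all(need %in% names(x))) {
      abort("named vector input needs entries hbond, saltbridge, vdw")
    }
    return(unname(sum(x[need])))
  }
  stopifnot(is.data.frame(x))
  x$total <- x$hbond + x$saltbridge + x$vdw
  x
}

#' Summarise contact counts
#'
#' Mean and block-averaged SEM per contact class and for the total.
#'
#' @param counts A `"contact_counts"` tibble from [count_contacts()].
#' @param n_blocks Blocks for the SEM, default 5.
#' @return Tibble: `class`, `mean`, `sem`, `n_frames`.
#' @export
contact_summary <- function(counts, n_blocks = 5L) {
  cls <- c("hbond", "saltbridge", "vdw", "total")
  bind_rows(lapply(cls, function(cl) {
    s <- block_average(counts[[cl]], n_blocks = n_blocks)
    tibble(class = cl, mean = s$mean, sem = s$sem, n_frames = nrow(counts))
  }))
}

#' Intra-domain hydrogen-bond counts per frame
#'
#' Counts (donor, hydrogen, acceptor) triples with both donor and acceptor
#' inside the domain selection, donor-acceptor distance below the
#' intra-domain cutoff (3.0 angstrom default) and deviation from linearity
#' below the angle cutoff (20 degrees default).
#'
#' @param traj A [trajectory()] with explicit hydrogens.
#' @param domain_sel Selection covering one domain.
#' @param criteria A [contact_criteria()].
#' @return A `"time_series"` tibble of counts.
#' @export
detect_hbonds_intra <- function(traj, domain_sel,
                                criteria = contact_criteria()) {
  top <- traj$topology
  sel <- as.integer(domain_sel)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    xyz <- frame_coords(traj, i)
    dh <- donor_hydrogen_pairs(top, xyz, criteria, traj$box)
    dh <- dh[dh$donor %in% sel, , drop = FALSE]
    if (nrow(dh) == 0L) return(0L)
    acc <- sel[!top$is_hydrogen[sel] &
                 top$element[sel] %in% criteria$acceptor_elements]
    if (length(acc) == 0L) return(0L)
    cnt <- 0L
    for (r in seq_len(nrow(dh))) {
      a_ok <- acc[acc != dh$donor[r]]
      if (!length(a_ok)) next
      d <- min_image_distance(
        matrix(xyz[dh$donor[r], ], length(a_ok), 3L, byrow = TRUE),
        xyz[a_ok, , drop = FALSE], traj$box
      )
      close <- a_ok[d < criteria$intra_hbond_da_max]
      for (a in close) {
        ang <- vertex_angle(xyz[dh$donor[r], ], xyz[dh$hydrogen[r], ], xyz[a, ],
                            traj$box)
        if (180 - ang < criteria$intra_hbond_angle_dev_max) cnt <- cnt + 1L
      }
    }
    cnt
  }, integer(1))
  new_time_series(traj$times, as.numeric(vals), label = "intra-domain H-bonds",
                  units = "count")
}

#' Ion coordination counts per frame
#'
#' Counts, within the coordination sphere around each ion atom, (a)
#' protein residues - a residue counts once if any of its non-hydrogen
#' atoms lies within the radius - and (b) water molecules, counted via
#' their oxygen.
#'
#' @param traj A [trajectory()].
#' @param ion_sel Selection with the ion atom(s).
#' @param environment_sels Named list with `protein` and `water`
#'   selections; defaults to the topology's protein and water-oxygen sets.
#' @param radius Coordination radius, angstrom (default 3.5).
#' @return Tibble: `frame`, `time_ns`, `n_residues`, `n_waters`.
#' @export
ion_coordination <- function(traj, ion_sel, environment_sels = NULL,
                             radius = contact_criteria()$coordination_radius) {
  top <- traj$topology
  ion <- as.integer(ion_sel)
  if (length(ion) == 0L) abort("ion selection is empty")
  env <- environment_sels %||% list(
    protein = select_atoms(top, "protein and not hydrogen"),
    water = select_atoms(top, "water and element O")
  )
  prot <- as.integer(env$protein)
  prot <- prot[!top$is_hydrogen[prot]]
  wat <- as.integer(env$water)
  wat <- wat[top$element[wat] == "O"]
  rk <- residue_key(top)
  nf <- n_frames(traj)
  nres <- integer(nf); nwat <- integer(nf)
  for (i in seq_len(nf)) {
    xyz <- frame_coords(traj, i)
    ion_xyz <- xyz[ion, , drop = FALSE]
    if (length(prot)) {
      dm <- pair_distances(ion_xyz, xyz[prot, , drop = FALSE], traj$box)
      within <- prot[apply(dm < radius, 2L, any)]
      nres[i] <- length(unique(rk[within]))
    }
    if (length(wat)) {
      dm <- pair_distances(ion_xyz, xyz[wat, , drop = FALSE], traj$box)
      nwat[i] <- sum(apply(dm < radius, 2L, any))
    }
  }
  tibble(frame = seq_len(nf), time_ns = traj$times,
         n_residues = nres, n_waters = nwat)
}
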