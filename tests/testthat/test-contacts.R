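# Contact detectors: boundary fixtures, oracle equivalence, invariances.

hb_count <- function(d, ang, crit = contact_criteria()) {
  sc <- gen_hbond_scene(d, ang)
  nrow(detect_hbonds_inter(sc$topology, sc$coords, 1:2, 3, crit))
}

test_that("hydrogen-bond boundaries follow the 3.5 A / 110 degree criteria", {
  expect_equal(hb_count(3.4, 170), 1L)
  expect_equal(hb_count(3.6, 170), 0L)
  expect_equal(hb_count(3.0, 100), 0L)  # below the angle floor
  expect_equal(hb_count(3.0, 111), 1L)
  # the alternative reading (angle >= 70) is one knob away
  expect_equal(hb_count(3.0, 100, contact_criteria(hbond_angle_min = 70)), 1L)
})

test_that("hydrogen-bond detection needs hydrogens unless distance-only", {
  top <- topology(tibble::tibble(
    name = c("N", "O"), element = c("N", "O"), resname = c("GLY", "SER"),
    resid = 1:2
  ))
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_error(detect_hbonds_inter(top, xyz, 1, 2), "distance-only|distance_only")
  rec <- detect_hbonds_inter(top, xyz, 1, 2, mode = "distance_only")
  expect_equal(nrow(rec), 1L)
})

test_that("salt-bridge boundaries follow the 4.0 A cutoff with group gating", {
  mk <- function(d, resnames = c("LYS", "ASP"), names = c("NZ", "OD1"),
                 elements = c("N", "O")) {
    top <- topology(tibble::tibble(
      name = names, element = elements, resname = resnames, resid = 1:2
    ))
    xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
    nrow(detect_salt_bridges(top, xyz, 1, 2))
  }
  expect_equal(mk(3.8), 1L)
  expect_equal(mk(4.1), 0L)
  # neutral pair at 3.0 A is not a salt bridge
  expect_equal(mk(3.0, c("ALA", "ALA"), c("N", "O"), c("N", "O")), 0L)
  # configured ligand phosphate oxygen counts as anionic
  top <- topology(tibble::tibble(
    name = c("NZ", "O1P"), element = c("N", "O"), resname = c("LYS", "LIG"),
    resid = 1:2
  ))
  crit <- contact_criteria(ligand_anion_names = "O1P")
  expect_equal(nrow(detect_salt_bridges(top, rbind(c(0, 0, 0), c(3.8, 0, 0)),
                                        1, 2, crit)), 1L)
  expect_equal(nrow(detect_salt_bridges(top, rbind(c(0, 0, 0), c(3.8, 0, 0)),
                                        1, 2)), 0L)
})

test_that("van der Waals contacts use the radius sum plus 0.5 A", {
  mk <- function(d, elements = c("C", "C"), names = c("C1", "C2")) {
    top <- assign_radii(topology(tibble::tibble(
      name = names, element = elements, resname = c("AAA", "BBB"), resid = 1:2
    )))
    nrow(detect_vdw_contacts(top, rbind(c(0, 0, 0), c(d, 0, 0)), 1, 2))
  }
  expect_equal(mk(3.8), 1L)  # threshold 1.70 + 1.70 + 0.5 = 3.9
  expect_equal(mk(4.0), 0L)
  expect_equal(mk(2.0, c("C", "H"), c("C1", "H1")), 0L)  # hydrogens excluded
  # missing radii are reported
  top <- topology(tibble::tibble(name = c("C1", "C2"), element = "C",
                                 resname = c("AAA", "BBB"), resid = 1:2))
  expect_error(detect_vdw_contacts(top, rbind(c(0, 0, 0), c(3, 0, 0)), 1, 2),
               "assign_radii")
})

test_that("total contacts equal the sum of the three classes", {
  expect_equal(total_contacts(c(hbond = 7.6, saltbridge = 0.6, vdw = 58.5)),
               66.7)
  expect_equal(total_contacts(c(hbond = 4.6, saltbridge = 0.3, vdw = 53)),
               57.9)
  df <- tibble::tibble(frame = 1:3, hbond = c(2, 0, 1),
                       saltbridge = c(1, 0, 0), vdw = c(5, 0, 3),
                       total = NA_real_)
  expect_equal(total_contacts(df)$total, c(8, 0, 4))
})

test_that("intra-domain hydrogen bonds use the 3.0 A / 20 degree defaults", {
  intra <- function(d, dev) {
    sc <- gen_hbond_scene(d, 180 - dev)
    tr <- trajectory(sc$topology, array(sc$coords, c(1, 3, 3)), dt = 1)
    detect_hbonds_intra(tr, select_atoms(sc$topology, "resid 35 to 145"))$value
  }
  expect_equal(intra(2.9, 15), 1)
  expect_equal(intra(3.1, 15), 0)
  expect_equal(intra(2.9, 25), 0)
})

test_that("ion coordination counts residues once and waters by oxygen", {
  tr <- gen_hydration_shell(list(c(2.4, 6)), jitter = 0, n_frames = 3, seed = 1)
  cc <- ion_coordination(tr, select_atoms(tr$topology, "ion"))
  expect_equal(cc$n_waters, rep(6L, 3))
  expect_equal(cc$n_residues, rep(0L, 3))

  # water oxygen at 3.6 A is outside the 3.5 A sphere
  out <- gen_hydration_shell(list(c(3.6, 5)), jitter = 0, n_frames = 1, seed = 1)
  expect_equal(ion_coordination(out, select_atoms(out$topology, "ion"))$n_waters,
               0L)

  # mixed scene: two Asp oxygens of one residue + three waters
  top <- topology(tibble::tibble(
    name = c("CA", "OD1", "OD2", "OH2", "OH2", "OH2"),
    element = c("CA", "O", "O", "O", "O", "O"),
    resname = c("CA", "ASP", "ASP", "HOH", "HOH", "HOH"),
    resid = c(1, 2, 2, 3, 4, 5), chain = c("I", "A", "A", "W", "W", "W")
  ))
  xyz <- rbind(c(0, 0, 0), c(2.4, 0, 0), c(0, 2.4, 0),
               c(0, 0, 2.4), c(-2.4, 0, 0), c(0, -2.4, 0))
  tr <- trajectory(top, array(xyz, c(1, 6, 3)), dt = 1)
  cc <- ion_coordination(tr, select_atoms(top, "ion"))
  expect_equal(cc$n_residues, 1L)
  expect_equal(cc$n_waters, 3L)
  expect_equal(unname(oracle_coordination(top, xyz, 1L)),
               c(cc$n_residues, cc$n_waters))
})

test_that("detectors agree exactly with the naive all-pairs oracle", {
  for (seed in 1:12) {
    sc <- random_contact_scene(seed)
    top <- sc$topology
    sel_prot <- which(top$chain == "A")
    sel_lig <- which(top$chain == "L")
    hb <- detect_hbonds_inter(top, sc$xyz, sel_prot, sel_lig)
    expect_identical(nrow(hb), oracle_hbonds(top, sc$xyz, sel_prot, sel_lig))
    sb <- detect_salt_bridges(top, sc$xyz, sel_prot, sel_lig)
    expect_identical(nrow(sb),
                     oracle_salt_bridges(top, sc$xyz, sel_prot, sel_lig))
    vw <- detect_vdw_contacts(top, sc$xyz, sel_prot, sel_lig)
    expect_identical(nrow(vw), oracle_vdw(top, sc$xyz, sel_prot, sel_lig))
  }
})

test_that("contact counts are invariant under rigid motion and rewrapping", {
  sc <- random_contact_scene(99)
  top <- sc$topology
  sel1 <- which(top$chain == "A"); sel2 <- which(top$chain == "L")
  count3 <- function(xyz, box = NULL) {
    c(nrow(detect_hbonds_inter(top, xyz, sel1, sel2, box = box)),
      nrow(detect_salt_bridges(top, xyz, sel1, sel2, box = box)),
      nrow(detect_vdw_contacts(top, xyz, sel1, sel2, box = box)))
  }
  base <- count3(sc$xyz)
  R <- rotation_about_axis(c(2, -1, 1), 77)
  moved <- sweep(sc$xyz %*% t(R), 2, c(12, -3, 8), "+")
  expect_identical(count3(moved), base)
  # PBC rewrap: shift some atoms by whole box lengths
  box <- c(40, 40, 40)
  basep <- count3(sc$xyz, box)
  rewrapped <- sc$xyz
  rewrapped[seq(1, nrow(rewrapped), by = 3), 1] <-
    rewrapped[seq(1, nrow(rewrapped), by = 3), 1] + box[1]
  expect_identical(count3(rewrapped, box), basep)
})

test_that("per-frame totals satisfy the class-sum identity over a trajectory", {
  sc <- random_contact_scene(7)
  nf <- 4
  co <- array(0, c(nf, nrow(sc$topology), 3))
  set.seed(7)
  for (i in seq_len(nf)) co[i, , ] <- sc$xyz + matrix(rnorm(length(sc$xyz), sd = 0.15),
                                                      nrow(sc$xyz), 3)
  tr <- trajectory(sc$topology, co, dt = 1)
  sel1 <- which(sc$topology$chain == "A"); sel2 <- which(sc$topology$chain == "L")
  counts <- count_contacts(tr, sel1, sel2)
  expect_identical(counts$total, counts$hbond + counts$saltbridge + counts$vdw)
  s <- contact_summary(counts, n_blocks = 2)
  expect_equal(s$mean[s$class == "total"],
               sum(s$mean[s$class != "total"]), tolerance = 1e-12)
})
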