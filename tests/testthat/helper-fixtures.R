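# Fixtures built in code, and naive brute-force oracles kept deliberately
# independent of the package's production code paths.

# minimal one-water PDB text (3 atoms, 1 residue)
water_pdb_lines <- function() {
  c(
    "ATOM      1  OH2 HOH W   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  H1  HOH W   1       0.957   0.000   0.000  1.00  0.00           H",
    "ATOM      3  H2  HOH W   1      -0.240   0.927   0.000  1.00  0.00           H",
    "END"
  )
}

write_water_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(water_pdb_lines(), path)
  path
}

# synthetic protein-like chain: n_res residues, one N/CA/C/O backbone each
chain_topology <- function(n_res, resname = "ALA") {
  tibble::tibble(
    name = rep(c("N", "CA", "C", "O"), n_res),
    element = rep(c("N", "C", "C", "O"), n_res),
    resname = resname,
    resid = rep(seq_len(n_res), each = 4L),
    chain = "A"
  ) |> tidytraj::topology()
}

# random mixed scene used by the contact-oracle tests: a protein-like part
# with donors/hydrogens/charged groups and a ligand-like part
random_contact_scene <- function(seed, n_res = 12L, n_lig = 18L, spread = 9) {
  set.seed(seed)
  prot <- do.call(rbind, lapply(seq_len(n_res), function(r) {
    rn <- sample(c("ALA", "ASP", "LYS", "SER", "ARG", "GLU"), 1L)
    extra <- switch(rn,
      ASP = tibble::tibble(name = c("OD1", "OD2"), element = "O"),
      GLU = tibble::tibble(name = c("OE1", "OE2"), element = "O"),
      LYS = tibble::tibble(name = c("NZ", "HZ1"), element = c("N", "H")),
      ARG = tibble::tibble(name = c("NH1", "HH11"), element = c("N", "H")),
      SER = tibble::tibble(name = c("OG", "HG"), element = c("O", "H")),
      tibble::tibble(name = character(), element = character())
    )
    at <- rbind(
      tibble::tibble(name = c("N", "H", "CA", "C", "O"),
                     element = c("N", "H", "C", "C", "O")),
      extra
    )
    at$resname <- rn
    at$resid <- r
    at$chain <- "A"
    at
  }))
  lig <- tibble::tibble(
    name = c("P1", "O1P", "O2P", "O3", "H3", paste0("C", seq_len(n_lig - 5L))),
    element = c("P", "O", "O", "O", "H", rep("C", n_lig - 5L)),
    resname = "LIG", resid = max(prot$resid) + 1L, chain = "L"
  )
  top <- tidytraj::topology(rbind(prot, lig))
  n <- nrow(top)
  xyz <- matrix(runif(n * 3, 0, spread), n, 3L)
  # put each hydrogen near a plausible donor so D-H bonds exist
  hyd <- which(top$is_hydrogen)
  don <- which(!top$is_hydrogen & top$element %in% c("N", "O", "S"))
  for (h in hyd) {
    d <- don[sample.int(length(don), 1L)]
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    xyz[h, ] <- xyz[d, ] + dir * runif(1, 0.95, 1.05)
  }
  list(topology = tidytraj::assign_radii(top), xyz = xyz)
}

# ---- naive oracles (explicit loops, no shared code with the package) ----

oracle_angle <- function(a, b, c_) {
  u <- a - b; v <- c_ - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

oracle_hbonds <- function(top, xyz, sel1, sel2, da_max = 3.5, ang_min = 110,
                          dh_max = 1.2) {
  hits <- 0L
  n <- nrow(top)
  for (h in seq_len(n)) {
    if (!top$is_hydrogen[h]) next
    # nearest donor-element heavy atom within dh_max
    best <- NA_integer_; bestd <- Inf
    for (d in seq_len(n)) {
      if (top$is_hydrogen[d] || !(top$element[d] %in% c("N", "O", "S"))) next
      dd <- sqrt(sum((xyz[h, ] - xyz[d, ])^2))
      if (dd < bestd) { bestd <- dd; best <- d }
    }
    if (!is.finite(bestd) || bestd >= dh_max) next
    d <- best
    for (a in seq_len(n)) {
      if (a == d || top$is_hydrogen[a] || !(top$element[a] %in% c("N", "O"))) next
      cross <- (d %in% sel1 && a %in% sel2) || (d %in% sel2 && a %in% sel1)
      if (!cross) next
      if (top$resid[a] == top$resid[d] && top$chain[a] == top$chain[d]) next
      if (sqrt(sum((xyz[d, ] - xyz[a, ])^2)) >= da_max) next
      if (oracle_angle(xyz[d, ], xyz[h, ], xyz[a, ]) <= ang_min) next
      hits <- hits + 1L
    }
  }
  hits
}

oracle_salt_bridges <- function(top, xyz, sel1, sel2, cutoff = 4.0) {
  anion <- logical(nrow(top)); cation <- logical(nrow(top))
  for (i in seq_len(nrow(top))) {
    rn <- top$resname[i]; nm <- top$name[i]
    anion[i] <- top$element[i] == "O" &&
      ((rn == "ASP" && nm %in% c("OD1", "OD2")) ||
         (rn == "GLU" && nm %in% c("OE1", "OE2")))
    cation[i] <- top$element[i] == "N" &&
      ((rn == "LYS" && nm == "NZ") ||
         (rn == "ARG" && nm %in% c("NE", "NH1", "NH2")))
  }
  hits <- 0L
  for (i in which(anion)) {
    for (j in which(cation)) {
      cross <- (i %in% sel1 && j %in% sel2) || (i %in% sel2 && j %in% sel1)
      if (!cross) next
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff) hits <- hits + 1L
    }
  }
  hits
}

oracle_vdw <- function(top, xyz, sel1, sel2, slack = 0.5) {
  hits <- 0L
  pairs_seen <- character()
  for (i in sel1) {
    for (j in sel2) {
      if (i == j || top$is_hydrogen[i] || top$is_hydrogen[j]) next
      key <- paste(min(i, j), max(i, j))
      if (key %in% pairs_seen) next
      thr <- top$vdw_radius[i] + top$vdw_radius[j] + slack
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < thr) {
        hits <- hits + 1L
        pairs_seen <- c(pairs_seen, key)
      }
    }
  }
  hits
}

oracle_coordination <- function(top, xyz, ion, radius = 3.5) {
  res_seen <- character(); waters <- 0L
  for (i in seq_len(nrow(top))) {
    if (i == ion) next
    d <- sqrt(sum((xyz[i, ] - xyz[ion, ])^2))
    if (d >= radius) next
    if (top$is_water[i] && top$element[i] == "O") {
      waters <- waters + 1L
    } else if (toupper(top$resname[i]) %in% c(
      "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
      "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
    ) && !top$is_hydrogen[i]) {
      res_seen <- unique(c(res_seen, paste(top$chain[i], top$resid[i])))
    }
  }
  c(residues = length(res_seen), waters = waters)
}

# brute-force radius of gyration
oracle_rg <- function(xyz, w) {
  w <- w / sum(w)
  cm <- c(sum(xyz[, 1] * w), sum(xyz[, 2] * w), sum(xyz[, 3] * w))
  sqrt(sum(w * ((xyz[, 1] - cm[1])^2 + (xyz[, 2] - cm[2])^2 +
                  (xyz[, 3] - cm[3])^2)))
}
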