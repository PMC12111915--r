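#' Build a topology from an atom table
#'
#' A topology is a tibble with one row per atom (class `"topology"`) carrying
#' the columns `index` (1-based, contiguous), `name`, `element`, `resname`,
#' `resid` (as in the source file, PDB convention), `chain`, `mass` (amu),
#' `charge` (e, may be `NA`), `vdw_radius` (angstrom, may be `NA`), and the
#' derived flags `is_hydrogen`, `is_water`, `is_ion`.
#'
#' @param atoms Data frame with at least `name`, `resname`, `resid`; missing
#'   `element`, `chain`, `mass`, `charge`, `vdw_radius` are inferred or set
#'   to `NA`.
#' @param water,ions Residue-name sets used for the `is_water` / `is_ion`
#'   flags.
#' @return A `topology` tibble.
#' @export
#' @examples
#' top <- topology(data.frame(
#'   name = c("OH2", "H1", "H2"), resname = "HOH", resid = 1
#' ))
#' nrow(top)
topology <- function(atoms, water = water_resnames(), ions = ion_resnames()) {
  atoms <- as_tibble(atoms)
  n <- nrow(atoms)
  if (n == 0L) abort("empty input: topology needs at least one atom")
  if (!"element" %in% names(atoms)) atoms$element <- NA_character_
  atoms$element <- toupper(trimws(as.character(atoms$element)))
  blank <- is.na(atoms$element) | atoms$element == ""
  if (any(blank)) {
    atoms$element[blank] <- mapply(
      infer_element, atoms$name[blank], atoms$resname[blank],
      USE.NAMES = FALSE
    )
  }
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  atoms$chain[is.na(atoms$chain) | atoms$chain == ""] <- "A"
  if (!"mass" %in% names(atoms)) atoms$mass <- NA_real_
  need_mass <- is.na(atoms$mass)
  if (any(need_mass)) {
    atoms$mass[need_mass] <- unname(element_masses()[atoms$element[need_mass]])
  }
  if (anyNA(atoms$mass)) {
    bad <- unique(atoms$element[is.na(atoms$mass)])
    abort(paste0("no mass known for element(s): ", paste(bad, collapse = ", ")))
  }
  if (!"charge" %in% names(atoms)) atoms$charge <- NA_real_
  if (!"vdw_radius" %in% names(atoms)) atoms$vdw_radius <- NA_real_
  # hydrogen by element, with a name-starts-with-H fallback for blank elements
  atoms$is_hydrogen <- atoms$element == "H" |
    (atoms$element == "" & grepl("^[0-9]*H", toupper(atoms$name)))
  atoms$is_water <- toupper(atoms$resname) %in% toupper(water)
  atoms$is_ion <- toupper(atoms$resname) %in% toupper(ions) & !atoms$is_water
  atoms$index <- seq_len(n)
  atoms$resid <- as.integer(atoms$resid)
  cols <- c(
    "index", "name", "element", "resname", "resid", "chain", "mass",
    "charge", "vdw_radius", "is_hydrogen", "is_water", "is_ion"
  )
  atoms <- atoms[, c(cols, setdiff(names(atoms), cols))]
  validate_topology(new_topology(atoms))
}

new_topology <- function(x) {
  class(x) <- c("topology", class(tibble()))
  x
}

validate_topology <- function(top) {
  stopifnot(is.data.frame(top))
  if (!identical(top$index, seq_len(nrow(top)))) {
    abort("topology atom indices must be 1..N and contiguous")
  }
  if (any(top$mass <= 0)) abort("atom masses must be > 0")
  r <- top$vdw_radius
  if (any(!is.na(r) & r <= 0)) abort("vdw radii must be > 0 when present")
  # residue spans must partition the atom list: a residue never reappears
  key <- residue_key(top)
  runs <- rle(key)
  if (anyDuplicated(runs$values)) {
    abort("residue spans must be contiguous: a residue reappears after an interruption")
  }
  top
}

residue_key <- function(top) paste(top$chain, top$resid, top$resname, sep = "\r")

#' Residue table of a topology
#'
#' @param top A `topology`.
#' @return Tibble with one row per residue: `resid`, `resname`, `chain`,
#'   and the atom-index span `first`, `last`.
#' @export
topology_residues <- function(top) {
  key <- residue_key(top)
  runs <- rle(key)
  last <- cumsum(runs$lengths)
  first <- last - runs$lengths + 1L
  tibble(
    resid = top$resid[first],
    resname = top$resname[first],
    chain = top$chain[first],
    first = first,
    last = last
  )
}

#' @export
print.topology <- function(x, ...) {
  res <- topology_residues(x)
  cat(sprintf(
    "# topology: %d atoms, %d residues, %d chain(s)\n",
    nrow(x), nrow(res), length(unique(x$chain))
  ))
  NextMethod()
}

#' Assign van der Waals radii from an element table
#'
#' Populates `vdw_radius` for every atom from a named element-to-radius map
#' (Bondi radii by default). Radii already present (for instance read from a
#' PQR file) are kept unless `override = TRUE`.
#'
#' @param top A `topology`.
#' @param table Named numeric vector, element symbol to radius in angstrom.
#' @param override Replace pre-populated radii? Default `FALSE`.
#' @return The topology with `vdw_radius` filled for all atoms.
#' @export
#' @examples
#' top <- topology(data.frame(name = "CA", element = "C",
#'                            resname = "ALA", resid = 1))
#' assign_radii(top)$vdw_radius  # 1.70
assign_radii <- function(top, table = bondi_radii(), override = FALSE) {
  names(table) <- toupper(names(table))
  fill <- if (override) rep(TRUE, nrow(top)) else is.na(top$vdw_radius)
  el <- top$element[fill]
  unknown <- !(el %in% names(table))
  if (any(unknown)) {
    bad <- top[fill, ][unknown, ]
    abort(paste0(
      "no van der Waals radius for element(s) ",
      paste(unique(el[unknown]), collapse = ", "),
      " (atoms ", paste(head(bad$index, 10L), collapse = ", "),
      if (nrow(bad) > 10L) ", ..." else "", ")"
    ))
  }
  top$vdw_radius[fill] <- unname(table[el])
  top
}

#' Named residue-range domain map
#'
#' Inclusive residue ranges naming protein domains. The default is the
#' three-domain architecture of PLC-zeta: the EF-hand pair region (residues
#' 35-145), the X-Y catalytic domain (155-465) and the C2 domain (466-589).
#' Residues outside every range belong to no domain and are excluded from
#' per-domain metrics.
#'
#' @param ... Named length-2 integer vectors `c(low, high)`; omit to get the
#'   default map.
#' @return Tibble with columns `domain`, `from`, `to`.
#' @export
#' @examples
#' domain_map()
#' domain_map(core = c(10, 50), tail = c(51, 80))
domain_map <- function(...) {
  ranges <- list(...)
  if (length(ranges) == 0L) {
    ranges <- list(`EF-hands` = c(35L, 145L), XY = c(155L, 465L),
                   C2 = c(466L, 589L))
  }
  if (is.null(names(ranges)) || any(names(ranges) == "")) {
    abort("every domain range must be named")
  }
  dm <- tibble(
    domain = names(ranges),
    from = vapply(ranges, function(r) as.integer(r[1L]), integer(1)),
    to = vapply(ranges, function(r) as.integer(r[2L]), integer(1))
  )
  if (any(dm$from > dm$to)) abort("domain ranges need from <= to")
  dm2 <- dm[order(dm$from), ]
  if (nrow(dm2) > 1L && any(dm2$from[-1L] <= dm2$to[-nrow(dm2)])) {
    abort("domain ranges must not overlap")
  }
  dm
}
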