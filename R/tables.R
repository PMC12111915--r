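# Reference tables: element masses, Bondi van der Waals radii, residue sets.
# Radii are the Bondi (1964) compilation with the common extensions for
# metals used in biomolecular work; masses are standard atomic weights.

#' Bondi van der Waals radii
#'
#' Default element-to-radius table (in angstrom) used by [assign_radii()].
#'
#' @return Named numeric vector, names are element symbols.
#' @export
#' @examples
#' bondi_radii()[["C"]]  # 1.70
bondi_radii <- function() {
  c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
    S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, HE = 1.40, NE = 1.54,
    AR = 1.88, "NA" = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39,
    FE = 1.40, MN = 1.39, CU = 1.40, SI = 2.10, B = 1.92, SE = 1.90
  )
}

element_masses <- function() {
  c(
    H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
    P = 30.974, S = 32.06, CL = 35.45, BR = 79.904, I = 126.904,
    "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
    FE = 55.845, MN = 54.938, CU = 63.546, SE = 78.971, SI = 28.085,
    B = 10.81, HE = 4.003, NE = 20.180, AR = 39.948
  )
}

# Standard amino-acid residue names (incl. common protonation variants).
protein_resnames <- function() {
  c(
    "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
    "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
    "TYR", "VAL", "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "ASH",
    "GLH", "LYN", "CYX", "CYM"
  )
}

#' Default water and ion residue-name sets
#'
#' Water molecules are recognised by residue name; ions by residue name or
#' element. Both sets can be overridden in [load_structure()].
#'
#' @name solvent_sets
#' @return Character vectors of residue names.
#' @export
water_resnames <- function() c("HOH", "WAT", "TIP3", "SOL", "TP3", "SPC")

#' @rdname solvent_sets
#' @export
ion_resnames <- function() {
  c("CA", "NA", "CL", "K", "MG", "ZN", "MN", "FE", "CU", "CAL", "SOD",
    "CLA", "POT", "MG2", "CA2")
}

backbone_names <- function() c("N", "CA", "C", "O")

# Infer element symbol from a PDB atom name when the element column is blank.
# Leading digits are stripped (e.g. "1HB" -> hydrogen); two-letter symbols are
# only accepted for names that cannot be a hydrogen/carbon/etc. ambiguity.
infer_element <- function(name, resname) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  if (nchar(nm) == 0L) return("")
  first <- substr(nm, 1L, 1L)
  two <- substr(nm, 1L, 2L)
  ions <- c("NA", "CL", "MG", "CA", "ZN", "FE", "MN", "CU", "BR")
  if (toupper(resname) %in% ion_resnames() && two %in% ions) return(two)
  if (toupper(resname) %in% ion_resnames() && first %in% c("K", "F", "I")) {
    return(first)
  }
  if (grepl("^[0-9]", name)) return(substr(gsub("^[0-9]+", "", toupper(name)), 1L, 1L))
  first
}
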