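# Trajectory container: a topology plus a time-ordered coordinate array.
# Coordinates are stored as an array [frame, atom, xyz] in angstrom; an
# optional parallel "unwrapped" array keeps displacements continuous across
# periodic boundaries (displacement analyses read unwrapped coordinates,
# distance analyses read wrapped ones).

#' Construct a trajectory
#'
#' @param topology A [topology()].
#' @param coords Either an array `[n_frames, n_atoms, 3]` or a matrix
#'   `[n_frames, 3 * n_atoms]` (x1,y1,z1,x2,...) of coordinates in angstrom.
#' @param dt Frame spacing in ns; frame times are `(k - 1) * dt`.
#' @param box Orthorhombic box edge lengths, numeric length 3 (angstrom), or
#'   `NULL` for a non-periodic system.
#' @param ucoords Optional unwrapped coordinates, same shape as `coords`.
#' @return A `trajectory` object.
#' @export
trajectory <- function(topology, coords, dt, box = NULL, ucoords = NULL) {
  coords <- as_coord_array(coords)
  n <- nrow(topology)
  if (dim(coords)[2L] != n) {
    abort(sprintf(
      "shape error: trajectory has %d atoms per frame but topology has %d",
      dim(coords)[2L], n
    ))
  }
  if (dim(coords)[1L] < 1L) abort("empty input: trajectory has zero frames")
  if (!is.null(ucoords)) {
    ucoords <- as_coord_array(ucoords)
    stopifnot(identical(dim(ucoords), dim(coords)))
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
      abort("box must be three positive orthorhombic edge lengths")
    }
  }
  if (!is.numeric(dt) || dt <= 0) abort("dt must be a positive time step (ns)")
  structure(
    list(
      topology = topology, coords = coords, ucoords = ucoords,
      box = box, dt = dt, times = (seq_len(dim(coords)[1L]) - 1) * dt
    ),
    class = "trajectory"
  )
}

as_coord_array <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) %% 3L != 0L) abort("coordinate matrix must have 3N columns")
    n <- ncol(x) %/% 3L
    a <- array(NA_real_, c(nrow(x), n, 3L))
    for (k in 1:3) a[, , k] <- x[, seq(k, ncol(x), by = 3L), drop = FALSE]
    a
  } else if (is.array(x) && length(dim(x)) == 3L && dim(x)[3L] == 3L) {
    x
  } else {
    abort("coords must be a [frames, atoms, 3] array or a [frames, 3N] matrix")
  }
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "# trajectory: %d frames x %d atoms, dt = %g ns (%g ns total)%s%s\n",
    n_frames(x), n_atoms(x), x$dt, max(x$times),
    if (is.null(x$box)) "" else
      sprintf(", box %.4g x %.4g x %.4g A", x$box[1], x$box[2], x$box[3]),
    if (is.null(x$ucoords)) "" else ", unwrapped coords kept"
  ))
  invisible(x)
}

#' Trajectory dimensions and frame access
#'
#' @param traj A `trajectory`.
#' @param i Frame index (1-based).
#' @param unwrapped Return unwrapped coordinates when available?
#' @return `n_frames()`/`n_atoms()` return counts; `frame_coords()` returns
#'   an `n_atoms x 3` coordinate matrix for one frame.
#' @name trajectory-access
#' @export
n_frames <- function(traj) dim(traj$coords)[1L]

#' @rdname trajectory-access
#' @export
n_atoms <- function(traj) dim(traj$coords)[2L]

#' @rdname trajectory-access
#' @export
frame_coords <- function(traj, i, unwrapped = FALSE) {
  if (i < 1L || i > n_frames(traj)) {
    abort(sprintf("frame index %d out of range 1..%d", i, n_frames(traj)))
  }
  src <- if (unwrapped && !is.null(traj$ucoords)) traj$ucoords else traj$coords
  m <- src[i, , , drop = FALSE]
  dim(m) <- dim(src)[2:3]
  m
}

# coordinates of a selection across all frames -> array [frames, |sel|, 3]
sel_coords <- function(traj, sel, unwrapped = FALSE) {
  src <- if (unwrapped && !is.null(traj$ucoords)) traj$ucoords else traj$coords
  src[, as.integer(sel), , drop = FALSE]
}

#' Read a structure file (PDB or PQR)
#'
#' Parses a PDB or PQR file into a topology and a single coordinate frame.
#' PQR files populate per-atom `charge` and `vdw_radius`. An orthorhombic
#' CRYST1 record becomes the box; a triclinic one raises an
#' unsupported-feature error.
#'
#' @param path File path; format from extension unless `format` given.
#' @param format `"auto"`, `"pdb"` or `"pqr"`.
#' @param water,ions Residue-name sets for solvent/ion flags, see
#'   [topology()].
#' @return List with elements `topology`, `coords` (N x 3 matrix, angstrom)
#'   and `box` (edge lengths or `NULL`).
#' @export
load_structure <- function(path, format = c("auto", "pdb", "pqr"),
                           water = water_resnames(), ions = ion_resnames()) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pqr$", path, ignore.case = TRUE)) "pqr" else "pdb"
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  validate_structure_lines(lines, path, format)
  box <- parse_cryst1(lines, path)
  if (format == "pqr") {
    pdb <- bio3d::read.pqr(path)
  } else {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
  }
  at <- pdb$atom
  atoms <- tibble(
    name = trimws(at$elety),
    element = if (format == "pqr") NA_character_ else trimws(at$elesy),
    resname = trimws(at$resid),
    resid = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    charge = if (format == "pqr") at$o else NA_real_,
    vdw_radius = if (format == "pqr") at$b else NA_real_
  )
  top <- topology(atoms, water = water, ions = ions)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3L, byrow = TRUE)
  list(topology = top, coords = xyz, box = box)
}

# Light well-formedness scan so malformed records fail with a line number
# before the parser sees them.
validate_structure_lines <- function(lines, path, format) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) abort(paste0("empty input: no ATOM/HETATM records in ", path))
  idx <- which(rec)
  if (format == "pdb") {
    bad_len <- idx[nchar(lines[idx]) < 54L]
    if (length(bad_len)) {
      abort(sprintf("parse error in %s, line %d: ATOM record shorter than the coordinate fields",
                    path, bad_len[1L]))
    }
    xyz_txt <- substr(lines[idx], 31L, 54L)
    coords <- suppressWarnings(cbind(
      as.numeric(substr(xyz_txt, 1L, 8L)),
      as.numeric(substr(xyz_txt, 9L, 16L)),
      as.numeric(substr(xyz_txt, 17L, 24L))
    ))
    bad <- idx[rowSums(is.na(coords)) > 0L]
    if (length(bad)) {
      abort(sprintf("parse error in %s, line %d: non-numeric coordinate field",
                    path, bad[1L]))
    }
    # duplicate atom serials within one model violate the format
    model_breaks <- grepl("^MODEL|^ENDMDL", lines)
    model_id <- cumsum(model_breaks)[idx]
    serial <- trimws(substr(lines[idx], 7L, 11L))
    if (anyDuplicated(paste(model_id, serial))) {
      d <- idx[duplicated(paste(model_id, serial))][1L]
      abort(sprintf("parse error in %s, line %d: duplicate atom serial number",
                    path, d))
    }
  } else {
    fields <- strsplit(trimws(lines[idx]), "\\s+")
    nf <- lengths(fields)
    bad <- idx[nf < 10L]
    if (length(bad)) {
      abort(sprintf("parse error in %s, line %d: PQR record needs 10+ whitespace-separated fields",
                    path, bad[1L]))
    }
  }
  invisible(TRUE)
}

parse_cryst1 <- function(lines, path) {
  cl <- lines[grepl("^CRYST1", lines)]
  if (length(cl) == 0L) return(NULL)
  f <- suppressWarnings(as.numeric(c(
    substr(cl[1L], 7L, 15L), substr(cl[1L], 16L, 24L), substr(cl[1L], 25L, 33L),
    substr(cl[1L], 34L, 40L), substr(cl[1L], 41L, 47L), substr(cl[1L], 48L, 54L)
  )))
  if (anyNA(f)) abort(paste0("parse error in ", path, ": malformed CRYST1 record"))
  if (any(abs(f[4:6] - 90) > 1e-6)) {
    abort("unsupported feature: triclinic boxes are not handled (orthorhombic only)")
  }
  if (all(f[1:3] == 1)) return(NULL)  # placeholder unit cell
  f[1:3]
}

#' Read a trajectory file against a topology
#'
#' Supports DCD and multi-model PDB. XTC is not readable in this toolchain
#' and raises an explicit unsupported-format error. Frame times are set to
#' `(k - 1) * dt`; the frame-saving interval is not recorded in either
#' format, so `dt` is a required input.
#'
#' @param path DCD or multi-model PDB file.
#' @param topology Topology the frames must match.
#' @param dt Frame spacing in ns.
#' @param box Optional orthorhombic box lengths; for PDB input a CRYST1
#'   record takes precedence.
#' @param format `"auto"`, `"dcd"` or `"pdb"`.
#' @return A [trajectory()].
#' @export
load_trajectory <- function(path, topology, dt,
                            box = NULL, format = c("auto", "dcd", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (ext == "xtc") {
      abort("unsupported format: XTC reading is not available; supply DCD or multi-model PDB")
    }
    format <- if (ext == "dcd") "dcd" else "pdb"
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    validate_structure_lines(lines, path, "pdb")
    cbox <- parse_cryst1(lines, path)
    if (!is.null(cbox)) box <- cbox
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  }
  if (nrow(xyz) == 0L) abort(paste0("empty input: no frames in ", path))
  if (ncol(xyz) != 3L * nrow(topology)) {
    abort(sprintf(
      "shape error: %s has %d atoms per frame, topology has %d",
      path, ncol(xyz) %/% 3L, nrow(topology)
    ))
  }
  trajectory(topology, xyz, dt = dt, box = box)
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, with a CRYST1 record when the
#' trajectory has a box. Coordinates are written at the format's native
#' 0.001 angstrom precision.
#'
#' @param traj A `trajectory`.
#' @param path Output file.
#' @param unwrapped Write unwrapped coordinates when available?
#' @return `path`, invisibly.
#' @export
write_models_pdb <- function(traj, path, unwrapped = FALSE) {
  top <- traj$topology
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(traj$box)) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      traj$box[1], traj$box[2], traj$box[3], 90, 90, 90
    ), con)
  }
  hetatm <- !(toupper(top$resname) %in% protein_resnames())
  rectag <- ifelse(hetatm, "HETATM", "ATOM  ")
  name4 <- ifelse(
    nchar(top$name) >= 4L, substr(top$name, 1L, 4L),
    ifelse(nchar(top$element) == 2L,
           formatC(top$name, width = -4L),
           paste0(" ", formatC(top$name, width = -3L)))
  )
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    m <- frame_coords(traj, i, unwrapped = unwrapped)
    writeLines(sprintf(
      "%s%5d %-4s%4s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rectag, (top$index - 1L) %% 99999L + 1L, name4,
      substr(top$resname, 1L, 4L), substr(top$chain, 1L, 1L),
      top$resid %% 10000L, m[, 1L], m[, 2L], m[, 3L], 1, 0, top$element
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Restrict a trajectory to a selection
#'
#' @param traj A `trajectory`.
#' @param sel A [select_atoms()] selection (or integer indices).
#' @return A `trajectory` over the selected atoms only.
#' @export
subset_trajectory <- function(traj, sel) {
  idx <- as.integer(sel)
  top <- topology(as_tibble(traj$topology)[idx, setdiff(names(traj$topology), "index")])
  trajectory(
    top, traj$coords[, idx, , drop = FALSE], dt = traj$dt, box = traj$box,
    ucoords = if (is.null(traj$ucoords)) NULL else
      traj$ucoords[, idx, , drop = FALSE]
  )
}
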