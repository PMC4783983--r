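#' @importFrom stats sd var setNames
#' @importFrom utils head tail read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Static chemistry tables.
#
# Donor/acceptor assignment is by atom name, not force-field typing: N/O
# heavy atoms that commonly carry a polar hydrogen are donors, N/O atoms
# with lone pairs are acceptors. Water oxygen (OW / O of HOH) is both.
# ---------------------------------------------------------------------------

.donor_names <- c("N", "NE", "NH1", "NH2", "ND1", "NE2", "ND2", "NZ",
                  "NE1", "OG", "OG1", "OH", "OW")
.acceptor_names <- c("O", "OXT", "OD1", "OD2", "OE1", "OE2", "OG", "OG1",
                     "OH", "ND1", "NE2", "OW")

# Bondi van der Waals radii (Angstrom) keyed by element.
.vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
                CA = 2.31, "NA" = 2.27, CL = 1.75, K = 2.75, MG = 1.73,
                ZN = 1.39, "F" = 1.47, BR = 1.85)

.mass_table <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 P = 30.974, CA = 40.078, "NA" = 22.990, CL = 35.45,
                 K = 39.098, MG = 24.305, ZN = 65.38, "F" = 18.998,
                 BR = 79.904)

.mainchain_names <- c("N", "H", "H1", "H2", "H3", "CA", "HA", "HA1", "HA2",
                      "C", "O", "OXT")

.solvent_resnames <- c("HOH", "SOL", "WAT", "TIP", "TIP3", "TIP4", "SPC")
.ion_resnames <- c("NA", "CL", "K", "MG", "ZN", "CA", "NA+", "CL-", "CAL",
                   "SOD", "CLA")

# Guess the element from a PDB atom name when the element column is absent.
guess_element <- function(name, resname) {
  nm <- toupper(trimws(name))
  if (toupper(trimws(resname)) %in% .ion_resnames && nm %in%
      names(.vdw_table)) {
    return(nm)
  }
  nm <- sub("^[0-9]+", "", nm)
  first <- substr(nm, 1L, 1L)
  if (first %in% c("H", "C", "N", "O", "S", "P", "F")) first else "C"
}

# ---------------------------------------------------------------------------
# System construction
# ---------------------------------------------------------------------------

#' Build a molecular system from an atom table and reference coordinates
#'
#' A `sd_system` bundles the atom metadata every analysis module needs:
#' solute/solvent partition, mainchain flags, hydrogen-bond donor/acceptor
#' roles, attached hydrogens, van der Waals radii and masses, plus the
#' reference (starting-structure) coordinates in Angstrom. Most users will
#' obtain one from [parse_structure()] or a synthetic generator rather than
#' calling this directly.
#'
#' @param atoms Data frame with one row per atom. Required columns: `name`,
#'   `resname`, `resid` (1-based residue index), `chain`. Optional columns
#'   (`element`, `is_solute`, `is_mainchain`, `is_hydrogen`, `vdw_radius`,
#'   `mass`, `donor`, `acceptor`) are filled from the name tables when
#'   absent.
#' @param reference N x 3 matrix of reference coordinates (Angstrom).
#' @param native_pairs Optional 2-column integer matrix of native-contact
#'   atom pairs; usually built later by [build_native_pairs()].
#' @return An object of class `sd_system`.
#' @export
sd_system <- function(atoms, reference, native_pairs = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  reference <- as.matrix(reference)
  if (nrow(reference) != nrow(atoms) || ncol(reference) != 3L) {
    stop("reference coordinates must be an N x 3 matrix matching the atom count")
  }
  n <- nrow(atoms)
  atoms$name <- toupper(trimws(as.character(atoms$name)))
  atoms$resname <- toupper(trimws(as.character(atoms$resname)))
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$element)) {
    atoms$element <- mapply(guess_element, atoms$name, atoms$resname)
  }
  atoms$element <- toupper(atoms$element)
  if (is.null(atoms$is_hydrogen)) atoms$is_hydrogen <- atoms$element == "H"
  if (is.null(atoms$is_solute)) {
    is_water <- atoms$resname %in% .solvent_resnames
    is_ion <- atoms$resname %in% .ion_resnames
    atoms$is_solute <- !(is_water | is_ion)
  }
  if (is.null(atoms$is_mainchain)) {
    atoms$is_mainchain <- atoms$is_solute & atoms$name %in% .mainchain_names
  }
  atoms$is_mainchain <- atoms$is_mainchain & atoms$is_solute
  if (is.null(atoms$vdw_radius)) {
    atoms$vdw_radius <- unname(.vdw_table[atoms$element])
    atoms$vdw_radius[is.na(atoms$vdw_radius)] <- 1.70
  }
  if (is.null(atoms$mass)) {
    atoms$mass <- unname(.mass_table[atoms$element])
    atoms$mass[is.na(atoms$mass)] <- 12.011
  }
  if (is.null(atoms$donor)) {
    atoms$donor <- !atoms$is_hydrogen & atoms$name %in% .donor_names
    # proline backbone nitrogen carries no hydrogen
    atoms$donor[atoms$name == "N" & atoms$resname == "PRO"] <- FALSE
  }
  if (is.null(atoms$acceptor)) {
    atoms$acceptor <- !atoms$is_hydrogen & atoms$name %in% .acceptor_names
  }
  rownames(atoms) <- NULL
  sys <- structure(list(atoms = atoms, reference = reference,
                        native_pairs = native_pairs),
                   class = "sd_system")
  sys$h_attached <- attach_hydrogens(sys)
  sys
}

# Assign each hydrogen to the nearest heavy N/O atom of the same residue
# within 1.25 A in the reference coordinates. Returns a list (one integer
# vector per atom) of attached hydrogen indices.
attach_hydrogens <- function(sys) {
  at <- sys$atoms
  n <- nrow(at)
  out <- vector("list", n)
  h_idx <- which(at$is_hydrogen)
  heavy_no <- which(!at$is_hydrogen & at$element %in% c("N", "O"))
  if (length(h_idx) && length(heavy_no)) {
    for (h in h_idx) {
      cand <- heavy_no[at$resid[heavy_no] == at$resid[h]]
      if (!length(cand)) next
      d2 <- dist2_point(sys$reference[h, ], sys$reference[cand, , drop = FALSE])
      j <- cand[which.min(d2)]
      if (min(d2) <= 1.25^2) out[[j]] <- c(out[[j]], h)
    }
  }
  out
}

#' @export
print.sd_system <- function(x, ...) {
  at <- x$atoms
  cat(sprintf("sd_system: %d atoms, %d residues (%d solute atoms, %d solvent/ion)\n",
              nrow(at), length(unique(at$resid)), sum(at$is_solute),
              sum(!at$is_solute)))
  invisible(x)
}

#' Number of atoms in a system
#' @param sys An `sd_system`.
#' @return Integer atom count.
#' @export
n_atoms <- function(sys) nrow(sys$atoms)

# ---------------------------------------------------------------------------
# PDB I/O (via bio3d)
# ---------------------------------------------------------------------------

#' Parse a PDB structure into a system
#'
#' Reads ATOM/HETATM records in file order, keeping the first alternate
#' location. Water residues (HOH/SOL/WAT/...) and monoatomic ions are
#' flagged as non-solute; mainchain, hydrogen-bond donor and acceptor flags
#' come from static atom-name tables documented in the source.
#'
#' @param pdb_text A single string, character vector of lines, or a path to
#'   a PDB file.
#' @return An [sd_system()].
#' @seealso [write_structure()], [read_trajectory_pdb()]
#' @export
parse_structure <- function(pdb_text) {
  path <- as_pdb_path(pdb_text)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty input: no ATOM/HETATM records found")
  # validate coordinate fields up front so we can name the offending line
  for (i in which(is_atom)) {
    flds <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
              substr(lines[i], 47, 54))
    vals <- suppressWarnings(as.numeric(flds))
    if (anyNA(vals)) {
      stop(sprintf("malformed coordinate field on line %d: '%s'", i, lines[i]))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  build_system_from_bio3d(pdb)
}

as_pdb_path <- function(pdb_text) {
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) &&
      file.exists(pdb_text)) {
    return(pdb_text)
  }
  lines <- if (length(pdb_text) == 1L) strsplit(pdb_text, "\n")[[1]] else pdb_text
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

build_system_from_bio3d <- function(pdb) {
  a <- pdb$atom
  # keep first altloc only
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop("empty input: no atoms after altloc filtering")
  res_key <- paste(a$chain, a$resno, a$insert, sep = "|")
  resid <- as.integer(factor(res_key, levels = unique(res_key)))
  atoms <- data.frame(
    name = a$elety, resname = a$resid, resid = resid,
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    resno_orig = a$resno, insert = ifelse(is.na(a$insert), "", a$insert),
    stringsAsFactors = FALSE)
  ele <- a$elesy
  if (!is.null(ele) && !all(is.na(ele) | trimws(ele) == "")) {
    atoms$element <- toupper(trimws(ele))
    miss <- is.na(atoms$element) | atoms$element == ""
    if (any(miss)) {
      atoms$element[miss] <- mapply(guess_element, atoms$name[miss],
                                    atoms$resname[miss])
    }
  }
  reference <- cbind(a$x, a$y, a$z)
  sd_system(atoms, reference)
}

#' Write a system to PDB text
#'
#' @param sys An `sd_system`.
#' @param path Output file; if `NULL` the PDB text is returned invisibly as
#'   a character vector.
#' @param coords Optional N x 3 coordinates to write instead of the
#'   reference coordinates.
#' @return The path (or the lines, if `path` is `NULL`), invisibly.
#' @export
write_structure <- function(sys, path = NULL, coords = NULL) {
  at <- sys$atoms
  if (is.null(coords)) coords <- sys$reference
  ret_lines <- is.null(path)
  if (ret_lines) path <- tempfile(fileext = ".pdb")
  resno <- if (!is.null(at$resno_orig)) at$resno_orig else at$resid
  type <- ifelse(at$is_solute, "ATOM", "HETATM")
  bio3d::write.pdb(file = path, xyz = mat_to_xyz(coords),
                   type = type, eleno = seq_len(nrow(at)), elety = at$name,
                   resid = at$resname, chain = at$chain, resno = resno,
                   elesy = at$element)
  if (ret_lines) {
    out <- readLines(path, warn = FALSE)
    unlink(path)
    return(invisible(out))
  }
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL block becomes one frame; frame times are assigned on a
#' uniform grid of `dt_ps`.
#'
#' @param pdb_text String/lines/path as in [parse_structure()].
#' @param dt_ps Frame spacing in ps (default 10, a common save interval).
#' @return An [sd_trajectory()].
#' @export
read_trajectory_pdb <- function(pdb_text, dt_ps = 10) {
  path <- as_pdb_path(pdb_text)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sys <- build_system_from_bio3d(pdb)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  f <- nrow(xyz)
  sd_trajectory(sys, xyz, times = dt_ps * seq_len(f))
}
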