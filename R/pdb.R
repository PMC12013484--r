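#' Read atom records from a PDB file
#'
#' Parses the ATOM/HETATM records of a PDB file into a data frame of atom
#' records. Parsing is done by [bio3d::read.pdb()]; on top of it this
#' function resolves alternate-location duplicates (the highest-occupancy
#' conformer wins, ties going to the alphabetically first altloc) and, by
#' default, drops hydrogen atoms, which are rarely resolved in X-ray
#' structures. Only the first model of multi-model files is read.
#'
#' @param path path to a PDB file.
#' @param keep_hydrogens keep hydrogen atoms? Default `FALSE`.
#' @return a data frame with one row per atom and columns `serial`,
#'   `name`, `resname`, `chain`, `resseq`, `x`, `y`, `z`, `hetero`
#'   (logical, HETATM origin), `occupancy`, `altloc`, `element`.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(paste0(
#'   "ATOM      1  CA  ALA A   1       1.000   2.000   3.000",
#'   "  1.00  0.00           C"), pdb)
#' read_pdb(pdb)
#' @export
read_pdb <- function(path, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("not a parsable PDB file: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L)
    stop("no ATOM/HETATM records found in ", path)
  atoms <- data.frame(
    serial    = as.integer(a$eleno),
    name      = trimws(a$elety),
    resname   = trimws(a$resid),
    chain     = ifelse(is.na(a$chain), "", as.character(a$chain)),
    resseq    = as.integer(a$resno),
    x = a$x, y = a$y, z = a$z,
    hetero    = a$type == "HETATM",
    occupancy = ifelse(is.na(a$o), 1, a$o),
    altloc    = ifelse(is.na(a$alt), "", as.character(a$alt)),
    element   = ifelse(is.na(a$elesy), "", trimws(a$elesy)),
    stringsAsFactors = FALSE)
  atoms <- resolve_altloc(atoms)
  if (!keep_hydrogens) {
    elem <- toupper(atoms$element)
    is_h <- elem %in% c("H", "D") |
      (elem == "" & grepl("^[0-9]*H", toupper(atoms$name)))
    atoms <- atoms[!is_h, , drop = FALSE]
  }
  if (nrow(atoms) == 0L) stop("no atoms left after filtering in ", path)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  rownames(atoms) <- NULL
  atoms
}

# Keep a single conformer per (chain, resseq, resname, name): highest
# occupancy; ties resolved by altloc sort order ('' and 'A' first).
resolve_altloc <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  key <- paste(atoms$chain, atoms$resseq, atoms$resname, atoms$name, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  keep <- !duplicated(key[ord])
  sel <- sort(ord[keep])             # restore original file order
  atoms[sel, , drop = FALSE]
}

#' Write atom records to a PDB file
#'
#' Writes fixed-column PDB v3.3 ATOM/HETATM records (coordinates at the
#' format's native 0.001 A precision), followed by `END`.
#'
#' @param atoms atom-record data frame as returned by [read_pdb()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  if (nrow(atoms) == 0L) stop("cannot write an empty atom set")
  name4 <- ifelse(nchar(atoms$name) >= 4L, substr(atoms$name, 1, 4),
                  sprintf(" %-3s", atoms$name))
  lines <- sprintf(
    "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(atoms$hetero, "HETATM", "ATOM"),
    atoms$serial %% 100000L, name4, "", atoms$resname,
    substr(paste0(atoms$chain, " "), 1, 1), atoms$resseq %% 10000L, "",
    atoms$x, atoms$y, atoms$z, atoms$occupancy, 0,
    atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Convert atom records to a point cloud
#'
#' @param atoms atom-record data frame ([read_pdb()]).
#' @param selection either `NULL` (all atoms), a logical vector over rows,
#'   or a predicate `function(atoms) -> logical`.
#' @return a [mol_cloud()] whose points are the selected atoms' positions,
#'   in input order, carrying the selected atom records.
#' @export
structure_to_pointcloud <- function(atoms, selection = NULL) {
  if (nrow(atoms) == 0L) stop("`atoms` is empty")
  keep <- if (is.null(selection)) rep(TRUE, nrow(atoms))
          else if (is.function(selection)) selection(atoms)
          else as.logical(selection)
  if (length(keep) != nrow(atoms))
    stop("selection length does not match the number of atoms")
  sel <- atoms[which(keep), , drop = FALSE]
  if (nrow(sel) == 0L) stop("selection matched no atoms (empty cloud)")
  mol_cloud(cbind(sel$x, sel$y, sel$z), atoms = sel)
}

# Residue names treated as solvent/ions rather than as a bound ligand.
.non_ligand_resnames <- c(
  "HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE",
  "CU", "NI", "CO", "CD", "HG", "IOD", "BR", "SO4", "PO4", "NO3", "ACT")

#' Select biologically relevant ligand atoms
#'
#' HETATM records excluding water and common ions/buffer components, or a
#' single named ligand when `resname` is given.
#'
#' @param atoms atom-record data frame.
#' @param resname optional residue name of the ligand to select.
#' @param exclude residue names never treated as ligand (default: waters
#'   and common ions).
#' @return logical selector over `atoms` rows.
#' @export
ligand_selector <- function(atoms, resname = NULL,
                            exclude = .non_ligand_resnames) {
  if (!is.null(resname)) return(atoms$resname %in% resname)
  atoms$hetero & !(atoms$resname %in% exclude)
}

#' Extract the ligand-defined binding pocket
#'
#' The pocket is the set of protein atoms whose distance to the nearest
#' ligand atom is at most `radius` (boundary inclusive). The conventional
#' pocket definition uses a 5 A shell around the bound ligand.
#'
#' @param protein_atoms atom-record data frame of the protein.
#' @param ligand_atoms atom-record data frame of the ligand.
#' @param radius shell radius in Angstrom (default 5).
#' @return a [mol_cloud()] of the pocket atoms (possibly empty, with a
#'   warning, when no protein atom lies within `radius`).
#' @export
extract_pocket <- function(protein_atoms, ligand_atoms, radius = 5.0) {
  if (nrow(protein_atoms) == 0L || nrow(ligand_atoms) == 0L)
    stop("protein and ligand atom sets must be nonempty")
  if (radius < 0) stop("`radius` must be nonnegative")
  P <- cbind(protein_atoms$x, protein_atoms$y, protein_atoms$z)
  L <- cbind(ligand_atoms$x, ligand_atoms$y, ligand_atoms$z)
  mind <- sqrt(apply(cross_dist2(P, L), 1L, min))
  keep <- mind <= radius
  if (!any(keep)) {
    warning("no protein atom within ", radius, " A of the ligand; ",
            "returning an empty pocket")
    return(mol_cloud(matrix(numeric(0), ncol = 3L),
                     atoms = protein_atoms[0, , drop = FALSE]))
  }
  sel <- protein_atoms[keep, , drop = FALSE]
  mol_cloud(cbind(sel$x, sel$y, sel$z), atoms = sel)
}
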