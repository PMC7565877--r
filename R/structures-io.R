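#' Bondi van der Waals radii
#'
#' Element-to-radius table (Angstrom) used to assign per-atom van der Waals
#' radii when reading structures. Values are the Bondi (1964) set for the
#' elements common in protein/nucleic systems, plus the divalent and
#' monovalent ions that occur in solvated polymerase systems.
#'
#' @param overrides named numeric vector of per-element overrides
#'   (names are element symbols, values radii in Angstrom).
#' @return named numeric vector mapping element symbol to radius (Angstrom).
#' @export
#' @examples
#' bondi_radii()[["C"]]   # 1.70
#' bondi_radii(c(P = 1.90))[["P"]]
bondi_radii <- function(overrides = NULL) {
  r <- c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
    MG = 1.73, "NA" = 2.27, K = 2.75, ZN = 1.39, CA = 2.31, FE = 1.94,
    MN = 2.05, SE = 1.90
  )
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)))
    r[toupper(names(overrides))] <- unname(overrides)
  }
  r
}

new_molecular_structure <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("atom_id", "element", "atom_name", "residue_name",
                "residue_number", "subunit_id", "x", "y", "z", "vdw_radius")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("missing structure columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$atom_id))
    stop("atom_id values must be unique")
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("all coordinates must be finite")
  if (!all(df$vdw_radius > 0))
    stop("all vdw radii must be positive")
  class(df) <- c("MolecularStructure", "data.frame")
  df
}

#' Construct a molecular structure from atom records
#'
#' The package's geometry substrate: a data frame of atoms with coordinates,
#' residue/subunit identity, and van der Waals radii. Most users obtain one
#' via [read_pdb_structure()] or [make_channel_phantom()].
#'
#' @param atom_id integer atom serial numbers (unique).
#' @param element element symbols.
#' @param atom_name PDB atom names.
#' @param residue_name residue names (e.g. "ALA", "CTP").
#' @param residue_number integer author residue numbers.
#' @param subunit_id chain/subunit identifiers.
#' @param xyz numeric matrix of coordinates, n x 3, Angstrom.
#' @param vdw_radius per-atom radii (Angstrom), or NULL to assign from
#'   `radius_table` by element.
#' @param radius_table element-to-radius mapping, see [bondi_radii()].
#' @param default_radius radius assigned (with a warning) to elements not in
#'   the table.
#' @return a `MolecularStructure` (data frame subclass).
#' @export
molecular_structure <- function(atom_id, element, atom_name, residue_name,
                                residue_number, subunit_id, xyz,
                                vdw_radius = NULL,
                                radius_table = bondi_radii(),
                                default_radius = 1.5) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L)
  n <- nrow(xyz)
  element <- toupper(as.character(element))
  if (is.null(vdw_radius)) {
    vdw_radius <- unname(radius_table[element])
    unknown <- is.na(vdw_radius)
    if (any(unknown)) {
      warning("unknown element(s) ",
              paste(unique(element[unknown]), collapse = ", "),
              "; using default radius ", default_radius, " A")
      vdw_radius[unknown] <- default_radius
    }
  }
  new_molecular_structure(data.frame(
    atom_id = as.integer(atom_id),
    element = element,
    atom_name = as.character(atom_name),
    residue_name = as.character(residue_name),
    residue_number = as.integer(residue_number),
    subunit_id = as.character(subunit_id),
    x = unname(xyz[, 1]), y = unname(xyz[, 2]), z = unname(xyz[, 3]),
    vdw_radius = unname(as.numeric(vdw_radius)),
    stringsAsFactors = FALSE
  ))
}

#' @export
print.MolecularStructure <- function(x, ...) {
  cat(sprintf("MolecularStructure: %d atoms, %d subunit(s), %d residue(s)\n",
              nrow(x), length(unique(x$subunit_id)),
              nrow(unique(x[, c("subunit_id", "residue_number")]))))
  invisible(x)
}

#' Coordinates of a structure as a matrix
#' @param structure a `MolecularStructure`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(structure) {
  cbind(structure$x, structure$y, structure$z, deparse.level = 0)
}

# Parse the fixed-width columns of one block of ATOM/HETATM lines.
parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- grepl("^ATOM|^HETATM", rec)
  lines <- lines[keep]
  if (length(lines) == 0L) return(NULL)
  field <- function(a, b) trimws(substr(lines, a, b))
  element <- field(77, 78)
  # fall back to the atom-name convention when the element column is absent
  name <- field(13, 16)
  noel <- element == ""
  if (any(noel)) {
    guess <- sub("^[0-9']*", "", name[noel])
    guess <- toupper(substr(guess, 1, 1))
    element[noel] <- guess
  }
  data.frame(
    atom_id = as.integer(field(7, 11)),
    element = toupper(element),
    atom_name = name,
    residue_name = field(18, 20),
    residue_number = as.integer(field(23, 26)),
    subunit_id = field(22, 22),
    x = as.numeric(field(31, 38)),
    y = as.numeric(field(39, 46)),
    z = as.numeric(field(47, 54)),
    stringsAsFactors = FALSE
  )
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records of a PDB file (first MODEL only) and assigns
#' van der Waals radii by element. Residue numbering is taken verbatim from
#' the file (author numbering); no renumbering is performed. Unknown
#' elements receive `default_radius` with a warning.
#'
#' @param path path to a PDB file.
#' @param radius_table element-to-radius mapping, default [bondi_radii()].
#' @param default_radius fallback radius (Angstrom) for unknown elements.
#' @return a `MolecularStructure`.
#' @export
read_pdb_structure <- function(path, radius_table = bondi_radii(),
                               default_radius = 1.5) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1] - 1L)]
  df <- parse_pdb_atoms(lines)
  if (is.null(df) || nrow(df) == 0L)
    stop("no ATOM/HETATM records parsed from ", path, " (empty structure)")
  molecular_structure(df$atom_id, df$element, df$atom_name, df$residue_name,
                      df$residue_number, df$subunit_id,
                      as.matrix(df[, c("x", "y", "z")]),
                      radius_table = radius_table,
                      default_radius = default_radius)
}

#' Write a structure to a PDB file
#'
#' Coordinates are written at the PDB format's fixed precision (3 decimal
#' places), so a read/write round trip reproduces coordinates to 1e-3 A.
#'
#' @param structure a `MolecularStructure`.
#' @param path output path.
#' @param frames optional list of n x 3 coordinate matrices; when supplied a
#'   multi-model PDB is written (one MODEL per frame) and the structure's
#'   own coordinates are ignored.
#' @return `path`, invisibly.
#' @export
write_pdb_structure <- function(structure, path, frames = NULL) {
  fmt_block <- function(xyz) {
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            structure$atom_id,
            substr(structure$atom_name, 1, 4),
            substr(structure$residue_name, 1, 3),
            substr(structure$subunit_id, 1, 1),
            structure$residue_number,
            xyz[, 1], xyz[, 2], xyz[, 3],
            substr(structure$element, 1, 2))
  }
  if (is.null(frames)) {
    out <- c(fmt_block(coords(structure)), "END")
  } else {
    out <- unlist(lapply(seq_along(frames), function(i) {
      c(sprintf("MODEL     %4d", i), fmt_block(frames[[i]]), "ENDMDL")
    }))
    out <- c(out, "END")
  }
  writeLines(out, path)
  invisible(path)
}

#' Residue selection
#'
#' A selection is a list of (subunit, residue numbers) entries, mirroring
#' the field convention of naming residue ranges per subunit (e.g. RPB1
#' 1100-1110).
#'
#' @param ... named arguments: each name is a subunit identifier and each
#'   value an integer vector of residue numbers.
#' @param entries alternatively, a list of `list(subunit_id=, residue_numbers=)`.
#' @return a `ResidueSelection`.
#' @export
#' @examples
#' residue_selection(A = 1:10, B = c(5, 7))
residue_selection <- function(..., entries = NULL) {
  if (is.null(entries)) {
    args <- list(...)
    if (length(args) == 0L || is.null(names(args)) || any(names(args) == ""))
      stop("supply named subunit = residues arguments or `entries`")
    entries <- lapply(names(args), function(nm)
      list(subunit_id = nm, residue_numbers = as.integer(args[[nm]])))
  }
  for (e in entries)
    if (length(e$residue_numbers) == 0L)
      stop("each selection entry needs a non-empty residue number set")
  structure(list(entries = entries), class = "ResidueSelection")
}

#' Resolve a residue selection into atom indices
#'
#' Returns the (sorted, unique) row indices of atoms whose
#' (subunit, residue number) pair is named by the selection. An empty result
#' is allowed but warned about.
#'
#' @param structure a `MolecularStructure`.
#' @param sel a `ResidueSelection`.
#' @param heavy_only drop hydrogens before matching.
#' @param quiet suppress the empty-selection warning.
#' @return integer vector of atom row indices.
#' @export
resolve_selection <- function(structure, sel, heavy_only = FALSE,
                              quiet = FALSE) {
  stopifnot(inherits(sel, "ResidueSelection"), nrow(structure) > 0L)
  idx <- integer(0)
  for (e in sel$entries) {
    hit <- structure$subunit_id == e$subunit_id &
      structure$residue_number %in% e$residue_numbers
    idx <- c(idx, which(hit))
  }
  idx <- sort(unique(idx))
  if (heavy_only) idx <- idx[structure$element[idx] != "H"]
  if (length(idx) == 0L && !quiet)
    warning("selection matched no atoms")
  idx
}

new_trajectory_window <- function(frames, frame_times, ligand_atom_groups,
                                  topology) {
  n_atoms <- nrow(frames[[1]])
  for (f in frames)
    if (nrow(f) != n_atoms) stop("all frames must have the same atom count")
  if (length(frame_times) != length(frames))
    stop("frame_times length must equal frame count")
  if (length(frame_times) > 1L && any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing")
  if (length(ligand_atom_groups) > 1L) {
    all_idx <- unlist(ligand_atom_groups)
    if (anyDuplicated(all_idx)) stop("ligand atom groups must be disjoint")
  }
  structure(list(frames = frames, frame_times = frame_times,
                 ligand_atom_groups = ligand_atom_groups,
                 topology = topology),
            class = "TrajectoryWindow")
}

#' @export
print.TrajectoryWindow <- function(x, ...) {
  cat(sprintf("TrajectoryWindow: %d frames x %d atoms, %d ligand group(s)\n",
              length(x$frames), nrow(x$frames[[1]]),
              length(x$ligand_atom_groups)))
  invisible(x)
}

#' Number of frames in a trajectory window
#' @param traj a `TrajectoryWindow`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Load a trajectory from multi-model PDB files
#'
#' Reads one or more multi-model PDB files into a `TrajectoryWindow` whose
#' frames are congruent with `topology`. Ligand atom groups are resolved
#' from `ligand_spec` (one group per matched residue instance) or, when
#' `ligand_spec` is NULL, from `ligand_resname`. Binary trajectory formats
#' (DCD/XTC) are not supported; convert to multi-model PDB upstream.
#'
#' @param paths character vector of multi-model PDB paths, in time order.
#' @param topology the `MolecularStructure` the frames correspond to.
#' @param ligand_spec optional `ResidueSelection` naming the ligand residues.
#' @param ligand_resname residue name identifying ligand molecules when
#'   `ligand_spec` is NULL (default "CTP").
#' @param frame_times optional numeric vector of times (ns); defaults to
#'   0, 1, 2, ... per frame.
#' @return a `TrajectoryWindow`.
#' @export
load_trajectory <- function(paths, topology, ligand_spec = NULL,
                            ligand_resname = "CTP", frame_times = NULL) {
  frames <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("cannot read file: ", p)
    lines <- readLines(p, warn = FALSE)
    starts <- grep("^MODEL", lines)
    ends <- grep("^ENDMDL", lines)
    blocks <- if (length(starts) == 0L) list(lines) else
      mapply(function(a, b) lines[a:b], starts, ends, SIMPLIFY = FALSE)
    for (b in blocks) {
      df <- parse_pdb_atoms(b)
      if (is.null(df)) next
      if (nrow(df) != nrow(topology))
        stop("frame atom count (", nrow(df),
             ") does not match topology (", nrow(topology), ")")
      frames[[length(frames) + 1L]] <- as.matrix(df[, c("x", "y", "z")])
    }
  }
  if (length(frames) == 0L) stop("no frames parsed")
  if (is.null(frame_times)) frame_times <- seq_along(frames) - 1
  groups <- resolve_ligand_groups(topology, ligand_spec, ligand_resname)
  new_trajectory_window(frames, frame_times, groups, topology)
}

# One atom-index group per ligand residue instance; ligand_resname = NA
# requests a ligand-free window.
resolve_ligand_groups <- function(topology, ligand_spec, ligand_resname) {
  if (is.null(ligand_spec) && length(ligand_resname) == 1L &&
        is.na(ligand_resname))
    return(list())
  if (!is.null(ligand_spec)) {
    idx <- resolve_selection(topology, ligand_spec, quiet = TRUE)
  } else {
    idx <- which(topology$residue_name == ligand_resname)
  }
  if (length(idx) == 0L)
    stop("no ligand atoms matched (selection error)")
  key <- paste(topology$subunit_id[idx], topology$residue_number[idx])
  unname(split(idx, factor(key, levels = unique(key))))
}

#' Build a trajectory window in memory
#'
#' @param frames list of n x 3 coordinate matrices.
#' @param topology a `MolecularStructure` with the same atom count.
#' @param frame_times numeric times (ns); default 0, 1, 2, ...
#' @param ligand_spec optional `ResidueSelection` for the ligand residues.
#' @param ligand_resname residue name used when `ligand_spec` is NULL;
#'   residues with this name form the ligand groups (may match none, in
#'   which case the window has zero ligand groups).
#' @return a `TrajectoryWindow`.
#' @export
trajectory_window <- function(frames, topology, frame_times = NULL,
                              ligand_spec = NULL, ligand_resname = "CTP") {
  if (is.null(frame_times)) frame_times <- seq_along(frames) - 1
  groups <- tryCatch(
    resolve_ligand_groups(topology, ligand_spec, ligand_resname),
    error = function(e) list())
  new_trajectory_window(frames, frame_times, groups, topology)
}
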