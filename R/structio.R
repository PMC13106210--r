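#' Structure, trajectory and table input/output
#'
#' Fixed-column PDB is the package's canonical structure format and
#' multi-model PDB its canonical trajectory format, so that every analysis
#' is exercisable from plain-text inputs. Interaction and energy tables are
#' headered CSV.
#'
#' @name structio
NULL

# ---- md_structure ----------------------------------------------------------

#' Construct a structure object from an atom table
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_name`, `res_id`, `chain`, `x`, `y`, `z`, optional `het` (logical,
#'   HETATM flag), optional `vdw_radius`, `mass` (filled from the element
#'   table when absent).
#' @return An object of class `md_structure`: a list with `atoms` (the atom
#'   table, augmented with `res_index`) and `residues` (one row per residue,
#'   columns `chain`, `res_id`, `res_name`).
#' @export
md_structure <- function(atoms) {
  req <- c("name", "res_name", "res_id", "chain", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$element)) {
    atoms$element <- vapply(seq_len(nrow(atoms)),
                            function(i) infer_element(atoms$name[i], atoms$het[i]),
                            character(1))
  }
  if (is.null(atoms$vdw_radius) || is.null(atoms$mass)) {
    props <- element_properties(atoms$element)
    if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- props$vdw
    if (is.null(atoms$mass)) atoms$mass <- props$mass
  }
  stopifnot(all(atoms$vdw_radius > 0), all(atoms$mass > 0))
  key <- paste(atoms$chain, atoms$res_id, atoms$res_name, sep = "\r")
  first <- !duplicated(key)
  residues <- data.frame(chain = atoms$chain[first], res_id = atoms$res_id[first],
                         res_name = atoms$res_name[first], stringsAsFactors = FALSE)
  atoms$res_index <- match(key, key[first])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, residues = residues), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat("md_structure:", nrow(x$atoms), "atoms,", nrow(x$residues), "residues,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Atom coordinates of a structure
#' @param x `md_structure`
#' @return n_atoms x 3 numeric matrix (Angstrom).
#' @export
coords <- function(x) {
  stopifnot(inherits(x, "md_structure"))
  cbind(x = x$atoms$x, y = x$atoms$y, z = x$atoms$z)
}

#' @noRd
set_coords <- function(x, xyz) {
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  x
}

#' @noRd
n_atoms <- function(x) nrow(x$atoms)

#' @noRd
n_residues <- function(x) nrow(x$residues)

# ---- PDB parsing -----------------------------------------------------------

#' @noRd
parse_pdb_atoms <- function(lines, path = "<pdb>") {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("no ATOM/HETATM records in ", path)
  icode <- trimws(substr(lines, 27, 27))
  if (any(icode != "")) {
    stop("insertion codes are not supported (line ",
         lineno[which(icode != "")[1]], " of ", path, ")")
  }
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) | trimws(s) == "")
    if (length(bad)) {
      stop("malformed ", what, " field at line ", lineno[bad[1]], " of ", path,
           ": '", trimws(s[bad[1]]), "'")
    }
    v
  }
  het <- substr(lines, 1, 6) == "HETATM"
  name <- trimws(substr(lines, 13, 16))
  elem <- trimws(substr(lines, 77, 78))
  no_elem <- elem == ""
  if (any(no_elem)) {
    elem[no_elem] <- vapply(which(no_elem),
                            function(i) infer_element(name[i], het[i]), character(1))
  }
  data.frame(
    serial   = as.integer(num(substr(lines, 7, 11), "serial")),
    name     = name,
    element  = toupper(elem),
    res_name = trimws(substr(lines, 18, 20)),
    res_id   = as.integer(num(substr(lines, 23, 26), "residue number")),
    chain    = ifelse(substr(lines, 22, 22) == " ", "A", substr(lines, 22, 22)),
    x        = num(substr(lines, 31, 38), "x coordinate"),
    y        = num(substr(lines, 39, 46), "y coordinate"),
    z        = num(substr(lines, 47, 54), "z coordinate"),
    het      = het,
    stringsAsFactors = FALSE
  )
}

#' Read a PDB file
#'
#' Parses ATOM and HETATM records of a fixed-column PDB file. For
#' multi-model files only the first model is read (use [read_trajectory()]
#' for the frame series). Van der Waals radii (Bondi set) and masses are
#' assigned from the element, inferring the element from the atom name when
#' columns 77-78 are blank. Insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @return `md_structure`. HETATM atoms carry `het = TRUE` in the atom table.
#' @seealso [write_pdb()], [read_trajectory()]
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  md_structure(parse_pdb_atoms(lines, path))
}

#' @noRd
format_pdb_atom_lines <- function(atoms) {
  name4 <- ifelse(nchar(atoms$name) >= 4L, sprintf("%-4s", atoms$name),
                  sprintf(" %-3s", atoms$name))
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(atoms$het, "HETATM", "ATOM"),
          atoms$serial %% 100000L, name4, atoms$res_name, atoms$chain,
          atoms$res_id, atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
}

#' Write a structure as a PDB file
#'
#' @param x `md_structure`
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "md_structure"))
  lines <- c(format_pdb_atom_lines(x$atoms), "END")
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write PDB to ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

# ---- md_trajectory ---------------------------------------------------------

#' Construct a trajectory object
#'
#' @param topology `md_structure` shared by all frames.
#' @param coord_array numeric array `n_frames x n_atoms x 3` (Angstrom).
#' @param timestep time between frames, ps.
#' @return Object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, coord_array, timestep = 1) {
  stopifnot(inherits(topology, "md_structure"))
  d <- dim(coord_array)
  if (length(d) != 3L || d[3] != 3L) stop("coord_array must be n_frames x n_atoms x 3")
  if (d[2] != n_atoms(topology)) {
    stop("coordinate array has ", d[2], " atoms but topology has ", n_atoms(topology))
  }
  if (d[1] < 1L) stop("trajectory needs at least one frame")
  structure(list(topology = topology, coords = coord_array, timestep = timestep),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", n_frames(x), "frames x", dim(x$coords)[2], "atoms,",
      "timestep", x$timestep, "ps\n")
  invisible(x)
}

#' Number of frames of a trajectory
#' @param traj `md_trajectory`
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj `md_trajectory`
#' @param i frame index (1-based).
#' @return n_atoms x 3 matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a trajectory
#'
#' Multi-model PDB is parsed natively: each MODEL block becomes a frame and
#' the first model supplies the topology unless `topology_path` is given.
#' A single-model PDB yields a one-frame trajectory.
#'
#' @param traj_path path to a (multi-model) PDB file.
#' @param topology_path optional path to a PDB providing the topology.
#' @param timestep ps between frames (metadata only).
#' @return `md_trajectory`.
#' @export
read_trajectory <- function(traj_path, topology_path = NULL, timestep = 1) {
  if (!file.exists(traj_path)) stop("file not found: ", traj_path)
  lines <- readLines(traj_path, warn = FALSE)
  starts <- which(substr(lines, 1, 5) == "MODEL")
  ends <- which(substr(lines, 1, 6) == "ENDMDL")
  blocks <- if (length(starts) == 0L) {
    list(lines)
  } else {
    if (length(starts) != length(ends)) stop("unbalanced MODEL/ENDMDL records in ", traj_path)
    lapply(seq_along(starts), function(k) lines[(starts[k] + 1L):(ends[k] - 1L)])
  }
  frames <- lapply(seq_along(blocks), function(k) parse_pdb_atoms(blocks[[k]], traj_path))
  topo <- if (is.null(topology_path)) md_structure(frames[[1]]) else read_pdb(topology_path)
  na <- n_atoms(topo)
  arr <- array(NA_real_, dim = c(length(frames), na, 3L))
  for (k in seq_along(frames)) {
    if (nrow(frames[[k]]) != na) {
      stop("frame ", k, " has ", nrow(frames[[k]]), " atoms but topology has ", na)
    }
    arr[k, , ] <- cbind(frames[[k]]$x, frames[[k]]$y, frames[[k]]$z)
  }
  md_trajectory(topo, arr, timestep = timestep)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj `md_trajectory`
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  atoms <- traj$topology$atoms
  out <- vector("list", n_frames(traj))
  for (k in seq_len(n_frames(traj))) {
    a <- atoms
    xyz <- frame_coords(traj, k)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    out[[k]] <- c(sprintf("MODEL     %4d", k), format_pdb_atom_lines(a), "ENDMDL")
  }
  writeLines(c(unlist(out), "END"), path)
  invisible(path)
}

# ---- selection -------------------------------------------------------------

#' Select atoms of a structure
#'
#' Named selections: `"calpha"` (CA atoms of non-HET residues), `"backbone"`
#' (N, CA, C, O of non-HET residues), `"heavy"` (all non-hydrogen),
#' `"protein"` (non-HET), `"hetero"` (HETATM), `"all"`. Alternatively a list
#' of predicates `name`, `res_id`, `res_name`, `chain`, `het`, each matched
#' by membership, combined with AND.
#'
#' @param x `md_structure` or `md_trajectory` (selection acts on the topology).
#' @param spec selection name or predicate list.
#' @param require_nonempty error (rather than return `integer(0)`) when the
#'   selection matches nothing.
#' @return Strictly increasing integer vector of atom indices.
#' @export
select_atoms <- function(x, spec = "all", require_nonempty = FALSE) {
  if (inherits(x, "md_trajectory")) x <- x$topology
  stopifnot(inherits(x, "md_structure"))
  a <- x$atoms
  keep <- if (is.character(spec) && length(spec) == 1L) {
    switch(spec,
      all      = rep(TRUE, nrow(a)),
      calpha   = a$name == "CA" & !a$het,
      backbone = a$name %in% c("N", "CA", "C", "O") & !a$het,
      heavy    = a$element != "H",
      protein  = !a$het,
      hetero   = a$het,
      stop("unknown named selection '", spec, "'")
    )
  } else if (is.list(spec)) {
    keep <- rep(TRUE, nrow(a))
    for (field in names(spec)) {
      if (!field %in% c("name", "res_id", "res_name", "chain", "het", "element")) {
        stop("unknown selection field '", field, "'")
      }
      keep <- keep & a[[field]] %in% spec[[field]]
    }
    keep
  } else {
    stop("spec must be a selection name or a predicate list")
  }
  idx <- which(keep)
  if (require_nonempty && length(idx) == 0L) {
    stop("selection matched no atoms (", deparse1(spec), ")")
  }
  idx
}

# ---- tables ----------------------------------------------------------------

.interaction_classes <- c("hbond", "ch_bond", "vdw", "pi", "alkyl", "other")

#' Read a docking interaction table
#'
#' CSV with header `ligand_id,chain,res_id,res_name,interaction_class`; one
#' row per (ligand, residue, interaction class), emulating per-ligand
#' interaction lists from docking post-analysis. Duplicate rows are dropped
#' with a warning.
#'
#' @param path CSV path.
#' @param n_ligands size of the ligand universe; defaults to the number of
#'   distinct `ligand_id` values present.
#' @return data.frame of class `interaction_table` with attribute `n_ligands`.
#' @export
read_interaction_table <- function(path, n_ligands = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("ligand_id", "chain", "res_id", "res_name", "interaction_class")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("interaction table is missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- !df$interaction_class %in% .interaction_classes
  if (any(bad)) stop("unknown interaction class(es): ",
                     paste(unique(df$interaction_class[bad]), collapse = ", "))
  as_interaction_table(df[req], n_ligands = n_ligands)
}

#' @noRd
as_interaction_table <- function(df, n_ligands = NULL) {
  dup <- duplicated(df[c("ligand_id", "chain", "res_id", "res_name", "interaction_class")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (ligand, residue, class) row(s) dropped", call. = FALSE)
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "n_ligands") <- if (is.null(n_ligands)) length(unique(df$ligand_id)) else n_ligands
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Read a per-residue energy decomposition table
#'
#' CSV with header `complex_id,chain,res_id,res_name,energy_kcal_mol`; one
#' row per (complex, residue), emulating per-residue binding free-energy
#' decomposition output (the producer is expected to have restricted
#' residues to the binding-site neighbourhood, e.g. within 4 Angstrom of
#' the ligand).
#'
#' @param path CSV path.
#' @return data.frame of class `energy_table`.
#' @export
read_energy_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("complex_id", "chain", "res_id", "res_name", "energy_kcal_mol")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("energy table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(df$energy_kcal_mol)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$energy_kcal_mol))))
    stop("non-numeric energy at row ", bad[1])
  }
  key <- paste(df$complex_id, df$chain, df$res_id, df$res_name)
  if (anyDuplicated(key)) {
    stop("energy table must have one row per (complex, residue); duplicate at row ",
         which(duplicated(key))[1])
  }
  rownames(df) <- NULL
  class(df) <- c("energy_table", "data.frame")
  df[req]
}
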