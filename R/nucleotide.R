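# Canonical nucleotide nomenclature (PDB chemical-component atom names) and
# the small-molecule ligand container used by grafting and validation.

# phosphate tail, from the terminal phosphate towards the ribose
TAIL_NTP <- c("PG", "O1G", "O2G", "O3G", "O3B", "PB", "O1B", "O2B",
              "O3A", "PA", "O1A", "O2A", "O5'")
TAIL_NDP <- c("PB", "O1B", "O2B", "O3B", "O3A", "PA", "O1A", "O2A", "O5'")
RIBOSE <- c("C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'")
PURINE_RING <- c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4")
PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")
BASE_ATOMS <- list(
  A = c(PURINE_RING, "N6"),
  G = c(PURINE_RING, "O6", "N2"),
  U = c(PYRIMIDINE_RING, "O2", "O4")
)

# bridging-imido analog codes seen in the reference crystals
ANALOG_PARENTS <- c(ANP = "ATP", GNP = "GTP", UNP = "UTP",
                    AN2 = "ADP", GN2 = "GDP", UN2 = "UDP")

#' Canonical atom-name roster for a nucleotide kind
#' @param kind one of `"ATP"`, `"ADP"`, `"GTP"`, `"GDP"`, `"UTP"`, `"UDP"`.
#' @return character vector of heavy-atom names.
#' @export
nucleotide_atom_names <- function(kind) {
  kind <- toupper(kind)
  base <- substr(kind, 1, 1)
  np <- if (substr(kind, 2, 3) == "TP") 3L else if (substr(kind, 2, 3) == "DP") 2L else
    stop("unknown nucleotide kind '", kind, "'", call. = FALSE)
  if (!base %in% names(BASE_ATOMS)) {
    stop("unknown nucleotide kind '", kind, "'", call. = FALSE)
  }
  c(if (np == 3L) TAIL_NTP else TAIL_NDP, RIBOSE, BASE_ATOMS[[base]])
}

#' Nucleotide ligand container
#'
#' Wraps a single small-molecule residue with canonical nucleotide atom
#' nomenclature: phosphate tail (PA/PB/PG with their oxygens), ribose
#' (C1'-C5', O2'-O5'), and a purine or pyrimidine base. Non-hydrolyzable
#' imido analogs are recognized by their bridging nitrogen (N3B for
#' beta,gamma-imido triphosphates, N3A for alpha,beta-imido diphosphates).
#'
#' @param atoms data.frame with columns `name`, `element`, `x`, `y`, `z`
#'   (and optionally `serial`).
#' @param comp_id component code (e.g. `"ATP"`, `"ANP"`, `"GDP"`).
#' @return an object of class `nucleotide` with fields `comp_id`, `atoms`,
#'   `analog_bridge` (`NA` or the bridging-nitrogen atom name), `base_type`
#'   (`"purine"` or `"pyrimidine"`) and `n_phosphate`.
#' @export
nucleotide <- function(atoms, comp_id) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  atoms$name <- trimws(atoms$name)
  nm <- atoms$name
  if (anyDuplicated(nm)) {
    stop("duplicate atom names in ligand: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  n_phos <- sum(toupper(atoms$element) == "P")
  if (!n_phos %in% 2:3) {
    stop("unrecognized nucleotide scaffold: expected 2 or 3 phosphorus ",
         "atoms, found ", n_phos, call. = FALSE)
  }
  base_type <- if (all(c("N9", "C8", "N7") %in% nm)) "purine"
  else if (all(c("N1", "C2", "N3", "C4", "C5", "C6") %in% nm)) "pyrimidine"
  else stop("unrecognized nucleotide scaffold: no purine or pyrimidine ",
            "ring atoms found", call. = FALSE)
  if (!"C1'" %in% nm) {
    stop("unrecognized nucleotide scaffold: missing ribose C1'", call. = FALSE)
  }
  bridge <- NA_character_
  if ("N3B" %in% nm && toupper(atoms$element[nm == "N3B"]) == "N") bridge <- "N3B"
  if ("N3A" %in% nm && toupper(atoms$element[nm == "N3A"]) == "N") bridge <- "N3A"
  glyc_n <- if (base_type == "purine") "N9" else "N1"
  d <- sqrt(sum((as.numeric(atoms[nm == "C1'", c("x", "y", "z")]) -
                   as.numeric(atoms[nm == glyc_n, c("x", "y", "z")]))^2))
  if (d < 1.2 || d > 1.8) {
    stop("glycosidic bond C1'-", glyc_n, " not present (distance ",
         sprintf("%.2f", d), " A)", call. = FALSE)
  }
  rownames(atoms) <- NULL
  structure(list(comp_id = toupper(comp_id), atoms = atoms,
                 analog_bridge = bridge, base_type = base_type,
                 n_phosphate = n_phos),
            class = "nucleotide")
}

#' @export
print.nucleotide <- function(x, ...) {
  cat(sprintf("nucleotide %s: %d heavy atoms, %d phosphates, %s base%s\n",
              x$comp_id, sum(toupper(x$atoms$element) != "H"),
              x$n_phosphate, x$base_type,
              if (!is.na(x$analog_bridge))
                paste0(", imido analog (", x$analog_bridge, ")") else ""))
  invisible(x)
}

#' Coordinates of named ligand atoms
#' @param ligand a [nucleotide()].
#' @param names atom names (default: all atoms).
#' @return matrix with one row per requested atom, rownames = atom names.
#' @export
ligand_coords <- function(ligand, names = NULL) {
  a <- ligand$atoms
  if (is.null(names)) names <- a$name
  idx <- match(names, a$name)
  if (anyNA(idx)) {
    stop("ligand ", ligand$comp_id, " is missing atoms: ",
         paste(names[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(a[idx, c("x", "y", "z")])
  rownames(m) <- names
  m
}

#' Extract a small-molecule component from a structure
#'
#' Resolves `sel` to exactly one non-water, non-polymer residue and returns
#' it as a [nucleotide()], with imido-analog bridging nitrogens detected
#' from atom names and elements.
#'
#' @param structure a [structure3d()].
#' @param sel a [selector()] (e.g. `selector(resname = "ANP")`).
#' @return a [nucleotide()].
#' @export
extract_component <- function(structure, sel) {
  sub <- select_atoms(structure, sel)
  if (n_atoms(sub) == 0) stop("selector matched no atoms", call. = FALSE)
  res <- split_residues(sub)
  if (length(res) != 1) {
    stop("selector must resolve to exactly one residue; matched ",
         length(res), call. = FALSE)
  }
  r <- res[[1]]
  if (r$category[1] %in% c("water", "metal", "polymer")) {
    stop("selected residue ", r$resname[1],
         " is not a small-molecule ligand (category: ", r$category[1], ")",
         call. = FALSE)
  }
  nucleotide(data.frame(name = r$atom, element = r$element,
                        x = r$x, y = r$y, z = r$z, serial = r$serial,
                        stringsAsFactors = FALSE),
             comp_id = r$resname[1])
}

#' Map corresponding atoms between two nucleotides
#'
#' Builds the name-correspondence used by [substrate_rmsd()]. `all_common`
#' is the intersection of heavy-atom names (phosphate tail, ribose, and the
#' base atoms the two components share); `phosphate_ribose` restricts to the
#' phosphate tail plus ribose; `nucleobase` to the ring atoms the bases
#' share. The ordering is deterministic (canonical roster order).
#'
#' @param lig_a,lig_b [nucleotide()] objects.
#' @param subset `"all_common"`, `"phosphate_ribose"`, or `"nucleobase"`.
#' @return an `atom_map`: data.frame with columns `a` and `b` plus a
#'   `subset` attribute.
#' @export
map_common_atoms <- function(lig_a, lig_b,
                             subset = c("all_common", "phosphate_ribose",
                                        "nucleobase")) {
  subset <- match.arg(subset)
  heavy <- function(l) l$atoms$name[toupper(l$atoms$element) != "H"]
  common <- intersect(heavy(lig_a), heavy(lig_b))
  pr <- c(TAIL_NTP, "N3B", "N3A", RIBOSE)
  ring <- union(PURINE_RING, PYRIMIDINE_RING)
  keep <- switch(subset,
                 all_common = common,
                 phosphate_ribose = intersect(common, pr),
                 nucleobase = intersect(common, ring))
  # canonical ordering: tail, ribose, then ring
  master <- unique(c(TAIL_NTP, "N3B", "N3A", RIBOSE, PURINE_RING,
                     PYRIMIDINE_RING, unlist(BASE_ATOMS)))
  keep <- keep[order(match(keep, master), keep)]
  if (length(keep) == 0) {
    stop("no common atoms between ", lig_a$comp_id, " and ", lig_b$comp_id,
         " for subset '", subset, "'", call. = FALSE)
  }
  out <- data.frame(a = keep, b = keep, stringsAsFactors = FALSE)
  attr(out, "subset") <- subset
  class(out) <- c("atom_map", "data.frame")
  out
}

#' Substrate RMSD in a common frame
#'
#' Plain coordinate RMSD over mapped atoms with no refitting: both ligands
#' must already sit in a common frame (their parent proteins having been
#' superposed first), so the value measures substrate displacement within
#' the protein-aligned frame.
#'
#' @param lig_a,lig_b [nucleotide()] objects in a common frame.
#' @param atom_map an atom map from [map_common_atoms()].
#' @return RMSD in Angstrom.
#' @export
substrate_rmsd <- function(lig_a, lig_b, atom_map = map_common_atoms(lig_a, lig_b)) {
  stopifnot(inherits(atom_map, "atom_map"), nrow(atom_map) > 0)
  coord_rmsd(ligand_coords(lig_a, atom_map$a), ligand_coords(lig_b, atom_map$b))
}

#' Apply a rigid transform to a nucleotide
#' @param ligand a [nucleotide()].
#' @param tf a [rigid_transform()].
#' @return the transformed [nucleotide()].
#' @export
transform_ligand <- function(ligand, tf) {
  ligand$atoms[, c("x", "y", "z")] <-
    transform_coords(as.matrix(ligand$atoms[, c("x", "y", "z")]), tf)
  ligand
}

#' Render a nucleotide as a one-residue structure
#' @param ligand a [nucleotide()].
#' @param chain chain identifier for the new residue.
#' @param resno residue number.
#' @return a [structure3d()].
#' @export
nucleotide_to_structure <- function(ligand, chain = "X", resno = 1L) {
  a <- ligand$atoms
  structure3d(data.frame(serial = seq_len(nrow(a)), atom = a$name,
                         altloc = "", resname = ligand$comp_id,
                         chain = chain, resno = resno, icode = "",
                         x = a$x, y = a$y, z = a$z, occ = 1, b = 0,
                         element = a$element, stringsAsFactors = FALSE),
              id = ligand$comp_id)
}
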