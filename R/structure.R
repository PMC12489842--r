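#' Macromolecular structure container
#'
#' A `structure3d` holds a flat atom table (one row per atom) with the
#' hierarchical keys chain / residue / atom, plus a per-residue category
#' (`polymer`, `ligand`, `water`, `metal`). It is the universal substrate of
#' every geometric operation in the package. Alternate conformers are
#' resolved at construction time: for each atom the conformer with the
#' highest occupancy is kept, ties broken by the lexicographically smallest
#' altloc, so downstream geometry is deterministic.
#'
#' @param atoms data.frame with columns `serial`, `atom` (atom name),
#'   `altloc`, `resname`, `chain`, `resno`, `icode`, `x`, `y`, `z`, `occ`,
#'   `b`, `element`. Missing bookkeeping columns are filled with defaults.
#' @param id free-text identifier.
#' @param source file path or accession tag the atoms came from.
#' @return an object of class `structure3d`.
#' @export
structure3d <- function(atoms, id = "struct", source = NA_character_) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("atom", "resname", "chain", "resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    stop("atom table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(atoms)
  if (n == 0) stop("structure must contain at least one atom", call. = FALSE)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$atom)
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  blank <- is.na(atoms$element) | atoms$element == ""
  if (any(blank)) atoms$element[blank] <- guess_element(atoms$atom[blank])
  atoms$chain[is.na(atoms$chain) | atoms$chain == ""] <- "A"
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates", call. = FALSE)
  }
  if (any(atoms$occ < 0 | atoms$occ > 1)) {
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  }
  atoms <- resolve_altlocs(atoms)
  atoms$category <- classify_residues(atoms)
  rownames(atoms) <- NULL
  structure(list(id = id, source = source, atoms = atoms),
            class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure3d '%s': %d atoms, %d residues, chains: %s\n",
              x$id, nrow(a),
              nrow(unique(a[, c("chain", "resno", "icode")])),
              paste(unique(a$chain), collapse = " ")))
  tab <- table(a$category[!duplicated(a[, c("chain", "resno", "icode")])])
  cat("  residues by category:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# One conformer per (chain, resno, icode, atom name): keep the highest
# occupancy, break ties by lexicographically smallest altloc.
resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$altloc)
  atoms <- atoms[ord, ]
  key <- key[ord]
  atoms <- atoms[!duplicated(key), ]
  atoms[order(atoms$serial), ]
}

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE", "SEC", "PYL")

WATER_CODES <- c("HOH", "WAT", "DOD")

METAL_ELEMENTS <- c("LI", "NA", "K", "RB", "CS", "MG", "CA", "SR", "BA",
                    "MN", "FE", "CO", "NI", "CU", "ZN", "CD", "HG", "AL")

# Residue-level categories: waters by component code, metals as single-atom
# residues with a metallic element, standard amino acids as polymer,
# everything else as ligand.
classify_residues <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  n_per <- table(key)
  cat_one <- function(resname, elements, nres) {
    if (toupper(resname) %in% WATER_CODES) return("water")
    if (nres == 1 && toupper(elements[1]) %in% METAL_ELEMENTS) return("metal")
    if (toupper(resname) %in% STANDARD_AA) return("polymer")
    "ligand"
  }
  res_cat <- vapply(unique(key), function(k) {
    idx <- which(key == k)
    cat_one(atoms$resname[idx[1]], atoms$element[idx], length(idx))
  }, character(1))
  unname(res_cat[key])
}

# Element from a PDB atom name when the element column is absent: strip
# digits/primes, recognize two-letter elements, else first letter.
guess_element <- function(names) {
  two <- c("CL", "BR", "FE", "ZN", "MG", "CA", "NA", "MN", "CU", "NI", "CO",
           "SE", "CD", "HG", "SR", "BA", "LI", "AL")
  vapply(names, function(nm) {
    s <- gsub("[0-9'*\"]", "", toupper(trimws(nm)))
    if (nchar(s) >= 2 && substr(s, 1, 2) %in% two) return(substr(s, 1, 2))
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Atom coordinates as a matrix
#' @param structure a `structure3d`.
#' @return N x 3 numeric matrix.
#' @export
atom_coords <- function(structure) {
  stopifnot(inherits(structure, "structure3d"))
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param structure a `structure3d`.
#' @param xyz N x 3 matrix matching the atom table.
#' @return the modified `structure3d`.
#' @export
set_atom_coords <- function(structure, xyz) {
  stopifnot(inherits(structure, "structure3d"),
            nrow(xyz) == nrow(structure$atoms))
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}

#' Atom selection
#'
#' `selector()` describes a conjunction of filters; `select_atoms()` returns
#' a new structure containing exactly the atoms satisfying all of them. An
#' empty selector selects everything; an empty result is legal.
#'
#' @param chain chain identifiers to keep, or `NULL` for all.
#' @param resno residue numbers to keep (vector or range), or `NULL`.
#' @param resname residue component codes to keep, or `NULL`.
#' @param category residue categories to keep
#'   (`"polymer"`, `"ligand"`, `"water"`, `"metal"`), or `NULL`.
#' @param atom atom names to keep, or `NULL`.
#' @return `selector()` returns a `selector` object.
#' @examples
#' s <- make_toy_complex(fixture_spec(seed = 1))
#' waters <- select_atoms(s, selector(category = "water"))
#' @export
selector <- function(chain = NULL, resno = NULL, resname = NULL,
                     category = NULL, atom = NULL) {
  if (!is.null(category)) {
    category <- match.arg(category, c("polymer", "ligand", "water", "metal"),
                          several.ok = TRUE)
  }
  structure(list(chain = chain, resno = resno, resname = resname,
                 category = category, atom = atom), class = "selector")
}

#' @param structure a `structure3d`.
#' @param sel a [selector()].
#' @return `select_atoms()` returns a `structure3d` restricted to the
#'   matching atoms (the input is untouched). The result may have zero
#'   atoms, in which case `NULL` is never returned but the atom table is
#'   empty-guarded by the caller via [n_atoms()].
#' @rdname selector
#' @export
select_atoms <- function(structure, sel = selector()) {
  stopifnot(inherits(structure, "structure3d"), inherits(sel, "selector"))
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$resno)) keep <- keep & a$resno %in% sel$resno
  if (!is.null(sel$resname)) keep <- keep & toupper(a$resname) %in% toupper(sel$resname)
  if (!is.null(sel$category)) keep <- keep & a$category %in% sel$category
  if (!is.null(sel$atom)) keep <- keep & a$atom %in% sel$atom
  out <- structure
  out$atoms <- a[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Number of atoms in a structure
#' @param structure a `structure3d`.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Split an atom table into residues
#'
#' Returns a list of data.frames, one per residue, in file order.
#' @param structure a `structure3d`.
#' @keywords internal
#' @export
split_residues <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  split(a, factor(key, levels = unique(key)))
}

#' Polymer residues of one chain, in sequence order
#' @noRd
chain_polymer <- function(structure, chain) {
  a <- structure$atoms
  a <- a[a$chain == chain & a$category == "polymer", , drop = FALSE]
  if (nrow(a) == 0) {
    stop("chain '", chain, "' has no standard polymer residues", call. = FALSE)
  }
  key <- paste(a$resno, a$icode, sep = "\r")
  a[order(a$resno, a$icode, a$serial), , drop = FALSE]
}

#' Single metal cofactor of a structure
#'
#' Returns the one metal atom (as a one-row data.frame) of a structure,
#' erroring when none or several are present unless `required` is `FALSE`.
#' @param structure a `structure3d`.
#' @param required error when absent?
#' @export
get_cofactor <- function(structure, required = TRUE) {
  a <- structure$atoms[structure$atoms$category == "metal", , drop = FALSE]
  if (nrow(a) == 0) {
    if (required) stop("no metal cofactor found in structure", call. = FALSE)
    return(NULL)
  }
  if (nrow(a) > 1) {
    stop("multiple metal atoms found; select one first", call. = FALSE)
  }
  a
}

#' Merge two structures into one atom table
#' @noRd
combine_structures <- function(a, b) {
  cols <- c("serial", "atom", "altloc", "resname", "chain", "resno", "icode",
            "x", "y", "z", "occ", "b", "element")
  at <- rbind(a$atoms[, cols], b$atoms[, cols])
  at$serial <- seq_len(nrow(at))
  structure3d(at, id = a$id, source = a$source)
}
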