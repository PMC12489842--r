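#' Read a macromolecular structure file
#'
#' Reads PDB or mmCIF files into a [structure3d()]. Only the first model of
#' multi-model files is kept, alternate conformers are resolved to the
#' highest-occupancy copy (ties to the lexicographically smallest altloc),
#' and residues are categorized as polymer / ligand / water / metal.
#' Hydrogens, when present, are retained but excluded from RMSD and
#' distance computations elsewhere in the package.
#'
#' @param path path to the file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension).
#' @return a [structure3d()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     pdb = "pdb", ent = "pdb",
                     cif = "mmcif", mmcif = "mmcif",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format explicitly", call. = FALSE))
  }
  raw <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, verbose = FALSE)
    },
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("failed to parse ", format, " file '", path,
         "': no ATOM/HETATM records found", call. = FALSE)
  }
  # some mmCIF parsers keep the quoting of primed atom names ("O5'")
  unquote <- function(x) gsub("^\"(.*)\"$|^'(.*)'$", "\\1\\2", x)
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    atom = unquote(trimws(at$elety)),
    altloc = ifelse(is.na(at$alt), "", trimws(at$alt)),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", trimws(at$chain)),
    resno = as.integer(at$resno),
    icode = ifelse(is.na(at$insert), "", trimws(at$insert)),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    element = if (!is.null(at$elesy)) trimws(at$elesy) else NA_character_,
    stringsAsFactors = FALSE
  )
  structure3d(atoms, id = tools::file_path_sans_ext(basename(path)),
              source = path)
}

#' Write a structure to disk
#'
#' Writes PDB v3.3 (via bio3d) or a minimal mmCIF `atom_site` loop.
#' Coordinates round-trip through [read_structure()] to 0.001 Angstrom.
#'
#' @param structure a [structure3d()].
#' @param path output file path.
#' @param format `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = c("pdb", "mmcif")) {
  stopifnot(inherits(structure, "structure3d"))
  format <- match.arg(format)
  a <- structure$atoms
  if (nrow(a) == 0) stop("refusing to write an empty structure", call. = FALSE)
  if (any(nchar(a$atom) > 4)) {
    stop("atom name longer than the 4-character PDB field: ",
         paste(unique(a$atom[nchar(a$atom) > 4]), collapse = ", "),
         call. = FALSE)
  }
  if (format == "pdb") {
    xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
    bio3d::write.pdb(file = path,
                     xyz = xyz,
                     type = ifelse(a$category == "polymer", "ATOM", "HETATM"),
                     resno = a$resno,
                     resid = a$resname,
                     eleno = a$serial,
                     elety = a$atom,
                     chain = a$chain,
                     insert = ifelse(a$icode == "", NA, a$icode),
                     alt = ifelse(a$altloc == "", NA, a$altloc),
                     o = a$occ,
                     b = a$b,
                     elesy = a$element,
                     verbose = FALSE)
  } else {
    # canonical PDB-style atom_site loop (column order matters to parsers)
    hdr <- c(paste0("data_", gsub("[^A-Za-z0-9_]", "_", structure$id)),
             "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id",
                      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                      "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                      "auth_seq_id", "auth_comp_id", "auth_asym_id",
                      "auth_atom_id", "pdbx_PDB_model_num")))
    quote_cif <- function(x) ifelse(grepl("['\" ]", x), paste0('"', x, '"'), x)
    rows <- sprintf(paste("%-6s %d %s %s %s %s %s 1 %d %s",
                          "%.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1"),
                    ifelse(a$category == "polymer", "ATOM", "HETATM"),
                    a$serial, a$element, quote_cif(a$atom),
                    ifelse(a$altloc == "", ".", a$altloc),
                    a$resname, a$chain, a$resno,
                    ifelse(a$icode == "", "?", a$icode),
                    a$x, a$y, a$z, a$occ, a$b,
                    a$resno, a$resname, a$chain, quote_cif(a$atom))
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Fetch a reference structure from the PDB, with caching
#'
#' Downloads `<pdb_id>.pdb` into `cache_dir` on first use and reuses the
#' cached file afterwards (no repeat network access). When offline and the
#' entry is not cached, fails with an explicit error advising manual
#' placement of the file in the cache directory.
#'
#' @param pdb_id 4-character PDB accession, e.g. `"3CJA"`.
#' @param cache_dir directory for cached files. Defaults to the
#'   `SUBSTRATEGRAFT_CACHE` environment variable, or `~/.cache/substrategraft`.
#' @return a [structure3d()].
#' @export
fetch_reference <- function(pdb_id, cache_dir = default_cache_dir()) {
  if (!grepl("^[A-Za-z0-9]{4}$", pdb_id)) {
    stop("'", pdb_id, "' is not a 4-character PDB accession", call. = FALSE)
  }
  pdb_id <- toupper(pdb_id)
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(pdb_id, ".pdb"))
  if (!file.exists(dest)) {
    alt <- file.path(cache_dir, paste0(pdb_id, ".cif"))
    if (file.exists(alt)) return(read_structure(alt, "mmcif"))
    url <- paste0("https://files.rcsb.org/download/", pdb_id, ".pdb")
    ok <- tryCatch({
      utils::download.file(url, dest, quiet = TRUE, mode = "wb")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(dest) || file.size(dest) == 0) {
      unlink(dest)
      stop("could not download PDB entry ", pdb_id, " (offline?). ",
           "Place ", pdb_id, ".pdb (or .cif) manually in the cache ",
           "directory: ", cache_dir, call. = FALSE)
    }
  }
  read_structure(dest, "pdb")
}

#' @rdname fetch_reference
#' @export
default_cache_dir <- function() {
  env <- Sys.getenv("SUBSTRATEGRAFT_CACHE", unset = "")
  if (nzchar(env)) return(env)
  file.path(path.expand("~"), ".cache", "substrategraft")
}
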