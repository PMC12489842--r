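#' Convert a non-hydrolyzable imido analog to the true substrate
#'
#' Replaces the bridging imido nitrogen by the bridging oxygen of the true
#' nucleotide: exactly one atom record changes (N3B -> O3B for
#' beta,gamma-imido triphosphates, N3A -> O3A for alpha,beta-imido
#' diphosphates), in place, with every coordinate left bit-identical. The
#' component code is updated to the parent nucleotide.
#'
#' @param ligand a [nucleotide()] with `analog_bridge` set.
#' @return the converted [nucleotide()].
#' @export
analog_to_substrate <- function(ligand) {
  stopifnot(inherits(ligand, "nucleotide"))
  if (is.na(ligand$analog_bridge)) {
    stop("ligand ", ligand$comp_id, " carries no imido bridge; ",
         "refusing a silent no-op conversion", call. = FALSE)
  }
  br <- ligand$analog_bridge
  new_name <- sub("^N", "O", br)
  i <- which(ligand$atoms$name == br)
  ligand$atoms$name[i] <- new_name
  ligand$atoms$element[i] <- "O"
  ligand$comp_id <- parent_comp_id(ligand)
  ligand$analog_bridge <- NA_character_
  ligand
}

# parent nucleotide code for an analog: by lookup when known, else derived
# from the base chemistry and phosphate count
parent_comp_id <- function(ligand) {
  if (ligand$comp_id %in% names(ANALOG_PARENTS)) {
    return(unname(ANALOG_PARENTS[ligand$comp_id]))
  }
  nm <- ligand$atoms$name
  letter <- if (ligand$base_type == "purine") {
    if ("N6" %in% nm) "A" else "G"
  } else {
    if ("N4" %in% nm) "C" else "U"
  }
  paste0(letter, if (ligand$n_phosphate == 3) "TP" else "DP")
}

#' Build a hybrid diphosphate by fragment recombination
#'
#' Constructs GDP or UDP in the productive binding pose from two crystal
#' ligands: the nucleobase of a triphosphate donor (GTP or UTP) is rigid-fit
#' onto the base of a diphosphate tail donor (the ADP analog) by nucleobase
#' atom correspondence, and the output combines the tail donor's phosphate +
#' ribose coordinates (copied exactly) with the fitted base atoms. Both
#' fragments are therefore internally rigid; only their relative placement
#' comes from the fit.
#'
#' Purine-purine bases map through the nine shared ring atoms;
#' pyrimidine-to-purine uses the glycosidic-geometry-preserving triple
#' N1->N9, C2->C4, C6->C8 (plus C1' on both sides).
#'
#' @param base_donor [nucleotide()] providing the base (e.g. a GTP or UTP
#'   analog).
#' @param tail_donor [nucleotide()] providing ribose + phosphates (an ADP
#'   analog or ADP).
#' @param max_fit_rmsd reject the recombination when the base fit exceeds
#'   this RMSD over mapped atoms, Angstrom.
#' @return a [nucleotide()] with `comp_id` `"GDP"` or `"UDP"` (or the
#'   tail donor's own diphosphate for a self-hybrid).
#' @export
build_hybrid_diphosphate <- function(base_donor, tail_donor,
                                     max_fit_rmsd = 1.0) {
  stopifnot(inherits(base_donor, "nucleotide"),
            inherits(tail_donor, "nucleotide"))
  if (tail_donor$n_phosphate != 2) {
    stop("tail donor must be a diphosphate", call. = FALSE)
  }
  if (base_donor$base_type == "purine" && tail_donor$base_type == "purine") {
    map_a <- c(PURINE_RING, "C1'")
    map_b <- c(PURINE_RING, "C1'")
  } else if (base_donor$base_type == "pyrimidine" &&
             tail_donor$base_type == "purine") {
    map_a <- c("N1", "C2", "C6", "C1'")
    map_b <- c("N9", "C4", "C8", "C1'")
  } else {
    stop("unsupported base combination: ", base_donor$base_type, " base on ",
         tail_donor$base_type, " tail", call. = FALSE)
  }
  fit <- kabsch_fit(ligand_coords(base_donor, map_a),
                    ligand_coords(tail_donor, map_b))
  if (fit$rmsd > max_fit_rmsd) {
    stop(sprintf(paste0("nucleobase fit RMSD %.2f A exceeds %.2f A: bases ",
                        "too dissimilar for the stated mapping"),
                 fit$rmsd, max_fit_rmsd), call. = FALSE)
  }
  fitted_base <- transform_ligand(base_donor, fit$transform)
  base_set <- BASE_ATOMS[[substr(parent_comp_id(base_donor), 1, 1)]]
  tail_base_set <- BASE_ATOMS[[substr(parent_comp_id(tail_donor), 1, 1)]]
  tail_keep <- tail_donor$atoms[!tail_donor$atoms$name %in% tail_base_set, ,
                                drop = FALSE]
  base_keep <- fitted_base$atoms[fitted_base$atoms$name %in% base_set, ,
                                 drop = FALSE]
  out_atoms <- rbind(tail_keep, base_keep)
  out_atoms$serial <- seq_len(nrow(out_atoms))
  comp <- paste0(substr(parent_comp_id(base_donor), 1, 1), "DP")
  out <- nucleotide(out_atoms, comp)
  # the glycosidic-bond range is enforced by nucleotide(); re-check explicitly
  glyc_n <- if (out$base_type == "purine") "N9" else "N1"
  d <- vnorm(ligand_coords(out, "C1'") - ligand_coords(out, glyc_n))
  if (d < 1.2 || d > 1.8) {
    stop(sprintf("hybrid glycosidic bond C1'-%s out of range (%.2f A)",
                 glyc_n, d), call. = FALSE)
  }
  out
}

#' Select the conserved active-site waters around the cofactor
#'
#' Partitions the waters of a solved complex into the cofactor's first
#' hydration shell (all water oxygens within `shell_cutoff` of the metal;
#' four expected), the catalytic water (nearest non-shell water to the
#' terminal phosphorus on its leaving-group side, i.e. anti to the last
#' bridging atom), and the terminal water (nearest remaining water within
#' `terminal_cutoff` of the last phosphate group's oxygens). Selection is
#' deterministic: distance first, atom serial as tie-break. A shell with
#' fewer than four waters yields a result flagged incomplete, with a
#' warning, never a silent success.
#'
#' @param source [structure3d()] containing waters and the cofactor.
#' @param cofactor one-row atom data.frame (see [get_cofactor()]); taken
#'   from `source` when omitted.
#' @param substrate [nucleotide()] defining the phosphate tail.
#' @param shell_cutoff first-shell metal-oxygen cutoff, Angstrom.
#' @param terminal_cutoff cutoff around the terminal phosphate oxygens, Angstrom.
#' @return a `site_waters` object: list with data.frames `shell`,
#'   `catalytic`, `terminal` (water oxygen atom rows) and logical `complete`.
#' @export
select_site_waters <- function(source, cofactor = get_cofactor(source),
                               substrate, shell_cutoff = 3.2,
                               terminal_cutoff = 4.0) {
  stopifnot(inherits(source, "structure3d"), inherits(substrate, "nucleotide"))
  wat <- source$atoms[source$atoms$category == "water" &
                        toupper(source$atoms$element) == "O", , drop = FALSE]
  empty <- wat[0, , drop = FALSE]
  if (nrow(wat) == 0) {
    warning("source contains no waters: site-water selection incomplete")
    return(structure(list(shell = empty, catalytic = empty, terminal = empty,
                          complete = FALSE), class = "site_waters"))
  }
  co <- as.numeric(cofactor[1, c("x", "y", "z")])
  wxyz <- as.matrix(wat[, c("x", "y", "z")])
  d_co <- sqrt(rowSums(sweep(wxyz, 2, co)^2))
  ord <- order(round(d_co, 6), wat$serial)
  shell_idx <- ord[d_co[ord] <= shell_cutoff]
  shell <- wat[shell_idx, , drop = FALSE]
  complete <- TRUE
  if (nrow(shell) < 4) {
    warning(sprintf("only %d first-shell waters found within %.2f A (4 expected)",
                    nrow(shell), shell_cutoff))
    complete <- FALSE
  }
  rest <- wat[setdiff(seq_len(nrow(wat)), shell_idx), , drop = FALSE]
  term_p <- if (substrate$n_phosphate == 3) "PG" else "PB"
  bridge <- if (substrate$n_phosphate == 3) {
    intersect(c("O3B", "N3B"), substrate$atoms$name)[1]
  } else {
    intersect(c("O3A", "N3A"), substrate$atoms$name)[1]
  }
  term_o <- intersect(if (substrate$n_phosphate == 3) c("O1G", "O2G", "O3G")
                      else c("O1B", "O2B", "O3B"), substrate$atoms$name)
  p_xyz <- as.numeric(ligand_coords(substrate, term_p))
  axis <- unit(p_xyz - as.numeric(ligand_coords(substrate, bridge)))
  catalytic <- empty
  if (nrow(rest) > 0) {
    rxyz <- as.matrix(rest[, c("x", "y", "z")])
    dp <- sqrt(rowSums(sweep(rxyz, 2, p_xyz)^2))
    proj <- as.numeric(sweep(rxyz, 2, p_xyz) %*% axis)
    cand <- which(proj > 0)
    if (length(cand)) {
      i <- cand[order(round(dp[cand], 6), rest$serial[cand])][1]
      catalytic <- rest[i, , drop = FALSE]
      rest <- rest[-i, , drop = FALSE]
    }
  }
  if (nrow(catalytic) == 0) complete <- FALSE
  terminal <- empty
  if (nrow(rest) > 0 && length(term_o)) {
    oxyz <- ligand_coords(substrate, term_o)
    dmin <- apply(cross_dist(as.matrix(rest[, c("x", "y", "z")]), oxyz), 1, min)
    cand <- which(dmin <= terminal_cutoff)
    if (length(cand)) {
      i <- cand[order(round(dmin[cand], 6), rest$serial[cand])][1]
      terminal <- rest[i, , drop = FALSE]
    }
  }
  if (nrow(terminal) == 0) complete <- FALSE
  structure(list(shell = shell, catalytic = catalytic, terminal = terminal,
                 complete = complete), class = "site_waters")
}

#' @export
print.site_waters <- function(x, ...) {
  cat(sprintf("site waters: %d shell, catalytic %s, terminal %s%s\n",
              nrow(x$shell),
              if (nrow(x$catalytic)) "present" else "missing",
              if (nrow(x$terminal)) "present" else "missing",
              if (x$complete) "" else " [incomplete]"))
  invisible(x)
}

#' Transplant substrate, cofactor and waters into a target model
#'
#' Applies the protein superposition to the selected components of the
#' solved source complex and inserts them as new residues of the target
#' model, on a dedicated chain with fresh serials. The transplanted bundle
#' is moved rigidly, so every distance within it is preserved. Steric
#' clashes between the bundle and the target are detected and reported on
#' the returned object (and as a warning), never silently dropped.
#'
#' @param target_model [structure3d()] of the target protein.
#' @param source_complex [structure3d()] of the solved complex (used for
#'   provenance bookkeeping).
#' @param superposition a `superposition` (or [rigid_transform()]) mapping
#'   source coordinates into the target frame.
#' @param substrate [nucleotide()] from the source complex.
#' @param cofactor one-row metal atom data.frame from the source complex.
#' @param waters a `site_waters` object from [select_site_waters()], or `NULL`.
#' @param graft_chain chain identifier for the transplanted residues.
#' @param clash_factor overlap factor passed to [steric_clashes()].
#' @return a `grafted_complex`: list with `structure` (target + bundle),
#'   `substrate`, `cofactor`, `waters` (all in the target frame), `clashes`,
#'   and `provenance`.
#' @export
graft_complex <- function(target_model, source_complex, superposition,
                          substrate, cofactor = get_cofactor(source_complex),
                          waters = NULL, graft_chain = "X",
                          clash_factor = 0.6) {
  tf <- if (inherits(superposition, "superposition")) superposition$transform
  else superposition
  stopifnot(inherits(tf, "rigid_transform"), inherits(substrate, "nucleotide"))
  if (graft_chain %in% unique(target_model$atoms$chain)) {
    stop("graft chain '", graft_chain, "' already exists in the target; ",
         "choose another", call. = FALSE)
  }
  cols <- c("serial", "atom", "altloc", "resname", "chain", "resno", "icode",
            "x", "y", "z", "occ", "b", "element")
  sub_t <- transform_ligand(substrate, tf)
  rows <- nucleotide_to_structure(sub_t, chain = graft_chain,
                                  resno = 1L)$atoms[, cols]
  resno_next <- 2L
  cof_t <- NULL
  if (!is.null(cofactor)) {
    cxyz <- transform_coords(as.matrix(cofactor[, c("x", "y", "z")]), tf)
    cof_t <- data.frame(serial = 0L, atom = cofactor$atom[1], altloc = "",
                        resname = cofactor$resname[1], chain = graft_chain,
                        resno = resno_next, icode = "",
                        x = cxyz[1], y = cxyz[2], z = cxyz[3],
                        occ = 1, b = 0, element = cofactor$element[1],
                        stringsAsFactors = FALSE)
    rows <- rbind(rows, cof_t[, cols])
    resno_next <- resno_next + 1L
  }
  wat_t <- NULL
  if (!is.null(waters)) {
    wall <- rbind(waters$shell, waters$catalytic, waters$terminal)
    if (nrow(wall)) {
      wxyz <- transform_coords(as.matrix(wall[, c("x", "y", "z")]), tf)
      wat_t <- data.frame(serial = 0L, atom = "O", altloc = "",
                          resname = "HOH", chain = graft_chain,
                          resno = seq(resno_next, length.out = nrow(wall)),
                          icode = "", x = wxyz[, 1], y = wxyz[, 2],
                          z = wxyz[, 3], occ = 1, b = 0, element = "O",
                          stringsAsFactors = FALSE)
      rows <- rbind(rows, wat_t[, cols])
    }
  }
  combined <- rbind(target_model$atoms[, cols], rows)
  combined$serial <- seq_len(nrow(combined))
  out_struct <- structure3d(combined, id = paste0(target_model$id, "+",
                                                  sub_t$comp_id),
                            source = target_model$source)
  clashes <- steric_clashes(out_struct, overlap_factor = clash_factor,
                            between = list(selector(chain = graft_chain),
                                           selector(chain = setdiff(
                                             unique(combined$chain),
                                             graft_chain))))
  if (nrow(clashes) > 0) {
    warning(nrow(clashes), " steric clash(es) between the grafted bundle ",
            "and the target model")
  }
  waters_out <- waters
  if (!is.null(waters_out)) {
    for (f in c("shell", "catalytic", "terminal")) {
      if (nrow(waters_out[[f]])) {
        waters_out[[f]][, c("x", "y", "z")] <-
          transform_coords(as.matrix(waters_out[[f]][, c("x", "y", "z")]), tf)
      }
    }
  }
  cof_out <- if (!is.null(cofactor)) {
    cofactor[, c("x", "y", "z")] <-
      transform_coords(as.matrix(cofactor[, c("x", "y", "z")]), tf)
    cofactor
  }
  structure(list(structure = out_struct,
                 substrate = sub_t,
                 cofactor = cof_out,
                 waters = waters_out,
                 graft_chain = graft_chain,
                 clashes = clashes,
                 provenance = list(
                   source = source_complex$id,
                   source_path = source_complex$source,
                   target = target_model$id,
                   transform = list(rotation = tf$rotation,
                                    translation = tf$translation),
                   components = c("substrate",
                                  if (!is.null(cofactor)) "cofactor",
                                  if (!is.null(waters)) "waters"))),
            class = "grafted_complex")
}

#' @export
print.grafted_complex <- function(x, ...) {
  nw <- if (is.null(x$waters)) 0 else
    nrow(x$waters$shell) + nrow(x$waters$catalytic) + nrow(x$waters$terminal)
  cat(sprintf(paste0("grafted complex: %s into %s (chain %s): substrate %s",
                     ", cofactor %s, %d waters, %d clash(es)\n"),
              x$provenance$source, x$provenance$target, x$graft_chain,
              x$substrate$comp_id,
              if (is.null(x$cofactor)) "none" else x$cofactor$resname[1],
              nw, nrow(x$clashes)))
  invisible(x)
}
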