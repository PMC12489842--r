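#' Pair residues of two protein chains by global sequence alignment
#'
#' Aligns the one-letter sequences of the polymer residues of one chain from
#' each structure (Needleman-Wunsch, BLOSUM62, gap open 10 / extend 0.5) and
#' returns the gap-free column pairing. Identity is reported over aligned
#' (non-gap) columns. Only residues with a CA atom enter the pairing, since
#' the superposition downstream is CA-based.
#'
#' @param struct_a,struct_b [structure3d()] objects.
#' @param chain_a,chain_b chain identifiers (default: first chain with
#'   polymer residues).
#' @return a `residue_pairing`: data.frame with columns `resno_a`,
#'   `icode_a`, `resno_b`, `icode_b`, and attributes `identity` and
#'   `aligned_length`.
#' @export
align_sequences <- function(struct_a, struct_b,
                            chain_a = first_polymer_chain(struct_a),
                            chain_b = first_polymer_chain(struct_b)) {
  ra <- polymer_residue_table(struct_a, chain_a)
  rb <- polymer_residue_table(struct_b, chain_b)
  if (nrow(ra) < 2 || nrow(rb) < 2) {
    stop("need at least 2 polymer residues with CA atoms per chain",
         call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(ra$aa1, collapse = "")),
    Biostrings::AAString(paste(rb$aa1, collapse = "")),
    type = "global", substitutionMatrix = blosum62_matrix(),
    gapOpening = 10, gapExtension = 0.5)
  sa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- ib <- 0L
  pairs <- vector("list", length(sa))
  n_aln <- 0L
  n_id <- 0L
  for (k in seq_along(sa)) {
    ga <- sa[k] == "-"
    gb <- sb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      n_aln <- n_aln + 1L
      if (sa[k] == sb[k]) n_id <- n_id + 1L
      pairs[[k]] <- c(ia, ib)
    }
  }
  pairs <- do.call(rbind, pairs)
  out <- data.frame(resno_a = ra$resno[pairs[, 1]],
                    icode_a = ra$icode[pairs[, 1]],
                    resno_b = rb$resno[pairs[, 2]],
                    icode_b = rb$icode[pairs[, 2]],
                    stringsAsFactors = FALSE)
  attr(out, "identity") <- n_id / n_aln
  attr(out, "aligned_length") <- n_aln
  attr(out, "chain_a") <- chain_a
  attr(out, "chain_b") <- chain_b
  class(out) <- c("residue_pairing", "data.frame")
  out
}

first_polymer_chain <- function(structure) {
  a <- structure$atoms
  ch <- unique(a$chain[a$category == "polymer"])
  if (length(ch) == 0) stop("structure has no polymer residues", call. = FALSE)
  ch[1]
}

# polymer residues of a chain that carry a CA atom, with one-letter codes
polymer_residue_table <- function(structure, chain) {
  a <- chain_polymer(structure, chain)
  ca <- a[a$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno, ca$icode), , drop = FALSE]
  data.frame(resno = ca$resno, icode = ca$icode,
             aa1 = bio3d::aa321(ca$resname),
             stringsAsFactors = FALSE)
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Iterative rigid superposition with outlier rejection
#'
#' Cycle 0 fits all paired CA atoms by least squares ([kabsch_fit()]); each
#' subsequent cycle drops pairs whose residual deviation exceeds
#' `reject_cutoff` and refits, stopping when no pair is dropped or the
#' cycle budget is exhausted. The reported RMSD covers the retained pairs.
#' Defaults (5 cycles, 2.0 Angstrom) mirror common interactive-alignment
#' practice.
#'
#' @param struct_a mobile [structure3d()].
#' @param struct_b fixed [structure3d()].
#' @param pairing a [align_sequences()] result (computed if omitted).
#' @param cycles maximum number of rejection cycles (>= 0).
#' @param reject_cutoff residual deviation above which a pair is dropped, Angstrom.
#' @return a `superposition` object: list with `transform` (maps
#'   `struct_a` coordinates into the `struct_b` frame), `rmsd`,
#'   `cycles_run`, `retained_pairs`, `rejected_pairs`, `initial_pairs`.
#' @export
iterative_superpose <- function(struct_a, struct_b,
                                pairing = align_sequences(struct_a, struct_b),
                                cycles = 5, reject_cutoff = 2.0) {
  stopifnot(inherits(pairing, "residue_pairing"), cycles >= 0,
            reject_cutoff > 0)
  ca_xyz <- function(s, chain, resno, icode) {
    a <- s$atoms
    idx <- match(paste(chain, resno, icode, "CA", sep = "\r"),
                 paste(a$chain, a$resno, a$icode, a$atom, sep = "\r"))
    idx
  }
  ia <- ca_xyz(struct_a, attr(pairing, "chain_a"), pairing$resno_a, pairing$icode_a)
  ib <- ca_xyz(struct_b, attr(pairing, "chain_b"), pairing$resno_b, pairing$icode_b)
  ok <- !is.na(ia) & !is.na(ib)
  A <- as.matrix(struct_a$atoms[ia[ok], c("x", "y", "z")])
  B <- as.matrix(struct_b$atoms[ib[ok], c("x", "y", "z")])
  n0 <- nrow(A)
  if (n0 == 0) stop("pairing contains no CA-bearing residue pairs", call. = FALSE)
  keep <- rep(TRUE, n0)
  fit <- NULL
  cycles_run <- 0L
  repeat {
    if (sum(keep) < 3) {
      stop("outlier rejection removed too many pairs (",
           sum(keep), " retained of ", n0,
           "); raise the cutoff or check the pairing", call. = FALSE)
    }
    fit <- kabsch_fit(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
    if (cycles_run >= cycles) break
    dev <- sqrt(rowSums((transform_coords(A, fit$transform) - B)^2))
    over <- which(keep & dev > reject_cutoff)
    if (length(over) == 0) break
    # drop at most the worst quarter of the retained pairs per cycle, so a
    # large displaced domain cannot evict the whole pairing in one step
    max_drop <- max(1L, ceiling(0.25 * sum(keep)))
    if (length(over) > max_drop) {
      over <- over[order(dev[over], decreasing = TRUE)][seq_len(max_drop)]
    }
    keep[over] <- FALSE
    cycles_run <- cycles_run + 1L
  }
  structure(list(transform = fit$transform, rmsd = fit$rmsd,
                 cycles_run = cycles_run,
                 retained_pairs = sum(keep),
                 rejected_pairs = n0 - sum(keep),
                 initial_pairs = n0,
                 pairing = pairing),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(paste0("superposition: rmsd %.4f A over %d CA pairs ",
                     "(%d rejected, %d cycles)\n"),
              x$rmsd, x$retained_pairs, x$rejected_pairs, x$cycles_run))
  invisible(x)
}

#' Apply a rigid transform to a whole structure
#'
#' Maps every atom coordinate x to R x + t. All intra-structure distances
#' are preserved (rigid motion).
#'
#' @param structure a [structure3d()].
#' @param tf a [rigid_transform()] (or a `superposition`, whose transform
#'   is used).
#' @return the transformed [structure3d()].
#' @export
apply_transform <- function(structure, tf) {
  if (inherits(tf, "superposition")) tf <- tf$transform
  stopifnot(inherits(tf, "rigid_transform"))
  set_atom_coords(structure, transform_coords(atom_coords(structure), tf))
}
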