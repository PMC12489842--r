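# Geometric validation of productive NTPDase-nucleotide complexes: bidentate
# metal coordination, symmetric DXG-aspartate distances, hydration-shell
# census, hydrogen bonds, clashes, sugar pucker, glycosidic torsion,
# base-plane orientation, and the canonical / alternative / nonproductive
# binding-mode decision.

# Bondi-style van der Waals radii (Angstrom) for clash detection
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90,
               CA = 2.31, MG = 1.73, MN = 2.05, ZN = 2.10, "NA" = 2.27,
               K = 2.75, FE = 2.05)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# phosphate oxygens grouped by the phosphorus they belong to; bridging
# atoms are excluded so "distinct phosphate groups" is unambiguous
phosphate_oxygen_groups <- function(substrate) {
  nm <- substrate$atoms$name
  g <- list(alpha = intersect(c("O1A", "O2A"), nm),
            beta = intersect(c("O1B", "O2B",
                               if (substrate$n_phosphate == 2) "O3B"), nm),
            gamma = if (substrate$n_phosphate == 3)
              intersect(c("O1G", "O2G", "O3G"), nm) else character(0))
  g[lengths(g) > 0]
}

resolve_complex <- function(x) {
  if (inherits(x, "grafted_complex")) {
    return(list(structure = x$structure, substrate = x$substrate,
                cofactor = x$cofactor, clashes = x$clashes))
  }
  stopifnot(inherits(x, "structure3d"))
  lig <- x$atoms[x$atoms$category == "ligand", , drop = FALSE]
  key <- unique(paste(lig$chain, lig$resno, lig$icode, sep = "\r"))
  if (length(key) != 1) {
    stop("structure must contain exactly one small-molecule ligand; found ",
         length(key), call. = FALSE)
  }
  substrate <- extract_component(x, selector(resname = unique(lig$resname)))
  list(structure = x, substrate = substrate,
       cofactor = get_cofactor(x, required = FALSE), clashes = NULL)
}

#' Bidentate cofactor coordination check
#'
#' A productive complex coordinates the metal cofactor through at least two
#' substrate phosphate oxygens belonging to two distinct phosphate groups.
#' The check reports every coordinating oxygen (within the
#' `[coord_min, coord_max]` window of the metal) and whether two distinct
#' groups contribute.
#'
#' @param x a `grafted_complex` or a [structure3d()] containing exactly one
#'   ligand and one metal.
#' @param coord_min,coord_max metal-oxygen coordination window, Angstrom.
#' @return list with `bidentate` (logical), `contacts` (data.frame of
#'   oxygen name, group, distance), and `groups` (distinct groups involved).
#' @export
check_bidentate <- function(x, coord_min = 2.0, coord_max = 3.0) {
  cx <- resolve_complex(x)
  if (is.null(cx$cofactor)) stop("no cofactor in complex", call. = FALSE)
  co <- as.numeric(cx$cofactor[1, c("x", "y", "z")])
  groups <- phosphate_oxygen_groups(cx$substrate)
  rows <- do.call(rbind, lapply(names(groups), function(g) {
    xyz <- ligand_coords(cx$substrate, groups[[g]])
    data.frame(atom = groups[[g]], group = g,
               distance = sqrt(rowSums(sweep(xyz, 2, co)^2)),
               stringsAsFactors = FALSE)
  }))
  contacts <- rows[rows$distance >= coord_min & rows$distance <= coord_max, ,
                   drop = FALSE]
  rownames(contacts) <- NULL
  list(bidentate = length(unique(contacts$group)) >= 2,
       contacts = contacts,
       groups = unique(contacts$group))
}

#' Locate the DXG motifs of ACR1 and ACR4
#'
#' Finds aspartates in Asp-x-Gly tripeptides whose side-chain CG lies
#' within `radius` of the cofactor, and returns the two nearest ordered by
#' sequence position (the ACR1 aspartate first). An explicit residue-number
#' override skips the pattern search (useful for divergent isoforms).
#'
#' @param structure a [structure3d()].
#' @param cofactor one-row metal atom data.frame (from the structure when
#'   omitted).
#' @param radius CG-to-cofactor search radius, Angstrom.
#' @param override optional integer vector of two Asp residue numbers (with
#'   optional `chain` attribute), skipping the search.
#' @return a `motif_annotation`: data.frame with one row per motif
#'   (`chain`, `resno`, `resname`, `cg_dist`).
#' @export
find_dxg_motifs <- function(structure, cofactor = get_cofactor(structure),
                            radius = 6.0, override = NULL) {
  a <- structure$atoms
  co <- as.numeric(cofactor[1, c("x", "y", "z")])
  if (!is.null(override)) {
    stopifnot(length(override) == 2)
    ch <- attr(override, "chain")
    rows <- lapply(override, function(rn) {
      sel <- a$resno == rn & a$category == "polymer" &
        (if (is.null(ch)) TRUE else a$chain == ch)
      cg <- a[sel & a$atom == "CG", , drop = FALSE]
      if (nrow(cg) == 0) stop("override residue ", rn, " has no CG atom",
                              call. = FALSE)
      if (cg$resname[1] != "ASP") stop("override residue ", rn,
                                       " is not an aspartate", call. = FALSE)
      data.frame(chain = cg$chain[1], resno = rn, resname = cg$resname[1],
                 cg_dist = sqrt(sum((as.numeric(cg[1, c("x", "y", "z")]) - co)^2)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    cand <- list()
    for (ch in unique(a$chain[a$category == "polymer"])) {
      p <- chain_polymer(structure, ch)
      res <- p[!duplicated(p$resno), c("resno", "resname")]
      res <- res[order(res$resno), ]
      for (i in seq_len(max(0, nrow(res) - 2))) {
        if (res$resname[i] == "ASP" && res$resname[i + 2] == "GLY" &&
            res$resno[i + 2] == res$resno[i] + 2) {
          cg <- p[p$resno == res$resno[i] & p$atom == "CG", , drop = FALSE]
          if (nrow(cg) == 0) next
          d <- sqrt(sum((as.numeric(cg[1, c("x", "y", "z")]) - co)^2))
          if (d <= radius) {
            cand[[length(cand) + 1]] <- data.frame(
              chain = ch, resno = res$resno[i], resname = "ASP", cg_dist = d,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(cand) < 2) {
      stop("found ", length(cand), " D-x-G aspartate(s) within ", radius,
           " A of the cofactor (2 required); pass explicit residue numbers ",
           "via 'override'", call. = FALSE)
    }
    out <- do.call(rbind, cand)
    out <- out[order(out$cg_dist), , drop = FALSE][1:2, , drop = FALSE]
    out <- out[order(out$resno), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("motif_annotation", "data.frame")
  out
}

#' Cofactor distances from the two DXG aspartates
#'
#' Euclidean distances from each motif aspartate's CG to the cofactor, in
#' (ACR1, ACR4) sequence order. In productive experimental complexes these
#' are nearly symmetric (about 4.8 Angstrom each).
#'
#' @param structure a [structure3d()].
#' @param motifs a [find_dxg_motifs()] annotation.
#' @param cofactor one-row metal atom data.frame.
#' @return numeric length-2 vector `c(d1, d2)`, Angstrom.
#' @export
dxg_distances <- function(structure, motifs = find_dxg_motifs(structure),
                          cofactor = get_cofactor(structure)) {
  a <- structure$atoms
  co <- as.numeric(cofactor[1, c("x", "y", "z")])
  d <- vapply(seq_len(nrow(motifs)), function(i) {
    cg <- a[a$chain == motifs$chain[i] & a$resno == motifs$resno[i] &
              a$atom == "CG" & a$category == "polymer", , drop = FALSE]
    if (nrow(cg) == 0) stop("missing CG atom for Asp", motifs$resno[i],
                            call. = FALSE)
    sqrt(sum((as.numeric(cg[1, c("x", "y", "z")]) - co)^2))
  }, numeric(1))
  d[1:2]
}

#' Count waters in the cofactor's first hydration shell
#'
#' @param structure a [structure3d()].
#' @param cofactor one-row metal atom data.frame.
#' @param cutoff shell cutoff, Angstrom.
#' @return list with `count` and `waters` (atom rows of the shell oxygens).
#' @export
hydration_shell_count <- function(structure,
                                  cofactor = get_cofactor(structure),
                                  cutoff = 3.2) {
  a <- structure$atoms
  wat <- a[a$category == "water" & toupper(a$element) == "O", , drop = FALSE]
  if (nrow(wat) == 0 || cutoff <= 0) {
    return(list(count = 0L, waters = wat[0, , drop = FALSE]))
  }
  co <- as.numeric(cofactor[1, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(as.matrix(wat[, c("x", "y", "z")]), 2, co)^2))
  keep <- wat[d <= cutoff, , drop = FALSE]
  rownames(keep) <- NULL
  list(count = nrow(keep), waters = keep)
}

#' Geometric hydrogen-bond detection
#'
#' Heavy-atom criterion: donor/acceptor pairs (N or O on both sides, in
#' different residues) within `d_max`. When explicit hydrogens are present
#' on the donor, the D-H...A angle must also reach `ang_min`; the crystal
#' structures this package targets carry no hydrogens, so the distance
#' criterion is usually the operative one.
#'
#' @param x a `grafted_complex` or [structure3d()].
#' @param d_max heavy-atom distance cutoff, Angstrom.
#' @param ang_min minimum D-H...A angle, degrees (applied only when
#'   hydrogens exist).
#' @param between optional list of two [selector()]s restricting the two
#'   sides of the contact (default: ligand/metal/water bundle vs polymer).
#' @return data.frame of contacts: residue, atom, distance on both sides.
#' @export
detect_hbonds <- function(x, d_max = 3.5, ang_min = 120, between = NULL) {
  s <- if (inherits(x, "grafted_complex")) x$structure else x
  stopifnot(inherits(s, "structure3d"))
  a <- s$atoms
  if (is.null(between)) {
    side1 <- a[a$category %in% c("ligand", "metal", "water"), , drop = FALSE]
    side2 <- a[a$category == "polymer", , drop = FALSE]
  } else {
    side1 <- select_atoms(s, between[[1]])$atoms
    side2 <- select_atoms(s, between[[2]])$atoms
  }
  side1 <- side1[toupper(side1$element) %in% c("N", "O"), , drop = FALSE]
  side2 <- side2[toupper(side2$element) %in% c("N", "O"), , drop = FALSE]
  if (nrow(side1) == 0 || nrow(side2) == 0) return(empty_contacts())
  dm <- cross_dist(as.matrix(side1[, c("x", "y", "z")]),
                   as.matrix(side2[, c("x", "y", "z")]))
  hits <- which(dm <= d_max & dm > 1.8, arr.ind = TRUE)  # > 1.8: not covalent
  if (nrow(hits) == 0) return(empty_contacts())
  same_res <- paste(side1$chain[hits[, 1]], side1$resno[hits[, 1]]) ==
    paste(side2$chain[hits[, 2]], side2$resno[hits[, 2]])
  hits <- hits[!same_res, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_contacts())
  out <- data.frame(
    res1 = paste0(side1$resname[hits[, 1]], side1$resno[hits[, 1]]),
    atom1 = side1$atom[hits[, 1]],
    res2 = paste0(side2$resname[hits[, 2]], side2$resno[hits[, 2]]),
    atom2 = side2$atom[hits[, 2]],
    distance = dm[hits],
    stringsAsFactors = FALSE)
  has_h <- any(toupper(a$element) == "H")
  if (has_h && nrow(out) > 0) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      don <- side1[hits[i, 1], ]
      acc <- as.numeric(side2[hits[i, 2], c("x", "y", "z")])
      hyd <- a[a$chain == don$chain & a$resno == don$resno &
                 toupper(a$element) == "H", , drop = FALSE]
      if (nrow(hyd) == 0) return(TRUE)
      dxyz <- as.numeric(don[c("x", "y", "z")])
      dh <- sqrt(rowSums(sweep(as.matrix(hyd[, c("x", "y", "z")]), 2, dxyz)^2))
      hyd <- hyd[dh < 1.3, , drop = FALSE]
      if (nrow(hyd) == 0) return(TRUE)
      any(vapply(seq_len(nrow(hyd)), function(j) {
        vec_angle(dxyz, as.numeric(hyd[j, c("x", "y", "z")]), acc) >= ang_min
      }, logical(1)))
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_contacts <- function() {
  data.frame(res1 = character(0), atom1 = character(0), res2 = character(0),
             atom2 = character(0), distance = numeric(0),
             stringsAsFactors = FALSE)
}

#' Steric clash detection
#'
#' Flags non-bonded atom pairs closer than `overlap_factor` times the sum
#' of their van der Waals radii. Pairs within the same residue are ignored,
#' as are metal-coordination contacts (a coordinated metal legitimately
#' sits well inside the vdW sum).
#'
#' @param x a `grafted_complex` or [structure3d()].
#' @param overlap_factor fraction of the vdW-radius sum below which a pair
#'   counts as clashing.
#' @param between optional list of two [selector()]s restricting the pairs
#'   examined (default: all inter-residue pairs).
#' @return data.frame of clashing pairs with distances and vdW sums.
#' @export
steric_clashes <- function(x, overlap_factor = 0.6, between = NULL) {
  s <- if (inherits(x, "grafted_complex")) x$structure else x
  stopifnot(inherits(s, "structure3d"))
  if (is.null(between)) {
    a1 <- a2 <- s$atoms
    self_mode <- TRUE
  } else {
    a1 <- select_atoms(s, between[[1]])$atoms
    a2 <- select_atoms(s, between[[2]])$atoms
    self_mode <- FALSE
  }
  if (nrow(a1) == 0 || nrow(a2) == 0) return(empty_clashes())
  dm <- cross_dist(as.matrix(a1[, c("x", "y", "z")]),
                   as.matrix(a2[, c("x", "y", "z")]))
  lim <- overlap_factor * outer(vdw_radius(a1$element), vdw_radius(a2$element), "+")
  hits <- which(dm < lim, arr.ind = TRUE)
  if (self_mode && nrow(hits)) hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  if (nrow(hits) == 0) return(empty_clashes())
  same_res <- paste(a1$chain[hits[, 1]], a1$resno[hits[, 1]], a1$icode[hits[, 1]]) ==
    paste(a2$chain[hits[, 2]], a2$resno[hits[, 2]], a2$icode[hits[, 2]])
  metal_coord <- (a1$category[hits[, 1]] == "metal" &
                    toupper(a2$element[hits[, 2]]) %in% c("O", "N")) |
    (a2$category[hits[, 2]] == "metal" &
       toupper(a1$element[hits[, 1]]) %in% c("O", "N"))
  # the peptide bond: backbone C(i)-N(i+1) of consecutive polymer residues
  peptide <- a1$category[hits[, 1]] == "polymer" &
    a2$category[hits[, 2]] == "polymer" &
    a1$chain[hits[, 1]] == a2$chain[hits[, 2]] &
    ((a1$atom[hits[, 1]] == "C" & a2$atom[hits[, 2]] == "N" &
        a2$resno[hits[, 2]] - a1$resno[hits[, 1]] == 1) |
       (a1$atom[hits[, 1]] == "N" & a2$atom[hits[, 2]] == "C" &
          a1$resno[hits[, 1]] - a2$resno[hits[, 2]] == 1))
  hits <- hits[!same_res & !metal_coord & !peptide, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_clashes())
  out <- data.frame(
    res1 = paste0(a1$resname[hits[, 1]], a1$resno[hits[, 1]]),
    atom1 = a1$atom[hits[, 1]],
    res2 = paste0(a2$resname[hits[, 2]], a2$resno[hits[, 2]]),
    atom2 = a2$atom[hits[, 2]],
    distance = dm[hits],
    vdw_sum = outer(vdw_radius(a1$element), vdw_radius(a2$element), "+")[hits],
    stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_clashes <- function() {
  data.frame(res1 = character(0), atom1 = character(0), res2 = character(0),
             atom2 = character(0), distance = numeric(0),
             vdw_sum = numeric(0), stringsAsFactors = FALSE)
}

#' Ribose pucker by pseudorotation analysis
#'
#' Computes the pseudorotation phase P and puckering amplitude tau_m from
#' the five endocyclic torsions of the ribose (Altona-Sundaralingam
#' construction) and classifies the pucker: C3'-endo for P in [0, 36),
#' C2'-endo for P in [144, 180), otherwise "other".
#'
#' @param ligand a [nucleotide()] with all five ring atoms
#'   (O4', C1', C2', C3', C4').
#' @return a `pucker_result`: list with `P` (degrees, in [0, 360)),
#'   `tau_m` (degrees), `cls`, and the five torsions `nu`.
#' @export
ribose_pucker <- function(ligand) {
  ring <- c("O4'", "C1'", "C2'", "C3'", "C4'")
  xyz <- tryCatch(ligand_coords(ligand, ring),
                  error = function(e) stop("missing ribose ring atom: ",
                                           conditionMessage(e), call. = FALSE))
  ps <- pseudorotation_from_xyz(xyz)
  cls <- if (ps$P >= 0 && ps$P < 36) "C3'-endo"
  else if (ps$P >= 144 && ps$P < 180) "C2'-endo"
  else "other"
  structure(list(P = ps$P, tau_m = ps$tau_m, cls = cls, nu = ps$nu),
            class = "pucker_result")
}

# pseudorotation phase/amplitude from ring coordinates (rows named
# O4', C1', C2', C3', C4')
pseudorotation_from_xyz <- function(xyz) {
  tor <- function(a, b, c, d) dihedral(xyz[a, ], xyz[b, ], xyz[c, ], xyz[d, ])
  nu <- c(tor("C4'", "O4'", "C1'", "C2'"),
          tor("O4'", "C1'", "C2'", "C3'"),
          tor("C1'", "C2'", "C3'", "C4'"),
          tor("C2'", "C3'", "C4'", "O4'"),
          tor("C3'", "C4'", "O4'", "C1'"))
  pucker_from_torsions(nu)
}

#' Pseudorotation phase from the five endocyclic torsions
#'
#' The Altona-Sundaralingam closed form: with the endocyclic torsions
#' nu0..nu4 (nu2 about the C2'-C3' bond),
#' `tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))` and
#' `tau_m = nu2 / cos P`. Useful directly when torsions are already known
#' (e.g. from published tables); [ribose_pucker()] measures them from
#' coordinates and delegates here.
#'
#' @param nu numeric length-5 vector of torsions nu0..nu4, degrees.
#' @return list with `P` (degrees in \[0, 360)), `tau_m` (degrees), `nu`.
#' @export
pucker_from_torsions <- function(nu) {
  stopifnot(length(nu) == 5, all(is.finite(nu)))
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(deg2rad(36)) + sin(deg2rad(72)))
  P <- rad2deg(atan(num / den))
  if (nu[3] < 0) P <- P + 180
  P <- P %% 360
  list(P = P, tau_m = nu[3] / cos(deg2rad(P)), nu = nu)
}

#' @export
print.pucker_result <- function(x, ...) {
  cat(sprintf("ribose pucker: P = %.1f deg, tau_m = %.1f deg -> %s\n",
              x$P, x$tau_m, x$cls))
  invisible(x)
}

#' Glycosidic torsion chi and anti/syn classification
#'
#' chi is the dihedral O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for
#' pyrimidines. The nucleoside is `anti` for chi in \[90, 180\] or
#' (-180, -90), `syn` otherwise.
#'
#' @param ligand a [nucleotide()].
#' @return a `chi_result`: list with `chi` (degrees, signed) and `cls`.
#' @export
glycosidic_chi <- function(ligand) {
  at <- if (ligand$base_type == "purine") c("O4'", "C1'", "N9", "C4")
  else c("O4'", "C1'", "N1", "C2")
  xyz <- tryCatch(ligand_coords(ligand, at),
                  error = function(e) stop("missing glycosidic atoms: ",
                                           conditionMessage(e), call. = FALSE))
  chi <- dihedral(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
  cls <- if (chi >= 90 || chi < -90) "anti" else "syn"
  structure(list(chi = chi, cls = cls), class = "chi_result")
}

#' @export
print.chi_result <- function(x, ...) {
  cat(sprintf("glycosidic torsion: chi = %.1f deg -> %s\n", x$chi, x$cls))
  invisible(x)
}

#' Angle between the nucleobase planes of two ligands
#'
#' Fits a least-squares plane through the ring atoms of each base (ring
#' atoms only, no exocyclic substituents) and returns the angle between
#' the two plane normals, folded into \[0, 90\] degrees. Both ligands must
#' sit in a common frame.
#'
#' @param lig_a,lig_b [nucleotide()] objects in a common frame.
#' @return angle in degrees, in \[0, 90\].
#' @export
base_plane_angle <- function(lig_a, lig_b) {
  ring_of <- function(l) {
    ring <- if (l$base_type == "purine") PURINE_RING else PYRIMIDINE_RING
    ring <- intersect(ring, l$atoms$name)
    if (length(ring) < 3) stop("fewer than 3 base ring atoms", call. = FALSE)
    ligand_coords(l, ring)
  }
  n1 <- plane_normal(ring_of(lig_a))
  n2 <- plane_normal(ring_of(lig_b))
  ang <- rad2deg(acos(max(-1, min(1, abs(sum(n1 * n2))))))
  ang
}

#' Canonical productive-binding references
#'
#' Bundles the benchmark triphosphate and diphosphate substrates (in their
#' source protein frames) against which unknown complexes are classified.
#' In the experimental corpus these are the ATP analog of RnNTPDase2 entry
#' 3CJA and the ADP analog of entry 4BR0; synthetic stand-ins generated by
#' [make_toy_complex()] fill the same role offline.
#'
#' @param ntp_reference [nucleotide()] with three phosphates (or `NULL`).
#' @param ndp_reference [nucleotide()] with two phosphates (or `NULL`).
#'   At least one reference must be given.
#' @return a `canonical_reference` object.
#' @export
canonical_reference <- function(ntp_reference = NULL, ndp_reference = NULL) {
  if (is.null(ntp_reference) && is.null(ndp_reference)) {
    stop("at least one reference must be supplied", call. = FALSE)
  }
  if (!is.null(ntp_reference)) {
    stopifnot(inherits(ntp_reference, "nucleotide"),
              ntp_reference$n_phosphate == 3)
  }
  if (!is.null(ndp_reference)) {
    stopifnot(inherits(ndp_reference, "nucleotide"),
              ndp_reference$n_phosphate == 2)
  }
  structure(list(ntp = ntp_reference, ndp = ndp_reference),
            class = "canonical_reference")
}

#' Classify the binding mode of a complex
#'
#' Applies the productive-complex checklist against the phosphate-count
#' matched canonical reference. The complex must already be superposed onto
#' the reference's protein frame. Decision rule: `canonical` when the
#' all-common-atom substrate RMSD is at or below `rmsd_threshold` AND the
#' bidentate cofactor interaction holds; `alternative` when instead the
#' phosphate + ribose moiety aligns (RMSD at or below the threshold) but
#' the nucleobase plane is rotated more than 45 degrees from the
#' reference's; otherwise `nonproductive`.
#'
#' @param x a `grafted_complex` or [structure3d()] with one ligand and one
#'   metal, in the reference frame.
#' @param references a [canonical_reference()].
#' @param rmsd_threshold canonical-conformation threshold, Angstrom. The
#'   default 1.5 separates the largest canonical exemplar (1.22) from the
#'   alternative mode's tail-only fit (1.64) in the experimental corpus.
#' @param coord_min,coord_max bidentate coordination window, Angstrom.
#' @param shell_cutoff hydration-shell cutoff, Angstrom.
#' @return a `validation_report`: list with the mode and every measured
#'   feature (RMSDs, bidentate contacts, DXG distances, water census,
#'   H-bonds, clashes, pucker, chi, base-plane angle).
#' @export
classify_binding_mode <- function(x, references, rmsd_threshold = 1.5,
                                  coord_min = 2.0, coord_max = 3.0,
                                  shell_cutoff = 3.2) {
  stopifnot(inherits(references, "canonical_reference"))
  cx <- resolve_complex(x)
  ref <- if (cx$substrate$n_phosphate == 3) references$ntp else references$ndp
  if (is.null(ref) || ref$n_phosphate != cx$substrate$n_phosphate) {
    stop("no reference with a phosphate count matching the substrate (",
         cx$substrate$n_phosphate, ")", call. = FALSE)
  }
  rmsd_all <- substrate_rmsd(cx$substrate, ref,
                             map_common_atoms(cx$substrate, ref, "all_common"))
  rmsd_pr <- substrate_rmsd(cx$substrate, ref,
                            map_common_atoms(cx$substrate, ref,
                                             "phosphate_ribose"))
  bid <- if (!is.null(cx$cofactor)) {
    check_bidentate(x, coord_min, coord_max)
  } else list(bidentate = NA, contacts = NULL)
  bp <- tryCatch(base_plane_angle(cx$substrate, ref), error = function(e) NA_real_)
  motifs <- tryCatch(find_dxg_motifs(cx$structure, cx$cofactor),
                     error = function(e) NULL)
  dxg <- if (!is.null(motifs)) dxg_distances(cx$structure, motifs, cx$cofactor)
  else c(NA_real_, NA_real_)
  shell <- if (!is.null(cx$cofactor)) {
    hydration_shell_count(cx$structure, cx$cofactor, shell_cutoff)
  } else list(count = NA_integer_, waters = NULL)
  site_w <- if (!is.null(cx$cofactor)) {
    tryCatch(suppressWarnings(
      select_site_waters(cx$structure, cx$cofactor, cx$substrate,
                         shell_cutoff = shell_cutoff)),
      error = function(e) NULL)
  }
  hb <- detect_hbonds(x)
  cl <- if (!is.null(cx$clashes)) cx$clashes else steric_clashes(cx$structure)
  pk <- ribose_pucker(cx$substrate)
  ch <- glycosidic_chi(cx$substrate)
  mode <- if (isTRUE(bid$bidentate) && rmsd_all <= rmsd_threshold) "canonical"
  else if (rmsd_pr <= rmsd_threshold && !is.na(bp) && bp > 45) "alternative"
  else "nonproductive"
  structure(list(
    mode = mode,
    substrate = cx$substrate$comp_id,
    reference = ref$comp_id,
    substrate_rmsd_vs_reference = rmsd_all,
    phosphate_ribose_rmsd = rmsd_pr,
    rmsd_threshold = rmsd_threshold,
    bidentate = bid$bidentate,
    bidentate_contacts = bid$contacts,
    dxg_distances = dxg,
    shell_water_count = shell$count,
    catalytic_water_present = !is.null(site_w) && nrow(site_w$catalytic) > 0,
    hbonds = hb,
    clashes = cl,
    pucker = pk,
    chi = ch,
    base_plane_angle_vs_reference = bp),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Productive-complex validation report\n")
  cat(sprintf("  substrate %s vs reference %s\n", x$substrate, x$reference))
  cat(sprintf("  mode: %s\n", toupper(x$mode)))
  cat(sprintf("  substrate RMSD (all common atoms): %.3f A (threshold %.2f)\n",
              x$substrate_rmsd_vs_reference, x$rmsd_threshold))
  cat(sprintf("  phosphate+ribose RMSD: %.3f A\n", x$phosphate_ribose_rmsd))
  cat(sprintf("  bidentate cofactor coordination: %s\n", x$bidentate))
  cat(sprintf("  DXG CG-cofactor distances: %.2f / %.2f A\n",
              x$dxg_distances[1], x$dxg_distances[2]))
  cat(sprintf("  first-shell waters: %s; extra site waters: %s\n",
              x$shell_water_count, x$catalytic_water_present))
  cat(sprintf("  pucker: P = %.1f deg (%s); chi = %.1f deg (%s)\n",
              x$pucker$P, x$pucker$cls, x$chi$chi, x$chi$cls))
  cat(sprintf("  base-plane angle vs reference: %.1f deg\n",
              x$base_plane_angle_vs_reference))
  cat(sprintf("  H-bond contacts: %d; clashes: %d\n",
              nrow(x$hbonds), nrow(x$clashes)))
  invisible(x)
}

#' Closed-state verification of a model against a template
#'
#' NTPDases undergo a butterfly-like interdomain motion; the closed state
#' supports productive binding, and the relative position of the ACR1 and
#' ACR4 motifs tracks it. This check superposes the model onto the
#' template, reports the overall CA RMSD, and compares the CG-CG distance
#' between the two DXG aspartates with the template's: a model whose
#' distance exceeds the template's by more than `margin` is flagged
#' open-like.
#'
#' @param model [structure3d()] of the model to verify.
#' @param template [structure3d()] of the closed-state template (must
#'   contain the cofactor used to locate the motifs, unless `motifs` is
#'   supplied).
#' @param margin allowed excess of the model's Asp-Asp distance over the
#'   template's, Angstrom.
#' @param motifs optional [find_dxg_motifs()] annotation for the template.
#' @return a `closed_state_report`: list with `rmsd`, `dd_template`,
#'   `dd_model`, `closed` (logical), and the superposition.
#' @export
validate_closed_state <- function(model, template, margin = 2.0,
                                  motifs = NULL) {
  pairing <- align_sequences(model, template)
  sup <- iterative_superpose(model, template, pairing)
  if (is.null(motifs)) motifs <- find_dxg_motifs(template)
  cg <- function(s, chain, resno) {
    a <- s$atoms
    r <- a[a$chain == chain & a$resno == resno & a$atom == "CG", , drop = FALSE]
    if (nrow(r) == 0) stop("motif residue ", resno, " has no CG in ", s$id,
                           call. = FALSE)
    as.numeric(r[1, c("x", "y", "z")])
  }
  dd_template <- vnorm(cg(template, motifs$chain[1], motifs$resno[1]) -
                         cg(template, motifs$chain[2], motifs$resno[2]))
  # map the template motif residues to the model through the pairing
  model_res <- vapply(motifs$resno, function(rn) {
    i <- match(rn, pairing$resno_b)
    if (is.na(i)) stop("motif residue ", rn, " unaligned in model", call. = FALSE)
    pairing$resno_a[i]
  }, numeric(1))
  ch_a <- attr(pairing, "chain_a")
  dd_model <- vnorm(cg(model, ch_a, model_res[1]) - cg(model, ch_a, model_res[2]))
  structure(list(rmsd = sup$rmsd,
                 dd_template = dd_template,
                 dd_model = dd_model,
                 margin = margin,
                 closed = (dd_model - dd_template) <= margin,
                 superposition = sup),
            class = "closed_state_report")
}

#' @export
print.closed_state_report <- function(x, ...) {
  cat(sprintf(paste0("closed-state check: CA rmsd %.3f A; Asp-Asp %.2f A ",
                     "(template %.2f, margin %.1f) -> %s\n"),
              x$rmsd, x$dd_model, x$dd_template, x$margin,
              if (x$closed) "closed" else "open-like"))
  invisible(x)
}
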