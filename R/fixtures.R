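# Synthetic, fully self-contained test inputs: idealized nucleotides at a
# chosen sugar pucker and glycosidic torsion, toy protein scaffolds with
# planted DXG motifs, a cofactor ion and waters at exact planned distances.
# Everything is generated deterministically from code (no downloads), so the
# whole pipeline is testable offline. These are geometric test vectors, not
# folded proteins.

#' Fixture specification
#'
#' Describes a synthetic productive-complex fixture: nucleotide kind, sugar
#' pucker target, glycosidic torsion target, and the planned active-site
#' distances. The same seed and spec always produce an identical structure.
#'
#' Default plan values follow the geometry conserved across productive
#' experimental complexes: near-symmetric DXG aspartate CG-cofactor
#' distances of 4.80 / 4.84 Angstrom, calcium-oxygen coordination around
#' 2.4 Angstrom, and a four-water first hydration shell plus catalytic and
#' terminal-phosphate waters.
#'
#' @param seed integer seed for the (optional) coordinate noise.
#' @param kind nucleotide kind: `"ATP"`, `"ADP"`, `"GTP"`, `"GDP"`,
#'   `"UTP"`, `"UDP"`.
#' @param P target pseudorotation phase, degrees (default 162, a C2'-endo
#'   pucker, as in the benchmark triphosphate complex).
#' @param chi target glycosidic torsion, degrees (default -120, anti).
#' @param coord_dist planned metal-oxygen coordination distances for the
#'   two bidentate phosphate oxygens, Angstrom.
#' @param dxg_dist planned Asp CG to cofactor distances (ACR1, ACR4), Angstrom.
#' @param shell_dist planned first-shell water-to-metal distance, Angstrom.
#' @param noise_sigma isotropic Gaussian coordinate noise, Angstrom.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L, kind = "ATP", P = 162, chi = -120,
                         coord_dist = c(2.35, 2.40),
                         dxg_dist = c(4.80, 4.84),
                         shell_dist = 2.40, noise_sigma = 0) {
  kind <- toupper(kind)
  if (!kind %in% c("ATP", "ADP", "GTP", "GDP", "UTP", "UDP")) {
    stop("unknown nucleotide kind '", kind, "'", call. = FALSE)
  }
  stopifnot(length(coord_dist) == 2, length(dxg_dist) == 2,
            all(coord_dist > 0), all(dxg_dist > 0), shell_dist > 0,
            noise_sigma >= 0)
  structure(list(seed = as.integer(seed), kind = kind, P = P, chi = chi,
                 coord_dist = coord_dist, dxg_dist = dxg_dist,
                 shell_dist = shell_dist, noise_sigma = noise_sigma),
            class = "fixture_spec")
}

# ---- idealized planar nucleobase templates --------------------------------

# Regular-polygon base geometry with exact ring closure: hexagon and (for
# purines) a fused pentagon sharing the C4-C5 edge, bond length 1.38 A.
# Exocyclic substituents sit on the external bisector of their ring atom.
base_template <- function(letter) {
  s <- 1.38
  hex_names <- switch(letter,
                      A = , G = c("C4", "C5", "C6", "N1", "C2", "N3"),
                      U = c("N1", "C2", "N3", "C4", "C5", "C6"))
  ang <- c(150, 210, 270, 330, 30, 90)
  hex <- cbind(s * cos(deg2rad(ang)), s * sin(deg2rad(ang)))
  rownames(hex) <- hex_names
  atoms <- data.frame(name = hex_names,
                      element = substr(hex_names, 1, 1),
                      x = hex[, 1], y = hex[, 2], z = 0,
                      stringsAsFactors = FALSE)
  if (letter %in% c("A", "G")) {
    # pentagon C4-C5-N7-C8-N9 fused on the C4(150)/C5(210) edge
    r5 <- s / (2 * sin(deg2rad(36)))
    a5 <- s / (2 * tan(deg2rad(36)))
    a6 <- s * cos(deg2rad(30))
    pc <- (a5 + a6) * c(cos(deg2rad(180)), sin(deg2rad(180)))
    th_c4 <- rad2deg(atan2(hex["C4", 2] - pc[2], hex["C4", 1] - pc[1]))
    # step from C4 away from C5: C5 sits at th_c4 - 72, so N9, C8, N7 ascend
    penta_new <- c("N9", "C8", "N7")
    for (k in 1:3) {
      th <- th_c4 + 72 * k
      atoms <- rbind(atoms, data.frame(
        name = penta_new[k], element = substr(penta_new[k], 1, 1),
        x = pc[1] + r5 * cos(deg2rad(th)), y = pc[2] + r5 * sin(deg2rad(th)),
        z = 0, stringsAsFactors = FALSE))
    }
  }
  exo <- switch(letter,
                A = list(N6 = c("C6", 1.34)),
                G = list(O6 = c("C6", 1.24), N2 = c("C2", 1.34)),
                U = list(O2 = c("C2", 1.23), O4 = c("C4", 1.23)))
  ring_center <- colMeans(hex)
  for (nm in names(exo)) {
    host <- exo[[nm]][1]
    blen <- as.numeric(exo[[nm]][2])
    h <- as.numeric(atoms[atoms$name == host, c("x", "y")])
    dir <- unit(c(h - ring_center, 0))[1:2]
    atoms <- rbind(atoms, data.frame(
      name = nm, element = substr(nm, 1, 1),
      x = h[1] + blen * dir[1], y = h[2] + blen * dir[2], z = 0,
      stringsAsFactors = FALSE))
  }
  rownames(atoms) <- NULL
  atoms
}

# ---- ribose ring at a target pseudorotation phase -------------------------

# Puckered pentagon: planar ring distorted by out-of-plane displacements
# z_j = A cos(psi + 144 j); the phase offset psi is root-found so the
# measured Altona-Sundaralingam phase equals the target.
ribose_ring_at_phase <- function(P_target, tau_target = 38) {
  ring <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  r <- 1.48 / (2 * sin(deg2rad(36)))
  build <- function(psi, A) {
    j <- 0:4
    th <- deg2rad(90 + 72 * j)
    xyz <- cbind(r * cos(th), r * sin(th), A * cos(deg2rad(psi + 144 * j)))
    rownames(xyz) <- ring
    xyz
  }
  measured <- function(psi, A) {
    pseudorotation_from_xyz(build(psi, A)[c("O4'", "C1'", "C2'", "C3'", "C4'"), ])
  }
  # calibrate amplitude, then scan the phase offset
  A <- 0.38
  m0 <- measured(0, A)
  A <- A * tau_target / abs(m0$tau_m)
  grid <- seq(0, 360, by = 0.1)
  pv <- vapply(grid, function(psi) measured(psi, A)$P, numeric(1))
  dd <- abs(((pv - P_target + 180) %% 360) - 180)
  psi0 <- grid[which.min(dd)]
  fine <- seq(psi0 - 0.2, psi0 + 0.2, by = 0.002)
  pv <- vapply(fine, function(psi) measured(psi, A)$P, numeric(1))
  dd <- abs(((pv - P_target + 180) %% 360) - 180)
  build(fine[which.min(dd)], A)
}

# ---- idealized nucleotide -------------------------------------------------

#' Build an idealized nucleotide at a chosen pucker and glycosidic torsion
#'
#' Constructs a full heavy-atom nucleotide (phosphate tail, ribose,
#' nucleobase) from idealized internal geometry: the ribose ring is built
#' at the requested pseudorotation phase (within ~0.1 degree), the base is
#' attached at exactly the requested glycosidic torsion, and the phosphate
#' tail follows an extended, linear-like conformation. Useful as a fully
#' offline stand-in for crystallographic ligands.
#'
#' @param kind `"ATP"`, `"ADP"`, `"GTP"`, `"GDP"`, `"UTP"`, or `"UDP"`.
#' @param P target pseudorotation phase, degrees in [0, 360).
#' @param chi target glycosidic torsion, degrees in (-180, 180].
#' @return a [nucleotide()].
#' @examples
#' lig <- make_ideal_nucleotide("ATP", P = 162, chi = -120)
#' ribose_pucker(lig)
#' glycosidic_chi(lig)
#' @export
make_ideal_nucleotide <- function(kind, P = 162, chi = -120) {
  kind <- toupper(kind)
  letter <- substr(kind, 1, 1)
  if (!kind %in% c("ATP", "ADP", "GTP", "GDP", "UTP", "UDP")) {
    stop("unknown nucleotide kind '", kind, "'", call. = FALSE)
  }
  if (P < 0 || P >= 360) stop("P must lie in [0, 360)", call. = FALSE)
  if (chi <= -180 || chi > 180) stop("chi must lie in (-180, 180]", call. = FALSE)
  n_phos <- if (substr(kind, 2, 3) == "TP") 3L else 2L

  ring <- ribose_ring_at_phase(P)
  xyz <- list()
  for (nm in rownames(ring)) xyz[[nm]] <- ring[nm, ]
  nu <- pseudorotation_from_xyz(ring[c("O4'", "C1'", "C2'", "C3'", "C4'"), ])$nu

  # ribose substituents (tetrahedral placements off the ring torsions)
  xyz[["O2'"]] <- place_atom(xyz[["O4'"]], xyz[["C1'"]], xyz[["C2'"]],
                             1.41, 112, nu[2] + 120)
  xyz[["O3'"]] <- place_atom(xyz[["C1'"]], xyz[["C2'"]], xyz[["C3'"]],
                             1.42, 111, nu[3] + 120)
  xyz[["C5'"]] <- place_atom(xyz[["C2'"]], xyz[["C3'"]], xyz[["C4'"]],
                             1.51, 116, nu[4] - 120)
  xyz[["O5'"]] <- place_atom(xyz[["C3'"]], xyz[["C4'"]], xyz[["C5'"]],
                             1.42, 110, 54)

  # nucleobase anchors: glycosidic nitrogen, then the two ring neighbours,
  # with the torsion O4'-C1'-N-(principal neighbour) set exactly to chi
  tpl <- base_template(letter)
  txyz <- as.matrix(tpl[, c("x", "y", "z")])
  rownames(txyz) <- tpl$name
  if (letter %in% c("A", "G")) {
    gn <- "N9"; nb1 <- "C4"; nb2 <- "C8"
  } else {
    gn <- "N1"; nb1 <- "C2"; nb2 <- "C6"
  }
  d1 <- vnorm(txyz[nb1, ] - txyz[gn, ])
  d2 <- vnorm(txyz[nb2, ] - txyz[gn, ])
  ang_tpl <- vec_angle(txyz[nb1, ], txyz[gn, ], txyz[nb2, ])
  xyz[[gn]] <- place_atom(xyz[["C4'"]], xyz[["O4'"]], xyz[["C1'"]],
                          1.47, 108.2, nu[1] - 120)
  a1 <- 126
  a2 <- 360 - a1 - ang_tpl
  anchor1 <- place_atom(xyz[["O4'"]], xyz[["C1'"]], xyz[[gn]], d1, a1, chi)
  anchor2 <- place_atom(xyz[["O4'"]], xyz[["C1'"]], xyz[[gn]], d2, a2, chi + 180)
  fit <- kabsch_fit(txyz[c(gn, nb1, nb2), ],
                    rbind(xyz[[gn]], anchor1, anchor2))
  placed <- transform_coords(txyz, fit$transform)
  for (nm in rownames(placed)) xyz[[nm]] <- placed[nm, ]

  # phosphate tail, extended
  xyz[["PA"]] <- place_atom(xyz[["C4'"]], xyz[["C5'"]], xyz[["O5'"]],
                            1.60, 119, 180)
  xyz[["O3A"]] <- place_atom(xyz[["C5'"]], xyz[["O5'"]], xyz[["PA"]],
                             1.61, 104, 180)
  xyz[["O1A"]] <- place_atom(xyz[["C5'"]], xyz[["O5'"]], xyz[["PA"]],
                             1.48, 108, 60)
  xyz[["O2A"]] <- place_atom(xyz[["C5'"]], xyz[["O5'"]], xyz[["PA"]],
                             1.48, 108, -60)
  xyz[["PB"]] <- place_atom(xyz[["O5'"]], xyz[["PA"]], xyz[["O3A"]],
                            1.61, 130, 150)
  if (n_phos == 3L) {
    xyz[["O3B"]] <- place_atom(xyz[["PA"]], xyz[["O3A"]], xyz[["PB"]],
                               1.61, 104, 180)
    xyz[["O1B"]] <- place_atom(xyz[["PA"]], xyz[["O3A"]], xyz[["PB"]],
                               1.48, 108, 60)
    xyz[["O2B"]] <- place_atom(xyz[["PA"]], xyz[["O3A"]], xyz[["PB"]],
                               1.48, 108, -60)
    xyz[["PG"]] <- place_atom(xyz[["O3A"]], xyz[["PB"]], xyz[["O3B"]],
                              1.61, 130, 150)
    xyz[["O1G"]] <- place_atom(xyz[["PB"]], xyz[["O3B"]], xyz[["PG"]],
                               1.49, 109, 180)
    xyz[["O2G"]] <- place_atom(xyz[["PB"]], xyz[["O3B"]], xyz[["PG"]],
                               1.49, 109, 60)
    xyz[["O3G"]] <- place_atom(xyz[["PB"]], xyz[["O3B"]], xyz[["PG"]],
                               1.49, 109, -60)
  } else {
    xyz[["O3B"]] <- place_atom(xyz[["O5'"]], xyz[["PA"]], xyz[["PB"]],
                               1.49, 109, 75)
    xyz[["O1B"]] <- place_atom(xyz[["PA"]], xyz[["O3A"]], xyz[["PB"]],
                               1.49, 109, 60)
    xyz[["O2B"]] <- place_atom(xyz[["PA"]], xyz[["O3A"]], xyz[["PB"]],
                               1.49, 109, -60)
  }

  want <- nucleotide_atom_names(kind)
  m <- do.call(rbind, xyz[want])
  atoms <- data.frame(name = want, element = guess_element(want),
                      x = m[, 1], y = m[, 2], z = m[, 3],
                      stringsAsFactors = FALSE)
  nucleotide(atoms, kind)
}

#' Turn a true nucleotide into its non-hydrolyzable imido analog
#'
#' The inverse of [analog_to_substrate()], for building test inputs:
#' replaces the last bridging oxygen (O3B for triphosphates, O3A for
#' diphosphates) by the imido nitrogen, coordinates untouched.
#'
#' @param ligand a [nucleotide()] without an analog bridge.
#' @return a [nucleotide()] flagged as an analog.
#' @export
nucleotide_as_analog <- function(ligand) {
  stopifnot(inherits(ligand, "nucleotide"))
  if (!is.na(ligand$analog_bridge)) {
    stop("ligand is already an analog", call. = FALSE)
  }
  target <- if (ligand$n_phosphate == 3) "O3B" else "O3A"
  i <- which(ligand$atoms$name == target)
  if (length(i) != 1) stop("ligand has no ", target, " bridge", call. = FALSE)
  ligand$atoms$name[i] <- sub("^O", "N", target)
  ligand$atoms$element[i] <- "N"
  analog_codes <- stats::setNames(names(ANALOG_PARENTS), ANALOG_PARENTS)
  if (ligand$comp_id %in% names(analog_codes)) {
    ligand$comp_id <- unname(analog_codes[ligand$comp_id])
  }
  ligand$analog_bridge <- sub("^O", "N", target)
  ligand
}

# ---- toy protein scaffold -------------------------------------------------

HELIX_SEQ <- c("ALA", "ALA", "ASP", "ALA", "GLY", "ALA", "ALA")

# Ideal alpha-helical peptide (phi -57, psi -47) with side chains to CG for
# Asp; returns an atom data.frame in a local frame.
build_helix_fragment <- function(seq3 = HELIX_SEQ, resno_start = 1L) {
  phi <- -57; psi <- -47; omega <- 180
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.0; a_cacn <- 116.6; a_cnca <- 121.7
  rows <- list()
  add <- function(resno, resname, name, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, resname = resname, resno = resno,
      x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE)
  }
  n <- c(0, 0, 0)
  ca <- c(b_nca, 0, 0)
  cc <- ca + b_cac * c(cos(deg2rad(180 - a_ncac)), sin(deg2rad(180 - a_ncac)), 0)
  for (i in seq_along(seq3)) {
    rn <- resno_start + i - 1L
    res <- seq3[i]
    add(rn, res, "N", n); add(rn, res, "CA", ca); add(rn, res, "C", cc)
    n_next <- place_atom(n, ca, cc, b_cn, a_cacn, psi)
    add(rn, res, "O", place_atom(n, ca, cc, 1.231, 120.8, psi + 180))
    if (res != "GLY") {
      cb <- place_atom(n_next, cc, ca, 1.53, 110.5, 122.6)
      add(rn, res, "CB", cb)
      if (res == "ASP") {
        cg <- place_atom(n, ca, cb, 1.52, 113, -65)
        add(rn, res, "CG", cg)
        add(rn, res, "OD1", place_atom(ca, cb, cg, 1.25, 119, -20))
        add(rn, res, "OD2", place_atom(ca, cb, cg, 1.25, 119, 160))
      }
    }
    if (i < length(seq3)) {
      ca_next <- place_atom(ca, cc, n_next, b_nca, a_cnca, omega)
      c_next <- place_atom(cc, n_next, ca_next, b_cac, a_ncac, phi)
      n <- n_next; ca <- ca_next; cc <- c_next
    }
  }
  do.call(rbind, rows)
}

# Rigidly place an atom table so that its `anchor` atom lands at `target`
# and the fragment extends along `away` (deterministic orientation).
place_fragment <- function(frag, anchor_idx, target, away) {
  xyz <- as.matrix(frag[, c("x", "y", "z")])
  p0 <- xyz[anchor_idx, ]
  centroid <- colMeans(xyz)
  v <- centroid - p0
  if (vnorm(v) < 1e-6) v <- c(1, 0, 0)
  u1 <- unit(v)
  ref <- if (abs(u1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u2 <- unit(ref - sum(ref * u1) * u1)
  u3 <- cross3(u1, u2)
  e1 <- unit(away)
  ref2 <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- unit(ref2 - sum(ref2 * e1) * e1)
  e3 <- cross3(e1, e2)
  rot <- cbind(e1, e2, e3) %*% t(cbind(u1, u2, u3))
  tf <- rigid_transform(rot, target - as.numeric(rot %*% p0))
  frag[, c("x", "y", "z")] <- transform_coords(xyz, tf)
  frag
}

# Rigid placement of a ligand so two named atoms sit at planned distances
# r1, r2 from the origin; the remaining roll degree of freedom points the
# ligand centroid towards +z. Errors on triangle-infeasible plans.
place_ligand_two_distances <- function(ligand, atom1, atom2, r1, r2) {
  p1 <- as.numeric(ligand_coords(ligand, atom1))
  p2 <- as.numeric(ligand_coords(ligand, atom2))
  d12 <- vnorm(p2 - p1)
  if (d12 > r1 + r2 - 1e-6 || d12 < abs(r1 - r2) + 1e-6) {
    stop(sprintf(paste0("infeasible distance plan: |%s-%s| = %.2f A cannot ",
                        "meet planned radii %.2f and %.2f A"),
                 atom1, atom2, d12, r1, r2), call. = FALSE)
  }
  t1 <- c(r1, 0, 0)
  x2 <- (r1^2 + r2^2 - d12^2) / (2 * r1)
  y2 <- sqrt(max(0, r2^2 - x2^2))
  t2 <- c(x2, y2, 0)
  u1 <- unit(p2 - p1)
  cen <- colMeans(as.matrix(ligand$atoms[, c("x", "y", "z")]))
  w <- cen - p1
  w_perp <- w - sum(w * u1) * u1
  if (vnorm(w_perp) < 1e-6) w_perp <- c(0, 0, 1)
  u2 <- unit(w_perp)
  u3 <- cross3(u1, u2)
  e1 <- unit(t2 - t1)
  zc <- c(0, 0, 1)
  e2 <- unit(zc - sum(zc * e1) * e1)  # centroid direction -> +z
  e3 <- cross3(e1, e2)
  rot <- cbind(e1, e2, e3) %*% t(cbind(u1, u2, u3))
  tf <- rigid_transform(rot, t1 - as.numeric(rot %*% p1))
  transform_ligand(ligand, tf)
}

#' Build a synthetic productive-complex fixture
#'
#' Assembles a toy active site around a calcium ion at the origin: an
#' idealized nucleotide placed so two phosphate oxygens from distinct
#' phosphate groups sit at the planned coordination distances, two
#' helical Asp-x-Gly fragments whose aspartate CG atoms sit at the planned
#' DXG distances, four first-shell waters at the planned shell distance,
#' and catalytic plus terminal-phosphate waters. All placements are exact
#' and deterministic; optional seeded Gaussian noise comes last.
#'
#' @param spec a [fixture_spec()].
#' @return a [structure3d()] with chains `A` (scaffold), `L` (nucleotide),
#'   `M` (Ca), `W` (waters), and a `"plan"` attribute recording the ground
#'   truth (coordinating atoms, planted distances).
#' @export
make_toy_complex <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  lig <- make_ideal_nucleotide(spec$kind, spec$P, spec$chi)
  ntp <- lig$n_phosphate == 3
  grp1 <- if (ntp) c("O1B", "O2B") else c("O1A", "O2A")
  grp2 <- if (ntp) c("O1G", "O2G", "O3G") else c("O1B", "O2B", "O3B")
  r1 <- spec$coord_dist[1]; r2 <- spec$coord_dist[2]
  cand <- expand.grid(a = grp1, b = grp2, stringsAsFactors = FALSE)
  cand$d <- apply(cand, 1, function(rw)
    vnorm(as.numeric(ligand_coords(lig, rw["a"])) -
            as.numeric(ligand_coords(lig, rw["b"]))))
  feas <- cand[cand$d < r1 + r2 - 0.3 & cand$d > abs(r1 - r2) + 0.3, ,
               drop = FALSE]
  if (nrow(feas) == 0) {
    stop("infeasible distance plan: no phosphate-oxygen pair can bridge ",
         "the planned coordination distances", call. = FALSE)
  }
  feas <- feas[order(feas$d, feas$a, feas$b), , drop = FALSE]
  pick <- feas[1, ]
  lig <- place_ligand_two_distances(lig, pick$a, pick$b, r1, r2)

  co <- c(0, 0, 0)
  d1v <- unit(as.numeric(ligand_coords(lig, pick$a)))
  d2v <- unit(as.numeric(ligand_coords(lig, pick$b)))
  bis <- unit(d1v + d2v)
  nrm <- unit(cross3(d1v, d2v))

  # scaffold: two DXG helical fragments, anchored by their Asp CG on the
  # far side of the metal from the phosphates, flanking in the
  # coordination plane
  f3 <- unit(cross3(bis, nrm))
  asp_dir1 <- unit(-bis + 0.55 * f3)
  asp_dir2 <- unit(-bis - 0.55 * f3)
  frag1 <- build_helix_fragment(HELIX_SEQ, resno_start = 1L)
  frag2 <- build_helix_fragment(HELIX_SEQ, resno_start = 11L)
  cg1 <- which(frag1$name == "CG")
  cg2 <- which(frag2$name == "CG")
  frag1 <- place_fragment(frag1, cg1, asp_dir1 * spec$dxg_dist[1], asp_dir1)
  frag2 <- place_fragment(frag2, cg2, asp_dir2 * spec$dxg_dist[2], asp_dir2)
  scaffold <- rbind(frag1, frag2)

  # waters: four first-shell, spread away from the nucleotide (which sits
  # on the +n_s side of the coordination plane) and from the aspartates,
  # then catalytic and terminal-phosphate waters
  lig_cen <- unit(colMeans(as.matrix(lig$atoms[, c("x", "y", "z")])))
  n_s <- if (sum(nrm * lig_cen) > 0) nrm else -nrm
  w_dirs <- list(-n_s,
                 unit(-bis - 0.9 * n_s),
                 f3, -f3)
  shell <- t(vapply(w_dirs, function(d) d * spec$shell_dist, numeric(3)))
  term_p <- if (ntp) "PG" else "PB"
  bridge <- if (ntp) "O3B" else "O3A"
  p_xyz <- as.numeric(ligand_coords(lig, term_p))
  axis <- unit(p_xyz - as.numeric(ligand_coords(lig, bridge)))
  w_cat <- p_xyz + 3.3 * axis
  term_o <- setdiff(grp2, pick$b)
  to_xyz <- ligand_coords(lig, term_o)
  far <- term_o[which.max(sqrt(rowSums(to_xyz^2)))]
  f_xyz <- as.numeric(ligand_coords(lig, far))
  w_term <- f_xyz + 2.8 * unit(f_xyz - p_xyz)
  waters <- rbind(shell, w_cat, w_term)

  lig_struct <- nucleotide_to_structure(lig, chain = "L", resno = 1L)$atoms
  cols <- c("serial", "atom", "altloc", "resname", "chain", "resno", "icode",
            "x", "y", "z", "occ", "b", "element")
  mk <- function(df) { df$serial <- 0L; df$altloc <- ""; df$icode <- "";
    df$occ <- 1; df$b <- 0; df[, cols] }
  prot <- data.frame(atom = scaffold$name, resname = scaffold$resname,
                     chain = "A", resno = scaffold$resno,
                     x = scaffold$x, y = scaffold$y, z = scaffold$z,
                     element = guess_element(scaffold$name),
                     stringsAsFactors = FALSE)
  metal <- data.frame(atom = "CA", resname = "CA", chain = "M", resno = 1L,
                      x = co[1], y = co[2], z = co[3], element = "CA",
                      stringsAsFactors = FALSE)
  wat <- data.frame(atom = "O", resname = "HOH", chain = "W",
                    resno = seq_len(nrow(waters)),
                    x = waters[, 1], y = waters[, 2], z = waters[, 3],
                    element = "O", stringsAsFactors = FALSE)
  atoms <- rbind(mk(prot), mk(lig_struct[, setdiff(names(lig_struct),
                                                   "category")]),
                 mk(metal), mk(wat))
  atoms$serial <- seq_len(nrow(atoms))
  out <- structure3d(atoms, id = paste0("toy-", spec$kind),
                     source = "synthetic fixture")
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    out <- set_atom_coords(out, atom_coords(out) +
                             matrix(stats::rnorm(3 * n_atoms(out),
                                                 sd = spec$noise_sigma),
                                    ncol = 3))
  }
  attr(out, "plan") <- list(spec = spec, coordinating = c(pick$a, pick$b),
                            dxg_resno = c(3L, 13L),
                            shell_waters = 4L)
  out
}

#' Rigidly perturb a structure, with optional seeded coordinate noise
#'
#' Applies a rotation about an axis through the centroid, then a
#' translation, then isotropic Gaussian noise (seeded). Noise is applied
#' after the rigid motion, so the planted transform remains the ground
#' truth for superposition-recovery tests.
#'
#' @param structure a [structure3d()].
#' @param rotation_angle degrees.
#' @param axis rotation axis (length-3).
#' @param translation length-3 vector, Angstrom.
#' @param noise_sigma Gaussian sigma per coordinate, Angstrom.
#' @param seed integer seed used when `noise_sigma > 0`.
#' @return the perturbed [structure3d()], with the applied
#'   [rigid_transform()] in attribute `"applied_transform"`.
#' @export
perturb_structure <- function(structure, rotation_angle = 0,
                              axis = c(0, 0, 1), translation = c(0, 0, 0),
                              noise_sigma = 0, seed = 1L) {
  xyz <- atom_coords(structure)
  cen <- colMeans(xyz)
  rot <- rotation_about_axis(axis, rotation_angle)
  tf <- rigid_transform(rot, cen - as.numeric(rot %*% cen) + translation)
  out <- set_atom_coords(structure, transform_coords(xyz, tf))
  if (noise_sigma > 0) {
    set.seed(seed)
    out <- set_atom_coords(out, atom_coords(out) +
                             matrix(stats::rnorm(3 * nrow(xyz), sd = noise_sigma),
                                    ncol = 3))
  }
  attr(out, "applied_transform") <- tf
  out
}
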