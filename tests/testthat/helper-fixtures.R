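# Shared helpers: tiny hand-written PDB records and geometric perturbations
# used across the test files. All fixtures are generated in code.

# minimal fixed-width PDB ATOM/HETATM line
pdb_line <- function(record = "ATOM", serial = 1, name = "CA", altloc = "",
                     resname = "ALA", chain = "A", resno = 1,
                     x = 0, y = 0, z = 0, occ = 1, b = 0, element = "C") {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt, altloc, resname, chain, resno,
          x, y, z, occ, b, element)
}

write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# rotate the nucleobase of a purine ligand about an axis through C1'
# lying in the base plane (perpendicular to the glycosidic bond): keeps the
# glycosidic bond length, moves the whole base by ~the rotation angle
swing_base <- function(lig, angle) {
  ring <- if (lig$base_type == "purine") {
    c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4", "N6", "O6", "N2")
  } else c("N1", "C2", "N3", "C4", "C5", "C6", "O2", "O4")
  ring <- intersect(ring, lig$atoms$name)
  gn <- if (lig$base_type == "purine") "N9" else "N1"
  c1 <- as.numeric(ligand_coords(lig, "C1'"))
  n <- as.numeric(ligand_coords(lig, gn))
  ring_xyz <- ligand_coords(lig, setdiff(ring, gn))
  normal <- svd(sweep(ligand_coords(lig, ring), 2,
                      colMeans(ligand_coords(lig, ring))))$v[, 3]
  axis <- pracma_cross(n - c1, normal)  # in-plane, perpendicular to the bond
  R <- rotation_about_axis(axis, angle)
  idx <- lig$atoms$name %in% ring
  xyz <- as.matrix(lig$atoms[idx, c("x", "y", "z")])
  lig$atoms[idx, c("x", "y", "z")] <- sweep(sweep(xyz, 2, c1) %*% t(R), 2,
                                            c1, "+")
  lig
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# replace the coordinates of the single ligand residue of a structure with
# the (name-matched) coordinates of `lig`
swap_ligand <- function(s, lig) {
  idx <- s$atoms$category == "ligand"
  ord <- match(s$atoms$atom[idx], lig$atoms$name)
  s$atoms[idx, c("x", "y", "z")] <- lig$atoms[ord, c("x", "y", "z")]
  s
}

# random proper rotation + translation (seeded by the caller)
random_rigid <- function() {
  ax <- stats::rnorm(3)
  rigid_transform(rotation_about_axis(ax, stats::runif(1, 0, 360)),
                  stats::rnorm(3, sd = 5))
}
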