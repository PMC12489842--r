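# Extraction, analog conversion, hybrid-diphosphate construction, site-water
# selection and grafting.

analog_complex <- function(kind = "ATP", seed = 1) {
  s <- make_toy_complex(fixture_spec(seed = seed, kind = kind))
  lig <- s$atoms$category == "ligand"
  bridge <- if (substr(kind, 2, 3) == "TP") "O3B" else "O3A"
  i <- which(lig & s$atoms$atom == bridge)
  s$atoms$atom[i] <- sub("^O", "N", bridge)
  s$atoms$element[i] <- "N"
  code <- c(ATP = "ANP", GTP = "GNP", UTP = "UNP",
            ADP = "AN2", GDP = "GN2", UDP = "UN2")[kind]
  s$atoms$resname[lig] <- code
  structure3d(s$atoms, id = s$id, source = s$source)
}

test_that("extract_component detects imido bridges and rejects non-ligands", {
  s3 <- analog_complex("ATP")
  anp <- extract_component(s3, selector(resname = "ANP"))
  expect_equal(anp$n_phosphate, 3L)
  expect_equal(anp$analog_bridge, "N3B")

  s2 <- analog_complex("ADP")
  an2 <- extract_component(s2, selector(resname = "AN2"))
  expect_equal(an2$n_phosphate, 2L)
  expect_equal(an2$analog_bridge, "N3A")

  # a water is not a nucleotide
  expect_error(extract_component(s3, selector(resname = "HOH", resno = 1)),
               "not a small-molecule ligand")
  # multiple matches
  expect_error(extract_component(s3, selector(resname = "HOH")),
               "exactly one")
  expect_error(extract_component(s3, selector(resname = "ZZZ")), "no atoms")
})

test_that("analog conversion changes exactly one atom record, in place", {
  anp <- extract_component(analog_complex("ATP"), selector(resname = "ANP"))
  atp <- analog_to_substrate(anp)
  expect_equal(atp$comp_id, "ATP")
  expect_true(is.na(atp$analog_bridge))
  # set-difference of name lists is exactly {N3B} -> {O3B}
  expect_identical(setdiff(anp$atoms$name, atp$atoms$name), "N3B")
  expect_identical(setdiff(atp$atoms$name, anp$atoms$name), "O3B")
  expect_equal(nrow(atp$atoms), nrow(anp$atoms))
  # every coordinate bit-identical, including the substituted atom
  expect_identical(atp$atoms[, c("x", "y", "z")], anp$atoms[, c("x", "y", "z")])
  # converting twice is refused
  expect_error(analog_to_substrate(atp), "no imido bridge")
  # diphosphate analog maps N3A -> O3A
  an2 <- extract_component(analog_complex("ADP"), selector(resname = "AN2"))
  adp <- analog_to_substrate(an2)
  expect_equal(adp$comp_id, "ADP")
  expect_identical(setdiff(adp$atoms$name, an2$atoms$name), "O3A")
})

test_that("hybrid diphosphates copy the tail exactly and the base rigidly", {
  gtp <- make_ideal_nucleotide("GTP")
  utp <- make_ideal_nucleotide("UTP")
  adp_an <- nucleotide_as_analog(make_ideal_nucleotide("ADP"))
  # move the donors into an arbitrary frame: the fit must not care
  set.seed(3)
  gtp <- transform_ligand(gtp, random_rigid())
  utp <- transform_ligand(utp, random_rigid())

  gdp <- build_hybrid_diphosphate(gtp, adp_an)
  expect_equal(gdp$comp_id, "GDP")
  expect_equal(gdp$n_phosphate, 2L)

  # tail atoms: coordinates equal the tail donor's to 1e-9
  tail <- setdiff(intersect(adp_an$atoms$name, gdp$atoms$name),
                  c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4", "N6"))
  expect_lt(max(abs(ligand_coords(gdp, tail) - ligand_coords(adp_an, tail))),
            1e-9)
  # guanine internal distances preserved from the base donor to 1e-9
  gset <- intersect(c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2",
                      "N3", "C4"), gdp$atoms$name)
  expect_lt(max(abs(dist(ligand_coords(gtp, gset)) -
                      dist(ligand_coords(gdp, gset)))), 1e-9)
  # chemically bonded glycosidic link
  d <- sqrt(sum((ligand_coords(gdp, "C1'") - ligand_coords(gdp, "N9"))^2))
  expect_gt(d, 1.2); expect_lt(d, 1.8)

  # heavy-atom count: UDP = (ADP-analog tail minus adenine) + uracil atoms
  udp <- build_hybrid_diphosphate(utp, adp_an)
  adenine <- c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4")
  uracil <- c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6")
  expect_equal(nrow(udp$atoms),
               nrow(adp_an$atoms) - length(adenine) + length(uracil))
  d2 <- sqrt(sum((ligand_coords(udp, "C1'") - ligand_coords(udp, "N1"))^2))
  expect_gt(d2, 1.2); expect_lt(d2, 1.8)

  # self-hybrid: ADP base on its own tail reproduces the tail donor
  self_h <- build_hybrid_diphosphate(make_ideal_nucleotide("ADP"), adp_an)
  expect_equal(self_h$comp_id, "ADP")
  expect_equal(sort(self_h$atoms$name),
               sort(sub("^O3A$", "N3A", make_ideal_nucleotide("ADP")$atoms$name)))
})

test_that("hybrid construction rejects an incongruent base mapping", {
  gtp <- make_ideal_nucleotide("GTP")
  adp_an <- nucleotide_as_analog(make_ideal_nucleotide("ADP"))
  # corrupt the donor's ring geometry so no rigid fit can reach 1 A
  bad <- gtp
  ring <- bad$atoms$name %in% c("C8", "N7", "C5")
  bad$atoms[ring, c("x", "y", "z")] <- bad$atoms[ring, c("x", "y", "z")] + 3
  expect_error(build_hybrid_diphosphate(bad, adp_an), "RMSD.*exceeds")
  # tail donor must be a diphosphate
  expect_error(build_hybrid_diphosphate(gtp, make_ideal_nucleotide("UTP")),
               "diphosphate")
})

test_that("site-water selection finds 4 + 1 + 1 waters deterministically", {
  s <- make_toy_complex(fixture_spec(seed = 1, kind = "ATP"))
  co <- get_cofactor(s)
  sub <- extract_component(s, selector(resname = "ATP"))
  sw <- select_site_waters(s, co, sub)
  expect_equal(nrow(sw$shell), 4L)
  expect_equal(nrow(sw$catalytic), 1L)
  expect_equal(nrow(sw$terminal), 1L)
  expect_true(sw$complete)
  # catalytic and terminal are distinct from shell members
  expect_false(sw$catalytic$serial %in% sw$shell$serial)
  expect_false(sw$terminal$serial %in% c(sw$shell$serial, sw$catalytic$serial))

  # invariant under water record reordering
  s2 <- s
  wat <- which(s2$atoms$category == "water")
  s2$atoms[wat, ] <- s2$atoms[rev(wat), ]
  sw2 <- select_site_waters(s2, get_cofactor(s2), sub)
  expect_setequal(round(sw2$shell$x, 9), round(sw$shell$x, 9))
  expect_equal(sw2$catalytic[, c("x", "y", "z")],
               sw$catalytic[, c("x", "y", "z")], ignore_attr = TRUE)
})

test_that("missing waters yield a flagged, warning-carrying partial result", {
  s <- make_toy_complex(fixture_spec(seed = 1))
  sub <- extract_component(s, selector(resname = "ATP"))
  dry <- s
  dry$atoms <- dry$atoms[dry$atoms$category != "water", , drop = FALSE]
  expect_warning(sw <- select_site_waters(dry, get_cofactor(dry), sub),
                 "no waters")
  expect_false(sw$complete)
  expect_equal(nrow(sw$shell), 0L)
})

test_that("equidistant waters break ties by lower serial", {
  s <- make_toy_complex(fixture_spec(seed = 1))
  sub <- extract_component(s, selector(resname = "ATP"))
  co <- get_cofactor(s)
  # two extra waters exactly mirrored about the terminal phosphorus axis,
  # equidistant from PG: the lower serial must win the catalytic slot
  pg <- as.numeric(ligand_coords(sub, "PG"))
  o3b <- as.numeric(ligand_coords(sub, "O3B"))
  ax <- (pg - o3b) / sqrt(sum((pg - o3b)^2))
  perp <- c(ax[2], -ax[1], 0); perp <- perp / sqrt(sum(perp^2))
  base <- s$atoms[s$atoms$category != "water", , drop = FALSE]
  p1 <- pg + 3 * ax + 1 * perp
  p2 <- pg + 3 * ax - 1 * perp
  wrow <- function(serial, p) data.frame(
    serial = serial, atom = "O", altloc = "", resname = "HOH", chain = "W",
    resno = serial, icode = "", x = p[1], y = p[2], z = p[3], occ = 1, b = 0,
    element = "O", stringsAsFactors = FALSE)
  cols <- setdiff(names(base), "category")
  s2 <- structure3d(rbind(base[, cols], wrow(900, p1), wrow(901, p2)))
  sw <- suppressWarnings(select_site_waters(s2, get_cofactor(s2), sub))
  expect_equal(sw$catalytic$resno, 900)
})

test_that("self-graft reproduces every transplanted coordinate exactly", {
  s <- make_toy_complex(fixture_spec(seed = 1))
  tgt <- select_atoms(s, selector(category = "polymer"))
  sub <- extract_component(s, selector(resname = "ATP"))
  co <- get_cofactor(s)
  sw <- select_site_waters(s, co, sub)
  sup <- iterative_superpose(s, tgt)
  g <- graft_complex(tgt, s, sup, sub, co, sw)
  expect_lt(max(abs(ligand_coords(g$substrate) - ligand_coords(sub))), 1e-9)
  expect_lt(max(abs(as.numeric(g$cofactor[, c("x", "y", "z")]) -
                      as.numeric(co[, c("x", "y", "z")]))), 1e-9)
  expect_equal(nrow(g$clashes), 0L)
  # exactly 1 ligand residue, 1 metal, 6 waters beyond the target atoms
  grafted <- select_atoms(g$structure, selector(chain = "X"))
  res <- split_residues(grafted)
  cats <- vapply(res, function(r) r$category[1], character(1))
  expect_equal(sum(cats == "ligand"), 1L)
  expect_equal(sum(cats == "metal"), 1L)
  expect_equal(sum(cats == "water"), 6L)
})

test_that("grafting commutes with rigid motion of the target", {
  s <- make_toy_complex(fixture_spec(seed = 2))
  tgt <- select_atoms(s, selector(category = "polymer"))
  sub <- extract_component(s, selector(resname = "ATP"))
  co <- get_cofactor(s)
  sw <- select_site_waters(s, co, sub)
  tgt2 <- perturb_structure(tgt, rotation_angle = 65, axis = c(0, 1, 1),
                            translation = c(3, -2, 5))
  tf <- attr(tgt2, "applied_transform")
  sup <- iterative_superpose(s, tgt2)
  g <- graft_complex(tgt2, s, sup, sub, co, sw)
  # transplanted bundle equals the source bundle under the same rotation
  expect_lt(max(abs(ligand_coords(g$substrate) -
                      transform_coords(ligand_coords(sub), tf))), 1e-8)
  # intra-bundle geometry rigid
  b0 <- rbind(ligand_coords(sub),
              as.matrix(sw$shell[, c("x", "y", "z")]))
  b1 <- rbind(ligand_coords(g$substrate),
              as.matrix(g$waters$shell[, c("x", "y", "z")]))
  expect_lt(max(abs(dist(b0) - dist(b1))), 1e-9)
  # provenance records the source and components
  expect_equal(g$provenance$components, c("substrate", "cofactor", "waters"))
})

test_that("graft refuses a colliding chain id and reports clashes", {
  s <- make_toy_complex(fixture_spec(seed = 1))
  tgt <- select_atoms(s, selector(category = "polymer"))
  sub <- extract_component(s, selector(resname = "ATP"))
  expect_error(graft_complex(tgt, s, identity_transform(), sub,
                             graft_chain = "A"), "already exists")
  # a deliberately wrong transform buries the ligand in the scaffold:
  # clashes are reported, not silently dropped
  helix_cen <- colMeans(atom_coords(tgt))
  bad_tf <- rigid_transform(diag(3), helix_cen -
                              colMeans(ligand_coords(sub)))
  expect_warning(g <- graft_complex(tgt, s, bad_tf, sub), "clash")
  expect_gt(nrow(g$clashes), 0)
})
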