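# Productive-complex validators: bidentate coordination, DXG motifs,
# hydration shell, H-bonds, clashes, pucker, chi, base-plane angle, and the
# binding-mode classifier.

toy <- make_toy_complex(fixture_spec(seed = 1, kind = "ATP"))
toy_ref <- extract_component(toy, selector(resname = "ATP"))

test_that("bidentate check requires two oxygens from distinct phosphate groups", {
  bid <- check_bidentate(toy)
  expect_true(bid$bidentate)
  expect_gte(nrow(bid$contacts), 2)
  expect_gte(length(unique(bid$contacts$group)), 2)

  # cofactor 8 A away -> no coordination
  far <- toy
  far$atoms[far$atoms$category == "metal", c("x", "y", "z")] <-
    c(8, 8, 8) / sqrt(3)
  expect_false(check_bidentate(far)$bidentate)

  # coordinating oxygens from a single phosphate group only -> not
  # bidentate: push the whole gamma group out of the coordination window
  same <- toy
  gamma <- same$atoms$category == "ligand" &
    same$atoms$atom %in% c("PG", "O1G", "O2G", "O3G")
  same$atoms[gamma, c("x", "y", "z")] <-
    same$atoms[gamma, c("x", "y", "z")] + 5
  bid_same <- check_bidentate(same)
  expect_false(bid_same$bidentate)
  expect_gte(nrow(bid_same$contacts), 1)   # the beta oxygen still binds
  expect_equal(unique(bid_same$contacts$group), "beta")

  no_metal <- select_atoms(toy, selector(category = c("polymer", "ligand",
                                                      "water")))
  expect_error(check_bidentate(no_metal), "cofactor")
})

test_that("DXG motif search finds the two planted aspartates in order", {
  m <- find_dxg_motifs(toy)
  expect_s3_class(m, "motif_annotation")
  expect_equal(m$resno, c(3L, 13L))
  expect_equal(m$resname, c("ASP", "ASP"))

  d <- dxg_distances(toy, m)
  expect_equal(d, c(4.80, 4.84), tolerance = 1e-6)

  # distances invariant under a rigid transform of the whole structure
  set.seed(12)
  moved <- apply_transform(toy, random_rigid())
  expect_equal(dxg_distances(moved, find_dxg_motifs(moved)), d,
               tolerance = 1e-9)

  # a single candidate is an annotation error suggesting an override
  one <- toy
  drop2 <- one$atoms$chain == "A" & one$atoms$resno >= 11
  one$atoms <- one$atoms[!drop2, , drop = FALSE]
  expect_error(find_dxg_motifs(one), "override")

  # explicit override skips the pattern search
  ov <- find_dxg_motifs(toy, override = c(3L, 13L))
  expect_equal(ov$resno, c(3L, 13L))
})

test_that("hydration-shell count is a clean monotone census", {
  expect_equal(hydration_shell_count(toy)$count, 4L)
  expect_equal(hydration_shell_count(toy, cutoff = 0)$count, 0L)
  cuts <- seq(0.5, 8, by = 0.5)
  counts <- vapply(cuts, function(cc) hydration_shell_count(toy, cutoff = cc)$count,
                   integer(1))
  expect_true(all(diff(counts) >= 0L))
})

test_that("geometric H-bond detection honors the distance cutoff", {
  mk_pair <- function(d) {
    structure3d(data.frame(
      atom = c("OD1", "N9"), resname = c("ASP", "ADE"), chain = c("A", "B"),
      resno = c(1, 2), x = c(0, d), y = 0, z = 0, element = c("O", "N"),
      stringsAsFactors = FALSE))
  }
  hb <- detect_hbonds(mk_pair(2.8),
                      between = list(selector(chain = "A"), selector(chain = "B")))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.8)
  hb2 <- detect_hbonds(mk_pair(4.0), d_max = 3.5,
                       between = list(selector(chain = "A"), selector(chain = "B")))
  expect_equal(nrow(hb2), 0L)

  # the toy complex shows conserved polar contacts around the site
  expect_gt(nrow(detect_hbonds(toy)), 0)
})

test_that("steric clash detection follows the vdW-overlap arithmetic", {
  two_c <- structure3d(data.frame(
    atom = c("C1", "C2"), resname = c("LIG", "LIG"), chain = c("A", "B"),
    resno = c(1, 2), x = c(0, 1.0), y = 0, z = 0, element = "C",
    stringsAsFactors = FALSE))
  cl <- steric_clashes(two_c, overlap_factor = 0.6)
  expect_equal(nrow(cl), 1L)       # 1.0 < 0.6 * 3.4
  expect_equal(cl$vdw_sum, 3.4)
  expect_equal(nrow(steric_clashes(two_c, overlap_factor = 0.25)), 0L)

  # count is monotone non-increasing as the factor decreases
  s <- perturb_structure(toy, noise_sigma = 0.35, seed = 5)
  fs <- c(0.8, 0.6, 0.4, 0.2)
  ns <- vapply(fs, function(f) nrow(steric_clashes(s, overlap_factor = f)),
               integer(1))
  expect_true(all(diff(ns) <= 0L))

  # the clean reference fixture has no clashes at the default factor
  expect_equal(nrow(steric_clashes(toy)), 0L)
})

test_that("pucker classification matches the constructed phase", {
  lig_c2 <- make_ideal_nucleotide("ATP", P = 162, chi = -120)
  p1 <- ribose_pucker(lig_c2)
  expect_equal(p1$P, 162, tolerance = 0.2)
  expect_equal(p1$cls, "C2'-endo")

  lig_c3 <- make_ideal_nucleotide("ATP", P = 18, chi = -120)
  p2 <- ribose_pucker(lig_c3)
  expect_equal(p2$P, 18, tolerance = 0.2)
  expect_equal(p2$cls, "C3'-endo")

  lig_other <- make_ideal_nucleotide("ATP", P = 90, chi = -120)
  expect_equal(ribose_pucker(lig_other)$cls, "other")

  broken <- lig_c2
  broken$atoms <- broken$atoms[broken$atoms$name != "O4'", , drop = FALSE]
  expect_error(ribose_pucker(broken), "missing")
})

test_that("pucker phase agrees with the brute-force cosine-model oracle", {
  # independent oracle: grid-fit nu_j = tau * cos(P + 144 j) over P,
  # coarse 0.5-degree pass refined to a 0.01-degree grid around the best P
  oracle_P <- function(nu) {
    j <- 0:4
    tau_at <- function(P) {
      cj <- cos(pi / 180 * (P + 144 * (j - 2)))
      sum(nu * cj) / sum(cj^2)
    }
    sse_at <- function(Ps) {
      vapply(Ps, function(P) {
        cj <- cos(pi / 180 * (P + 144 * (j - 2)))
        sum((nu - tau_at(P) * cj)^2)
      }, numeric(1))
    }
    coarse <- seq(0, 359.5, by = 0.5)
    p0 <- coarse[which.min(sse_at(coarse))]
    fine <- seq(p0 - 0.6, p0 + 0.6, by = 0.01)
    best <- fine[which.min(sse_at(fine))]
    # disambiguate the (P, tau) vs (P + 180, -tau) degeneracy by the
    # standard convention tau_m > 0
    if (tau_at(best) < 0) best <- best + 180
    best %% 360
  }
  # 1000 random puckered rings drawn in torsion space: the closed-form
  # phase must match the grid fit to 0.1 degree
  set.seed(99)
  for (k in seq_len(1000)) {
    P_true <- stats::runif(1, 0, 360)
    tau <- stats::runif(1, 25, 45)
    nu <- tau * cos(pi / 180 * (P_true + 144 * (-2:2))) +
      stats::rnorm(5, sd = 0.02)
    res <- pucker_from_torsions(nu)
    po <- oracle_P(nu)
    dd <- abs(((res$P - po + 180) %% 360) - 180)
    expect_lt(dd, 0.1)
    expect_lt(abs(((res$P - P_true + 180) %% 360) - 180), 0.5)
  }

  # full-coordinate path: 3D puckered pentagons carry a small anharmonic
  # distortion, so the estimators agree to degree scale and always fall in
  # the same classification window
  ring_names <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  lig <- make_ideal_nucleotide("ATP")
  for (k in seq_len(200)) {
    psi <- stats::runif(1, 0, 360)
    amp <- stats::runif(1, 0.25, 0.5)
    th <- pi / 180 * (90 + 72 * (0:4))
    ringxyz <- cbind(1.26 * cos(th), 1.26 * sin(th),
                     amp * cos(pi / 180 * (psi + 144 * (0:4))))
    idx <- match(ring_names, lig$atoms$name)
    lig$atoms[idx, c("x", "y", "z")] <- ringxyz
    res <- ribose_pucker(lig)
    po <- oracle_P(res$nu)
    expect_lt(abs(((res$P - po + 180) %% 360) - 180), 2)
  }
})

test_that("glycosidic chi classification separates anti from syn", {
  expect_equal(glycosidic_chi(make_ideal_nucleotide("ATP", chi = -120))$cls,
               "anti")
  expect_equal(glycosidic_chi(make_ideal_nucleotide("ATP", chi = 60))$cls,
               "syn")
  expect_equal(glycosidic_chi(make_ideal_nucleotide("UTP", chi = 170))$cls,
               "anti")
  ch <- glycosidic_chi(make_ideal_nucleotide("GTP", chi = -120))
  expect_equal(ch$chi, -120, tolerance = 1e-6)
  broken <- make_ideal_nucleotide("ATP")
  broken$atoms <- broken$atoms[broken$atoms$name != "C4", , drop = FALSE]
  expect_error(glycosidic_chi(broken), "missing")
})

test_that("base-plane angle is 0 for self, equals an in-plane rotation, folds to [0,90]", {
  atp <- make_ideal_nucleotide("ATP")
  expect_equal(base_plane_angle(atp, atp), 0, tolerance = 1e-6)
  for (ang in c(30, 60, 90, 120)) {
    swung <- swing_base(atp, ang)
    expect_equal(base_plane_angle(swung, atp), min(ang, 180 - ang),
                 tolerance = 1e-6)
  }
  # degenerate ring -> geometry error
  flat <- atp
  ring <- flat$atoms$name %in% c("N9", "C8", "N7", "C5", "C6", "N1", "C2",
                                 "N3", "C4")
  flat$atoms[ring, "y"] <- flat$atoms[ring, "x"]
  flat$atoms[ring, "z"] <- flat$atoms[ring, "x"]
  flat$atoms[ring, "x"] <- flat$atoms[ring, "x"]
  expect_error(base_plane_angle(flat, atp), "degenerate|collinear")
})

test_that("binding-mode classifier separates canonical, alternative, nonproductive", {
  refs <- canonical_reference(ntp_reference = toy_ref)
  # canonical: the reference complex against itself
  rep_c <- classify_binding_mode(toy, refs)
  expect_equal(rep_c$mode, "canonical")
  expect_equal(rep_c$substrate_rmsd_vs_reference, 0, tolerance = 1e-9)
  expect_true(rep_c$bidentate)
  expect_equal(rep_c$shell_water_count, 4L)
  expect_true(rep_c$catalytic_water_present)
  expect_equal(rep_c$dxg_distances, c(4.80, 4.84), tolerance = 1e-6)

  # alternative: phosphate/ribose aligned, base swung ~90 degrees
  alt <- swap_ligand(toy, swing_base(toy_ref, 90))
  rep_a <- classify_binding_mode(alt, refs)
  expect_equal(rep_a$mode, "alternative")
  expect_gt(rep_a$base_plane_angle_vs_reference, 45)
  expect_lt(rep_a$phosphate_ribose_rmsd, 0.5)
  expect_gt(rep_a$substrate_rmsd_vs_reference, rep_a$rmsd_threshold)

  # nonproductive: whole substrate displaced out of the site
  off <- toy_ref
  off$atoms[, c("x", "y", "z")] <- off$atoms[, c("x", "y", "z")] + 4
  rep_n <- classify_binding_mode(swap_ligand(toy, off), refs)
  expect_equal(rep_n$mode, "nonproductive")

  # phosphate-count mismatch with the only reference -> input error
  toy_adp <- make_toy_complex(fixture_spec(seed = 1, kind = "ADP"))
  expect_error(classify_binding_mode(toy_adp, refs), "phosphate count")
  # and an NDP reference fixes it
  adp_ref <- extract_component(toy_adp, selector(resname = "ADP"))
  rep_d <- classify_binding_mode(toy_adp,
                                 canonical_reference(ndp_reference = adp_ref))
  expect_equal(rep_d$mode, "canonical")
})

test_that("validators are invariant under rigid motion and record permutation", {
  refs <- canonical_reference(ntp_reference = toy_ref)
  rep0 <- classify_binding_mode(toy, refs)

  set.seed(77)
  tf <- random_rigid()
  moved <- apply_transform(toy, tf)
  moved_ref <- transform_ligand(toy_ref, tf)
  rep1 <- classify_binding_mode(moved,
                                canonical_reference(ntp_reference = moved_ref))
  expect_equal(rep1$substrate_rmsd_vs_reference,
               rep0$substrate_rmsd_vs_reference, tolerance = 1e-9)
  expect_equal(rep1$dxg_distances, rep0$dxg_distances, tolerance = 1e-9)
  expect_equal(rep1$shell_water_count, rep0$shell_water_count)
  expect_equal(rep1$bidentate, rep0$bidentate)
  expect_equal(rep1$pucker$P, rep0$pucker$P, tolerance = 1e-6)
  expect_equal(rep1$chi$chi, rep0$chi$chi, tolerance = 1e-6)
  expect_equal(rep1$mode, rep0$mode)

  # permute atom records
  set.seed(5)
  perm <- toy
  ordx <- sample(nrow(perm$atoms))
  perm$atoms <- perm$atoms[ordx, , drop = FALSE]
  expect_equal(check_bidentate(perm)$bidentate, check_bidentate(toy)$bidentate)
  expect_equal(hydration_shell_count(perm)$count,
               hydration_shell_count(toy)$count)
  expect_equal(nrow(steric_clashes(perm)), nrow(steric_clashes(toy)))
})

test_that("closed-state verification flags an opened ACR4", {
  template <- toy
  model <- select_atoms(toy, selector(category = "polymer"))
  r <- validate_closed_state(model, template)
  expect_lt(r$rmsd, 1e-9)
  expect_true(r$closed)
  expect_equal(r$dd_model, r$dd_template, tolerance = 1e-9)

  # rotate/translate the second DXG fragment away along the Asp-Asp axis
  open_model <- model
  a <- open_model$atoms
  cg <- function(rn) as.numeric(a[a$resno == rn & a$atom == "CG",
                                  c("x", "y", "z")])
  axis <- cg(13) - cg(3)
  axis <- 6 * axis / sqrt(sum(axis^2))
  idx <- a$resno >= 11
  open_model$atoms[idx, c("x", "y", "z")] <-
    sweep(as.matrix(a[idx, c("x", "y", "z")]), 2, axis, "+")
  r2 <- validate_closed_state(open_model, template)
  expect_false(r2$closed)
  expect_gt(r2$dd_model - r2$dd_template, 2)
})
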