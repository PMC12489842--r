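#' Pipeline configuration
#'
#' All tunables of the transfer-and-validate workflow with documented
#' defaults; an empty configuration reproduces the documented behavior.
#' Serializable to/from JSON via [write_run_config()] / [read_run_config()].
#'
#' @param cycles superposition outlier-rejection cycles.
#' @param reject_cutoff rejection cutoff, Angstrom.
#' @param rmsd_threshold canonical-mode RMSD threshold, Angstrom.
#' @param coord_min,coord_max bidentate coordination window, Angstrom.
#' @param shell_cutoff first-hydration-shell cutoff, Angstrom.
#' @param terminal_cutoff terminal-phosphate water cutoff, Angstrom.
#' @param clash_factor vdW overlap factor for clash detection.
#' @param hbond_dmax H-bond heavy-atom distance cutoff, Angstrom.
#' @param graft_chain chain identifier for transplanted residues.
#' @param cache_dir PDB download cache directory.
#' @param convert_analog convert imido analogs to true substrates?
#' @param allow_nonproductive exit cleanly even when validation says
#'   nonproductive?
#' @return a `run_config` object (a named list).
#' @export
run_config <- function(cycles = 5, reject_cutoff = 2.0, rmsd_threshold = 1.5,
                       coord_min = 2.0, coord_max = 3.0, shell_cutoff = 3.2,
                       terminal_cutoff = 4.0, clash_factor = 0.6,
                       hbond_dmax = 3.5, graft_chain = "X",
                       cache_dir = default_cache_dir(),
                       convert_analog = TRUE, allow_nonproductive = FALSE) {
  structure(list(cycles = cycles, reject_cutoff = reject_cutoff,
                 rmsd_threshold = rmsd_threshold, coord_min = coord_min,
                 coord_max = coord_max, shell_cutoff = shell_cutoff,
                 terminal_cutoff = terminal_cutoff,
                 clash_factor = clash_factor, hbond_dmax = hbond_dmax,
                 graft_chain = graft_chain, cache_dir = cache_dir,
                 convert_analog = convert_analog,
                 allow_nonproductive = allow_nonproductive),
            class = "run_config")
}

#' @param config a `run_config`.
#' @param path JSON file path.
#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}

#' Transfer a crystallographic substrate into a target model and validate
#'
#' The full workflow: sequence-guided iterative superposition of the source
#' complex onto the target model, transplantation of substrate + cofactor +
#' conserved site waters, optional analog-to-substrate conversion, and the
#' productive-binding validation against canonical references.
#'
#' @param target a [structure3d()] target model, or a file path.
#' @param source a [structure3d()] solved complex, a file path, or a
#'   4-character PDB accession (fetched through the cache).
#' @param substrate_resname component code of the substrate to extract from
#'   the source (e.g. `"ANP"`).
#' @param references a [canonical_reference()]; when `NULL`, the source's
#'   own (converted) substrate is used as the matching reference, so a
#'   self-graft validates as canonical by construction.
#' @param config a [run_config()].
#' @param out_dir when given, writes `complex.pdb`, `report.json` and
#'   `provenance.json` there.
#' @return list with `graft` (a `grafted_complex`), `report` (a
#'   `validation_report`), and `superposition`.
#' @export
run_pipeline <- function(target, source, substrate_resname,
                         references = NULL, config = run_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  load_struct <- function(x) {
    if (inherits(x, "structure3d")) return(x)
    if (is.character(x) && grepl("^[A-Za-z0-9]{4}$", x) && !file.exists(x)) {
      return(fetch_reference(x, config$cache_dir))
    }
    read_structure(x)
  }
  target <- load_struct(target)
  source <- load_struct(source)

  substrate <- extract_component(source, selector(resname = substrate_resname))
  if (config$convert_analog && !is.na(substrate$analog_bridge)) {
    substrate <- analog_to_substrate(substrate)
  }
  cofactor <- get_cofactor(source)
  waters <- suppressWarnings(
    select_site_waters(source, cofactor, substrate,
                       shell_cutoff = config$shell_cutoff,
                       terminal_cutoff = config$terminal_cutoff))

  sup <- iterative_superpose(source, target,
                             cycles = config$cycles,
                             reject_cutoff = config$reject_cutoff)
  graft <- suppressWarnings(
    graft_complex(target, source, sup, substrate, cofactor, waters,
                  graft_chain = config$graft_chain,
                  clash_factor = config$clash_factor))

  if (is.null(references)) {
    ref_lig <- transform_ligand(substrate, sup$transform)
    references <- if (ref_lig$n_phosphate == 3) {
      canonical_reference(ntp_reference = ref_lig)
    } else {
      canonical_reference(ndp_reference = ref_lig)
    }
  }
  report <- classify_binding_mode(graft, references,
                                  rmsd_threshold = config$rmsd_threshold,
                                  coord_min = config$coord_min,
                                  coord_max = config$coord_max,
                                  shell_cutoff = config$shell_cutoff)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_structure(graft$structure, file.path(out_dir, "complex.pdb"))
    write_validation_report(report, file.path(out_dir, "report.json"),
                            config = config)
    jsonlite::write_json(provenance_json(graft),
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(graft = graft, report = report, superposition = sup)
}

#' Write a validation report as versioned JSON
#'
#' @param report a `validation_report`.
#' @param path output JSON path.
#' @param config optional [run_config()] recorded (with a hash) for
#'   reproducibility.
#' @export
write_validation_report <- function(report, path, config = NULL) {
  out <- list(
    schema = "substrategraft/validation-report/v1",
    mode = report$mode,
    substrate = report$substrate,
    reference = report$reference,
    substrate_rmsd_vs_reference = report$substrate_rmsd_vs_reference,
    phosphate_ribose_rmsd = report$phosphate_ribose_rmsd,
    rmsd_threshold = report$rmsd_threshold,
    bidentate = report$bidentate,
    bidentate_contacts = report$bidentate_contacts,
    dxg_distances = report$dxg_distances,
    shell_water_count = report$shell_water_count,
    catalytic_water_present = report$catalytic_water_present,
    n_hbonds = nrow(report$hbonds),
    hbonds = report$hbonds,
    n_clashes = nrow(report$clashes),
    clashes = report$clashes,
    pucker = list(P = report$pucker$P, tau_m = report$pucker$tau_m,
                  cls = report$pucker$cls),
    chi = list(chi = report$chi$chi, cls = report$chi$cls),
    base_plane_angle_vs_reference = report$base_plane_angle_vs_reference)
  if (!is.null(config)) {
    cfg <- unclass(config)
    out$config <- cfg
    out$config_hash <- paste0("crc32-", format(sum(utf8ToInt(
      paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                               character(1)), collapse = ";"))), scientific = FALSE))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

provenance_json <- function(graft) {
  p <- graft$provenance
  list(schema = "substrategraft/provenance/v1",
       source = p$source, source_path = p$source_path, target = p$target,
       graft_chain = graft$graft_chain,
       rotation = p$transform$rotation,
       translation = p$transform$translation,
       components = p$components,
       n_clashes = nrow(graft$clashes))
}
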