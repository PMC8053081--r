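#' Default pipeline configuration
#'
#' Nested list of every tunable parameter of the end-to-end simulate ->
#' measure -> summarize pipeline, with the assay defaults: CCA
#' single-stranded motif, 12% i.i.d. occupancy, 94.2% mean stretch at
#' 0.34 nm/bp, 0.92 quantum-dot labeling probability, 300 nm resolution.
#' The synthetic genome default is a 48,502 bp linear molecule, the size of
#' the lambda standard.
#'
#' @return A `ptomap_config` object (validated nested list).
#' @export
default_config <- function() {
  cfg <- list(
    genome = list(fasta = NULL,
                  synthetic = list(length = 48502L, gc = 0.5)),
    motif = list(recognition = "CCA", mode = "single_stranded",
                 linkage_offset = 1L),
    modification = list(f = 0.12, mode = "iid", rho = 0),
    chemistry = list(p_label_nick = 0.8, bg_nick_rate = 1e-6,
                     d_break = 500, p_label_qd = 0.92, p_end_label = 0.7),
    optics = list(nm_per_bp_B = 0.34, stretch_mean = 0.942,
                  stretch_sd = 0.02, resolution_nm = 300,
                  localization_sd_nm = 50, pixel_nm = 100,
                  psf_sigma_nm = 150),
    simulate = list(n_molecules = 500L, length_model = "fixed",
                    length_bp = NULL, meanlog = log(20e3), sdlog = 0.5),
    measurement = list(expected_genome_kb = NULL, length_tol = 0.05,
                       n_standards = 100L,
                       bin_edges_kb = default_bin_edges_kb,
                       dissimilarity_bin_kb = 2,
                       bootstrap_B = 1000L),
    seed = 1L)
  structure(cfg, class = "ptomap_config")
}

# recursive unknown-key check against the default skeleton
check_keys <- function(user, ref, path = character(0)) {
  extra <- setdiff(names(user), names(ref))
  if (length(extra) > 0)
    stop("unknown config key: ",
         paste(c(path, extra[1]), collapse = "."))
  for (nm in names(user))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_keys(as.list(user[[nm]]), ref[[nm]], c(path, nm))
  invisible(TRUE)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.null(user[[nm]])) next   # NULL means "keep the default"
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(user[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  # constructors carry the range checks and name the offending field
  motif_spec(cfg$motif$recognition, cfg$motif$mode, cfg$motif$linkage_offset)
  modification_model(cfg$modification$f, cfg$modification$mode,
                     cfg$modification$rho)
  do.call(chemistry_params, cfg$chemistry)
  do.call(optics_params, cfg$optics)
  if (cfg$simulate$n_molecules < 1) stop("n_molecules must be >= 1")
  if (cfg$measurement$length_tol < 0) stop("length_tol must be >= 0")
  if (!is.null(cfg$genome$fasta) && !file.exists(cfg$genome$fasta))
    stop("missing fasta: ", cfg$genome$fasta)
  invisible(cfg)
}

#' Load, validate and dump pipeline configurations
#'
#' Configurations are YAML. Keys absent from the file take the
#' [default_config()] values; unknown keys are rejected with the offending
#' key named; out-of-range values are rejected by the same validators the
#' pipeline itself uses.
#'
#' @param path YAML file path (for `load_config`) / output path (for
#'   `dump_config`).
#' @param overrides Optional named list merged over the file contents.
#' @return `load_config`: a validated `ptomap_config`.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  base <- default_config()
  user <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else list()
  if (is.null(user)) user <- list()
  check_keys(user, base)
  cfg <- merge_config(unclass(base), user)
  if (!is.null(overrides)) {
    check_keys(overrides, base)
    cfg <- merge_config(cfg, overrides)
  }
  cfg <- structure(cfg, class = "ptomap_config")
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param cfg A `ptomap_config`.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ptomap_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Derive a stage-specific RNG seed
#'
#' Each pipeline stage draws from its own substream seeded by a
#' deterministic hash of the master seed and the stage name, so changing
#' one stage's parameters never perturbs another stage's draws.
#'
#' @param seed Master integer seed.
#' @param stage Stage name.
#' @return An integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 65537) %% (2^31 - 1))
}

#' Simulate combed calibration standards
#'
#' Draws `n` independent stretch fractions and returns the measured lengths
#' (um) of full-length standards of size `genome_size_bp`.
#'
#' @param genome_size_bp Standard genome size (bp).
#' @param n Number of standards.
#' @param params An [optics_params()].
#' @return Numeric vector of lengths in um.
#' @export
simulate_standards <- function(genome_size_bp, n, params) {
  vapply(seq_len(n), function(i) {
    genome_size_bp * params$nm_per_bp_B * draw_stretch(params) / 1000
  }, numeric(1))
}

#' Run the end-to-end pipeline
#'
#' Executes scan -> sample -> modify -> label -> comb/collapse -> calibrate
#' -> select -> spacings -> statistics, writing all artifacts to `out_dir`:
#' `sites.bed`, `molecules.tsv`, `fragments.tsv`, `spots.tsv`,
#' `spacings.tsv`, `summary.json` and `run.log`. Identical config + seed
#' give byte-identical tabular outputs.
#'
#' @param cfg A `ptomap_config` (or path to a YAML config).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages (default TRUE).
#' @return Invisibly, a list with the in-memory results (`sites`,
#'   `calibration`, `records`, `selected`, `spacings`, `histogram`,
#'   `density`, `heterogeneity`, `summary`).
#' @export
run_pipeline <- function(cfg, out_dir, quiet = TRUE) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "ptomap_config"))
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, paste0("[", length(log_lines) + 1L, "] ", msg))
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  seed <- cfg$seed
  say("ptomap ", as.character(utils::packageVersion("ptomap")),
      " master seed ", seed)

  genome <- stage("genome", {
    if (!is.null(cfg$genome$fasta)) read_genome(cfg$genome$fasta)
    else random_genome(c(synthetic = cfg$genome$synthetic$length),
                       gc = cfg$genome$synthetic$gc,
                       seed = derive_seed(seed, "genome"))
  })
  contig <- names(genome)[1]
  genome_bp <- nchar(as.character(genome[[contig]]))

  spec <- motif_spec(cfg$motif$recognition, cfg$motif$mode,
                     cfg$motif$linkage_offset)
  sites <- stage("scan", scan_motifs(genome, spec))
  write_bed(sites[sites$contig == contig, ], file.path(out_dir, "sites.bed"))
  say("scan: ", nrow(sites), " sites")

  model <- modification_model(cfg$modification$f, cfg$modification$mode,
                              cfg$modification$rho)
  templates <- stage("sample", sample_molecules(
    genome, cfg$simulate$n_molecules, sites,
    length_model = cfg$simulate$length_model,
    length_bp = cfg$simulate$length_bp, meanlog = cfg$simulate$meanlog,
    sdlog = cfg$simulate$sdlog, contig = contig,
    seed = derive_seed(seed, "sample")))

  set.seed(derive_seed(seed, "modify"))
  mols <- stage("modify", lapply(templates, place_modifications, model))
  write_molecule_table(mols, file.path(out_dir, "molecules.tsv"))

  chem <- do.call(chemistry_params, cfg$chemistry)
  set.seed(derive_seed(seed, "label"))
  fragments <- stage("label", {
    fl <- lapply(mols, function(m) {
      fr <- if (spec$mode == "single_stranded")
        simulate_nick_labeling(m, chem)
      else list(simulate_qd_labeling(m, chem))
      lapply(fr, attach_end_label, chem)
    })
    unlist(fl, recursive = FALSE)
  })
  write_fragment_table(fragments, file.path(out_dir, "fragments.tsv"))
  say("label: ", length(fragments), " fragments from ", length(mols),
      " molecules")

  optics <- do.call(optics_params, cfg$optics)
  set.seed(derive_seed(seed, "optics"))
  tab <- stage("optics", observe_fragments(fragments, optics))
  write_spot_table(tab, file.path(out_dir, "spots.tsv"))

  set.seed(derive_seed(seed, "standards"))
  std <- stage("calibrate",
               simulate_standards(genome_bp, cfg$measurement$n_standards,
                                  optics))
  calib <- calibrate(std, genome_bp, optics$nm_per_bp_B)
  say("calibrate: stretch ", signif(calib$stretch_fraction, 4),
      ", kb/um ", signif(calib$kb_per_um, 4))

  expected_kb <- cfg$measurement$expected_genome_kb %||% (genome_bp / 1000)
  recs <- stage("measure", molecule_records(tab, calib))
  sel <- stage("select",
               select_molecules(recs, expected_kb,
                                cfg$measurement$length_tol))
  sp <- stage("spacings", neighbor_spacings(sel))
  utils::write.table(as.data.frame(sp), file.path(out_dir, "spacings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("select: ", nrow(sel$records), " molecules, ", nrow(sp), " spacings")

  hist <- spacing_histogram(sp$distance_kb, cfg$measurement$bin_edges_kb)
  het <- stage("heterogeneity",
               spots_per_molecule(sel, cfg$measurement$dissimilarity_bin_kb))
  p_label <- if (spec$mode == "single_stranded") chem$p_label_nick
             else chem$p_label_qd
  motif_density <- nrow(sites) / (genome_bp / 1000)
  resolution_kb <- optics$resolution_nm / 1000 * calib$kb_per_um
  density <- NULL
  if (nrow(sp) > 0 && mean(sp$distance_kb) > resolution_kb) {
    density <- stage("density", estimate_density(
      sp$distance_kb, resolution_kb, motif_density, p_label,
      B = cfg$measurement$bootstrap_B,
      seed = derive_seed(seed, "bootstrap")))
  }

  summary <- list(
    package = "ptomap",
    version = as.character(utils::packageVersion("ptomap")),
    seed = seed,
    genome = list(contig = contig, length_bp = genome_bp),
    motif = list(recognition = spec$recognition, mode = spec$mode,
                 n_sites = nrow(sites),
                 density_per_kb = motif_density),
    n_molecules = length(mols),
    n_fragments = length(fragments),
    n_selected = nrow(sel$records),
    no_data = nrow(sp) == 0,
    calibration = list(kb_per_um = calib$kb_per_um,
                       stretch_fraction = calib$stretch_fraction,
                       n_standards = calib$n_standards),
    spacing_histogram = list(bin_edges_kb = hist$bin_edges_kb,
                             counts = hist$counts,
                             fractions = hist$fractions,
                             n = hist$n),
    spots_per_molecule = as.list(stats::setNames(
      as.integer(het$spots_per_molecule),
      names(het$spots_per_molecule))),
    mean_pairwise_dissimilarity = het$mean_pairwise_dissimilarity,
    density = if (is.null(density)) NULL else
      list(lambda_eff_per_kb = density$lambda_eff, f_hat = density$f_hat,
           ci_low = density$ci_low, ci_high = density$ci_high,
           n_gaps = density$n_gaps))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(config = cfg, sites = sites, calibration = calib,
                 records = recs, selected = sel, spacings = sp,
                 histogram = hist, density = density, heterogeneity = het,
                 summary = summary))
}
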