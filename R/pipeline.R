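# End-to-end orchestration: simulate (or load) -> calibrate -> histogram ->
# peaks -> FDR -> annotate -> curate -> redox -> quant -> categories ->
# waves -> enrichment, from a single config, with a run manifest.

.OXWAVE_STAGES <- c("simulate", "calibrate", "histogram", "peaks", "fdr",
                    "annotate", "curate", "redox", "quant", "categories",
                    "waves", "enrichment")

.default_thresholds <- function() {
  list(
    fdr = 0.01,            # identification q-value threshold
    min_score = 0.15,      # recalibration quality gate
    ppm_window = 20,
    bin_width = 0.001,     # Da
    min_count = NULL,      # peak apex threshold; NULL = 5 x median bin count
    match_tol = 0.01,      # Da, annotation matching
    min_replicates = 4L,   # curation replicate-detection threshold
    redox_tol = 0.01,      # Da, alkylation-tag matching
    category_alpha = 0.05, # BH q threshold for categories
    min_size = 5L, max_size = 500L,
    min_psms = 50L,        # enrichment reporting threshold
    k_clusters = 2L, linkage = "average",
    zp_filter = "max_gt", zp_threshold = 0
  )
}

#' Derive a per-stage seed from the single run seed
#'
#' Stage `i` uses `(seed * 101 + i * 7919) mod (2^31 - 1)`, so each stage
#' is independently reproducible from the run seed.
#'
#' @param seed Integer run seed.
#' @param stage_index 1-based stage index.
#' @return An integer seed below 2^31.
#' @export
derive_stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 101 + stage_index * 7919) %% (2^31 - 1))
}

#' Load and validate a pipeline configuration
#'
#' @param config A YAML file path or a list. Top-level keys: `seed`
#'   (integer), exactly one of `simulation` (arguments to [sim_config()])
#'   or `input` (paths `psm_table`, `design`, optional `categories`,
#'   `modifications`), and optional `thresholds` overriding the defaults.
#' @return Validated config list of class `oxwave_config`.
#' @export
oxwave_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("seed", "simulation", "input", "thresholds")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (!has_sim && !has_input) {
    stop("config must provide either a 'simulation' block or an 'input' block")
  }
  if (has_sim && has_input) {
    stop("config must provide only one of 'simulation' and 'input'")
  }
  if (is.null(config$seed)) config$seed <- 1L
  th <- .default_thresholds()
  for (nm in names(config$thresholds)) {
    if (!nm %in% names(th)) stop("unknown threshold: ", nm)
    th[[nm]] <- config$thresholds[[nm]]
  }
  config$thresholds <- th
  structure(config, class = c("oxwave_config", "list"))
}

#' Run the full oxidation-wave pipeline
#'
#' Executes all stages in order from one configuration, writing each
#' stage's result tables plus a JSON run manifest (config snapshot, seed,
#' per-stage row counts, package version, timestamps) to `out_dir`.
#' Re-running with the same config and seed reproduces every output table
#' bit-identically.
#'
#' @param config Config list or YAML path (see [oxwave_config()]).
#' @param out_dir Output directory (created if needed).
#' @param write_tables Write stage TSVs (default TRUE); the full result
#'   list is always returned invisibly.
#' @return (Invisibly) list with all stage objects: `truth`, `design`,
#'   `psms`, `histogram`, `peaks`, `psms_filtered`, `curated`,
#'   `redox_calls`, `quant`, `categories`, `timecourse`, `clustering`,
#'   `wave_clusters`, `redox_timecourse`, `enrichment`,
#'   `protein_enrichment`, `tests`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("oxwave_run_"),
                         write_tables = TRUE) {
  cfg <- oxwave_config(config)
  th <- cfg$thresholds
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage_counts <- list()
  note <- function(stage, n_in, n_out) {
    stage_counts[[stage]] <<- list(n_in = n_in, n_out = n_out)
  }
  emit <- function(obj, file, kind) {
    if (write_tables) .write_versioned_tsv(obj, file.path(out_dir, file), kind)
  }

  # --- stage 1: simulate or load ------------------------------------------
  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    sim_args$seed <- derive_stage_seed(cfg$seed, 1L)
    scfg <- do.call(sim_config, sim_args)
    truth <- generate_ground_truth(scfg)
    design <- simulate_design(scfg)
    psms <- simulate_psm_table(truth, scfg)
    mods <- default_modifications()
    categories <- split(truth$proteins$protein, truth$proteins$category)
  } else {
    truth <- NULL
    psms <- read_psm_table(cfg$input$psm_table)
    design <- read_design(cfg$input$design)
    mods <- if (!is.null(cfg$input$modifications)) {
      read_modifications(cfg$input$modifications)
    } else default_modifications()
    categories <- if (!is.null(cfg$input$categories)) {
      read_categories(cfg$input$categories)
    } else list()
  }
  note("simulate", 0L, nrow(psms))
  emit(psms, "psms.tsv", "psm")
  emit(design, "design.tsv", "design")

  # --- stage 2: recalibrate -----------------------------------------------
  cal <- recalibrate(psms, min_score = th$min_score, ppm_window = th$ppm_window)
  note("calibrate", nrow(psms), nrow(cal))

  # --- stage 3: delta-mass histogram --------------------------------------
  hist <- build_deltam_histogram(cal, bin_width = th$bin_width)
  note("histogram", nrow(cal), nrow(hist))
  emit(hist, "histogram.tsv", "histogram")

  # --- stage 4: peak detection and assignment -----------------------------
  peaks <- detect_peaks(hist, min_count = th$min_count)
  cal <- assign_psms_to_peaks(cal, peaks)
  note("peaks", nrow(hist), nrow(peaks))

  # --- stage 5: three-scope FDR and identification filter -----------------
  cal <- compute_fdr(cal)
  psms_filtered <- cal[cal$q_global <= th$fdr & !cal$is_decoy, ]
  note("fdr", nrow(cal), nrow(psms_filtered))
  emit(psms_filtered, "psms_filtered.tsv", "psm")

  # --- stage 6: peak annotation -------------------------------------------
  peaks <- annotate_peaks(peaks, mods, match_tol = th$match_tol)
  peaks <- peak_fdr_summary(cal, peaks)
  note("annotate", nrow(peaks), nrow(peaks))
  emit(peaks, "peaks.tsv", "peaks")

  # --- stage 7: curation ---------------------------------------------------
  curated <- curate_modified_peptides(psms_filtered, peaks, design,
                                      min_replicates = th$min_replicates,
                                      mod_list = mods)
  note("curate", nrow(psms_filtered), nrow(curated))
  emit(curated, "curated_peptides.tsv", "curated")

  # --- stage 8: redox classification --------------------------------------
  pk_idx <- match(psms_filtered$peak_id, peaks$peak_id)
  mod_name <- peaks$mod_name[pk_idx]
  tag_psms <- psms_filtered[!is.na(mod_name) &
                              mod_name %in% c("Carbamidomethyl", "Methylthio") &
                              grepl("C", psms_filtered$peptide, fixed = TRUE), ]
  redox_calls <- if (nrow(tag_psms) > 0L) {
    classify_cys_state(tag_psms, tol = th$redox_tol)
  } else {
    data.table::data.table(spectrum_id = character(), peptide = character(),
                           protein = character(), cys_position = integer(),
                           tag_mass = numeric(), state = character())
  }
  note("redox", nrow(tag_psms), nrow(redox_calls))
  emit(redox_calls, "redox_calls.tsv", "redox")

  # --- stage 9: two-pass quantification -----------------------------------
  qin <- data.table::copy(psms_filtered)
  qmod <- peaks$mod_name[match(qin$peak_id, peaks$peak_id)]
  qin <- qin[!is.na(qmod)]
  qmod <- qmod[!is.na(qmod)]
  qin[, modified := qmod != "Unmodified"]
  qin[, peptide_key := ifelse(modified,
                              paste(peptide, qmod, site_position, sep = "|"),
                              peptide)]
  quant <- run_wspp(qin, design)
  note("quant", nrow(qin), nrow(quant$peptides))
  emit(quant$proteins, "protein_quant.tsv", "quant")
  emit(quant$peptides, "peptide_quant.tsv", "quant")
  emit(quant$variances, "variances.tsv", "quant")

  # --- stage 10: functional categories ------------------------------------
  cats <- if (length(categories) > 0L) {
    category_fdr(compute_category_z(quant$proteins, categories,
                                    min_size = th$min_size,
                                    max_size = th$max_size),
                 alpha = th$category_alpha)
  } else {
    data.table::data.table(category = character(), sample_id = character(),
                           n_proteins = integer(), Zc = numeric(),
                           p = numeric(), q = numeric(), significant = logical())
  }
  note("categories", nrow(quant$proteins), nrow(cats))
  emit(cats, "categories.tsv", "categories")

  # --- stage 11: wave clustering ------------------------------------------
  curated_keys <- paste(curated$peptide, curated$ptm, curated$site_position,
                        sep = "|")
  zp_mod <- quant$peptides[quant$peptides$modified &
                             quant$peptides$peptide_key %in% curated_keys, ]
  timecourse <- NULL; clustering <- NULL; wave_clusters <- list()
  if (nrow(zp_mod) >= 2L) {
    timecourse <- build_timecourse_matrix(
      data.table::data.table(id = zp_mod$peptide_key,
                             sample_id = zp_mod$sample_id, z = zp_mod$Zp),
      design)
    if (nrow(timecourse$values) >= 2L) {
      clustering <- hca_pearson(timecourse, linkage = th$linkage,
                                k = th$k_clusters)
      for (cl in sort(unique(clustering$labels))) {
        wave_clusters[[as.character(cl)]] <-
          extract_wave_cluster(timecourse, clustering$labels, cl,
                               filter_rule = th$zp_filter,
                               threshold = th$zp_threshold)
      }
    }
  }
  redox_timecourse <- if (nrow(redox_calls) > 0L &&
                          any(redox_calls$state == "reversibly_oxidized")) {
    tryCatch(reversible_oxidation_timecourse(redox_calls, quant, design),
             error = function(e) NULL)
  } else NULL
  n_rows_tc <- if (is.null(timecourse)) 0L else nrow(timecourse$values)
  note("waves", nrow(zp_mod), n_rows_tc)
  if (!is.null(clustering)) {
    emit(data.table::data.table(id = names(clustering$labels),
                                cluster = unname(clustering$labels)),
         "wave_clusters.tsv", "clusters")
  }

  # --- stage 12: enrichment and group-difference statistics ---------------
  enrichment <- NULL; protein_enrichment <- NULL; tests <- NULL
  if (!is.null(clustering)) {
    # PSM-level PTM/residue composition of the curated population
    cur <- data.table::as.data.table(curated)
    cur[, key := paste(peptide, ptm, site_position, sep = "|")]
    pop <- cur[, .(ptm = rep(ptm, n_psms), residue = rep(site_residue, n_psms),
                   key = rep(key, n_psms))]
    enr <- lapply(sort(unique(clustering$labels)), function(cl) {
      keys <- names(clustering$labels)[clustering$labels == cl]
      e <- ptm_enrichment(pop[key %in% keys], pop, min_psms = th$min_psms)
      if (nrow(e) > 0L) e[, cluster := cl]
      e
    })
    enrichment <- data.table::rbindlist(enr, fill = TRUE)
    if (nrow(enrichment) > 0L) emit(enrichment, "ptm_enrichment.tsv", "enrichment")
  }
  # oxidized-protein enrichment over identified target PSMs
  ox_names <- c("Oxidation", "Dioxidation", "Trioxidation")
  pf <- data.table::as.data.table(psms_filtered)
  pf[, mod_name := peaks$mod_name[match(peak_id, peaks$peak_id)]]
  counts <- pf[, .(total = .N,
                   oxidized = sum(!is.na(mod_name) & mod_name %in% ox_names)),
               by = protein]
  if (nrow(counts) > 0L && sum(counts$oxidized) > 0L) {
    protein_enrichment <- oxidized_protein_enrichment(counts)
    emit(protein_enrichment, "protein_enrichment.tsv", "enrichment")
  }
  # Kruskal-Wallis across time points on reversibly oxidized Cys Zp
  if (!is.null(redox_timecourse)) {
    rx_pep <- quant$peptides[quant$peptides$modified &
                               grepl("Methylthio", quant$peptides$peptide_key,
                                     fixed = TRUE), ]
    grp <- split(rx_pep$Zp, rx_pep$timepoint_label)
    grp <- grp[lengths(grp) > 0L]
    if (length(grp) >= 2L) {
      kw <- group_difference_tests(grp, test = "kruskal_wallis")
      tests <- data.table::data.table(test = "kruskal_wallis",
                                      what = "reversible_cys_oxidation_zp",
                                      statistic = kw$statistic, p = kw$p,
                                      method = kw$method)
      emit(tests, "tests.tsv", "tests")
    }
  }
  n_enr <- if (is.null(enrichment)) 0L else nrow(enrichment)
  note("enrichment", n_rows_tc, n_enr)

  manifest <- list(
    package_version = as.character(utils::packageVersion("oxwave")),
    seed = cfg$seed,
    config = unclass(cfg),
    stages = lapply(.OXWAVE_STAGES, function(s) {
      c(list(name = s), stage_counts[[s]])
    }),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (write_tables) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(
    truth = truth, design = design, psms = psms, calibrated = cal,
    histogram = hist, peaks = peaks, psms_filtered = psms_filtered,
    curated = curated, redox_calls = redox_calls, quant = quant,
    categories = cats, timecourse = timecourse, clustering = clustering,
    wave_clusters = wave_clusters, redox_timecourse = redox_timecourse,
    enrichment = enrichment, protein_enrichment = protein_enrichment,
    tests = tests, manifest = manifest, out_dir = out_dir
  ))
}
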