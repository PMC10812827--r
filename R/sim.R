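# Synthetic ischemia/reperfusion-style PTM experiments with known ground
# truth: baseline + multi-time-point isobaric design, an early irreversible
# oxidation wave (mono-oxidized K/F/N/D), a late wave (mono/di/tri-oxidized
# C/W) overlapping a reversible-Cys-oxidation wave, decoy and false-target
# PSMs, a systematic mass-calibration offset, artifact delta-mass
# populations, and category-level protein abundance effects.

#' Simulation configuration
#'
#' Builds and validates the configuration that defines a synthetic
#' experiment. Defaults emulate the porcine reperfusion time-course design:
#' 7 reperfusion time points plus baseline, n = 4 biological replicates per
#' group, one 10-plex per replicate with channel 1 a pooled-baseline
#' reference.
#'
#' @param n_proteins Number of target proteins.
#' @param peptides_per_protein Tryptic-like peptides simulated per protein.
#' @param n_timepoints Number of post-baseline time points.
#' @param n_replicates Biological replicates per group (= number of plexes).
#' @param channels_per_plex Isobaric channels per plex (>= n_timepoints + 2:
#'   one reference, one baseline, one per time point; leftover channels
#'   carry a pooled QC sample).
#' @param frac_modified Fraction of peptides carrying an irreversible
#'   oxidative PTM (split evenly between the two waves).
#' @param frac_redox Fraction of peptides carrying time-varying reversible
#'   Cys oxidation.
#' @param wave1_template,wave2_template,redox_wave_template Per-time-point
#'   effect sizes in Zp units (length `n_timepoints`). Wave 1 peaks at the
#'   first time point, wave 2 and the reversible-Cys wave mid-course.
#' @param decoy_fraction Decoy PSMs as a fraction of true-target PSMs; an
#'   equal number of incorrect ("false target") PSMs is simulated so that
#'   target-decoy FDR estimates can be checked against truth.
#' @param calib_offset_ppm Systematic mass-calibration error (ppm).
#' @param sigma_ppm Random mass error (ppm, 1 s.d.).
#' @param sigma_log2 Reporter-intensity noise (log2 s.d. per channel).
#' @param sigma_bio Biological replicate variation of protein abundance
#'   (log2 s.d. per protein and sample).
#' @param spectra_per_peptide Spectra per peptidoform per plex.
#' @param base_intensity Reporter intensity scale.
#' @param score_mean_target,score_mean_decoy,score_sd Search-score model:
#'   correct targets vs decoys/false targets (Gaussian).
#' @param artifact_deltams Delta masses of artifact/combination PSM
#'   populations the curation filter must discard.
#' @param artifact_fraction Fraction of peptides emitting one PSM per
#'   artifact delta mass.
#' @param decoy_deltam_range Uniform delta-mass range for decoy and
#'   false-target PSMs (Da).
#' @param category_effects Named list of per-time-point log2 fold-change
#'   vectors; each named category receives `category_fraction` of proteins.
#' @param category_fraction Fraction of proteins per named category.
#' @param redox_f_base Baseline reversibly-oxidized fraction of redox
#'   peptides.
#' @param seed Integer seed; the whole experiment is deterministic given it.
#' @return Object of class `oxwave_sim_config` (a validated list).
#' @export
sim_config <- function(n_proteins = 150L,
                       peptides_per_protein = 6L,
                       n_timepoints = 7L,
                       n_replicates = 4L,
                       channels_per_plex = 10L,
                       frac_modified = 0.25,
                       frac_redox = 0.15,
                       wave1_template = c(2.5, 1.5, 0.8, 0.3, 0.1, 0, 0),
                       wave2_template = c(0, 0.1, 0.4, 1.2, 2.5, 2.2, 1.5),
                       redox_wave_template = c(0.2, 0.4, 0.8, 1.6, 2.4, 1.8, 1.2),
                       decoy_fraction = 0.15,
                       calib_offset_ppm = 8,
                       sigma_ppm = 1.0,
                       sigma_log2 = 0.15,
                       sigma_bio = 0.05,
                       spectra_per_peptide = 2L,
                       base_intensity = 2^20,
                       score_mean_target = 3,
                       score_mean_decoy = 1.6,
                       score_sd = 0.5,
                       artifact_deltams = c(1.003355, 2.006710, 58.005480),
                       artifact_fraction = 0.03,
                       decoy_deltam_range = c(-60, 60),
                       category_effects = list(
                         immune = c(0, 0, 0.1, 0.3, 0.6, 0.8, 1.0),
                         mitochondrial = c(0, 0, 0, 0, 0, -0.2, -0.6)
                       ),
                       category_fraction = 0.12,
                       redox_f_base = 0.15,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_replicates < 2L) stop("n_replicates must be >= 2")
  for (nm in c("frac_modified", "frac_redox", "decoy_fraction",
               "artifact_fraction", "category_fraction", "redox_f_base")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(nm, " must be a fraction in [0, 1]")
  }
  for (nm in c("wave1_template", "wave2_template", "redox_wave_template")) {
    if (length(cfg[[nm]]) != cfg$n_timepoints) {
      stop(nm, " must have length n_timepoints (", cfg$n_timepoints, ")")
    }
  }
  for (eff in cfg$category_effects) {
    if (length(eff) != cfg$n_timepoints) {
      stop("every category_effects entry must have length n_timepoints")
    }
  }
  if (cfg$channels_per_plex < cfg$n_timepoints + 2L) {
    stop("channels_per_plex must be >= n_timepoints + 2")
  }
  structure(cfg, class = "oxwave_sim_config")
}

# Injected peptide-level log2 effect per Zp unit: the expected standard
# error of a peptide's log2 ratio under the noise model (two channels per
# ratio, spectra averaged), so that injected wave templates land on the Zp
# scale after standardization.
#' @rdname sim_config
#' @param config An `oxwave_sim_config`.
#' @export
zp_effect_scale <- function(config) {
  config$sigma_log2 * sqrt(2) / sqrt(config$spectra_per_peptide)
}

.TAG_REDUCED <- 57.021464   # carbamidomethyl (IAM), blocks free thiols
.TAG_OXIDIZED <- 45.987721  # methylthio (MMTS), marks reversibly oxidized Cys
.OX_MONO <- 15.994915
.OX_DI <- 31.989829
.OX_TRI <- 47.984744

.intensity_col <- function(ch) sprintf("intensity_%02d", ch)

# random tryptic-like peptides: length 8-14, C-terminal K/R, low C/W rate
.random_peptides <- function(n, rng_alphabet = NULL) {
  aa <- c("G", "A", "S", "P", "V", "T", "L", "I", "N", "D", "Q", "K", "E",
          "M", "H", "F", "R", "Y", "C", "W")
  wt <- c(8, 8, 7, 6, 7, 6, 9, 6, 5, 6, 4, 6, 7, 2, 3, 4, 5, 3, 1.5, 1.5)
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    len <- sample(8:14, need, replace = TRUE)
    body <- vapply(len, function(l) {
      paste(sample(aa, l - 1L, replace = TRUE, prob = wt), collapse = "")
    }, character(1))
    cterm <- sample(c("K", "R"), need, replace = TRUE)
    out <- unique(c(out, paste0(body, cterm)))
  }
  out[seq_len(n)]
}

# replace the residue at a random internal position with `res`
.inject_residue <- function(peptide, res) {
  pos <- sample(seq_len(nchar(peptide) - 1L), 1L)
  paste0(substr(peptide, 1L, pos - 1L), res,
         substr(peptide, pos + 1L, nchar(peptide)))
}

.site_of <- function(peptide, residues) {
  hits <- which(strsplit(peptide, "")[[1]] %in% residues)
  if (length(hits) == 0L) return(NA_integer_)
  if (length(hits) == 1L) hits else sample(hits, 1L)
}

#' Generate the ground truth of a synthetic experiment
#'
#' Partitions proteins into functional categories with injected abundance
#' time courses, generates unique tryptic-like peptides, assigns a fraction
#' of them irreversible oxidative PTMs (wave 1: mono-oxidation on
#' K/F/N/D; wave 2: mono-/di-/tri-oxidation on C/W), designates a subset of
#' Cys peptides as carrying time-varying reversible oxidation, and creates
#' the decoy complement. Deterministic given `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @return Object of class `oxwave_ground_truth`: a list with elements
#'   `config`, `proteins` (protein/category table), `protein_log2fc`
#'   (protein x time matrix), `peptides` (peptide/protein/class table),
#'   `modified_peptide_truth`, `redox_truth` (with per-time oxidized
#'   fractions `f_1..f_K`), `injected_deltam_peaks`, and `decoy_ids`.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "oxwave_sim_config"))
  set.seed(config$seed)
  K <- config$n_timepoints

  proteins <- sprintf("P%04d", seq_len(config$n_proteins))
  cat_names <- names(config$category_effects)
  n_per_cat <- max(2L, round(config$category_fraction * config$n_proteins))
  category <- rep(NA_character_, config$n_proteins)
  idx <- seq_len(config$n_proteins)
  for (cn in cat_names) {
    take <- utils::head(idx[is.na(category[idx])], n_per_cat)
    category[take] <- cn
  }
  rest <- which(is.na(category))
  if (length(rest) > 0L) {
    category[rest] <- sprintf("bulk_%02d", ceiling(seq_along(rest) / 20))
  }
  protein_log2fc <- matrix(0, config$n_proteins, K,
                           dimnames = list(proteins, NULL))
  for (cn in cat_names) {
    protein_log2fc[category == cn, ] <-
      matrix(config$category_effects[[cn]], sum(category == cn), K, byrow = TRUE)
  }

  npep <- config$n_proteins * config$peptides_per_protein
  peptide <- .random_peptides(npep)
  parent <- rep(proteins, each = config$peptides_per_protein)

  n_mod <- round(config$frac_modified * npep)
  n_w1 <- floor(n_mod / 2)
  n_w2 <- n_mod - n_w1
  n_redox <- round(config$frac_redox * npep)
  picks <- sample(npep, n_w1 + n_w2 + n_redox)
  i_w1 <- picks[seq_len(n_w1)]
  i_w2 <- picks[n_w1 + seq_len(n_w2)]
  i_rx <- picks[n_w1 + n_w2 + seq_len(n_redox)]

  # wave 1: mono-oxidation on K/F/N/D
  w1_res <- sample(c("K", "F", "N", "D"), n_w1, replace = TRUE)
  for (j in seq_len(n_w1)) {
    i <- i_w1[j]
    if (!grepl(w1_res[j], substr(peptide[i], 1L, nchar(peptide[i]) - 1L), fixed = TRUE) &&
        substr(peptide[i], nchar(peptide[i]), nchar(peptide[i])) != w1_res[j]) {
      peptide[i] <- .inject_residue(peptide[i], w1_res[j])
    }
  }
  w1_site <- vapply(seq_len(n_w1), function(j) .site_of(peptide[i_w1[j]], w1_res[j]),
                    integer(1))

  # wave 2: mono/di/tri-oxidation on C/W
  w2_res <- sample(c("C", "W"), n_w2, replace = TRUE)
  for (j in seq_len(n_w2)) {
    i <- i_w2[j]
    if (!grepl(w2_res[j], peptide[i], fixed = TRUE)) {
      peptide[i] <- .inject_residue(peptide[i], w2_res[j])
    }
  }
  w2_site <- vapply(seq_len(n_w2), function(j) .site_of(peptide[i_w2[j]], w2_res[j]),
                    integer(1))
  w2_ptm <- sample(c("Oxidation", "Dioxidation", "Trioxidation"), n_w2,
                   replace = TRUE, prob = c(0.4, 0.3, 0.3))
  w2_delta <- c(Oxidation = .OX_MONO, Dioxidation = .OX_DI,
                Trioxidation = .OX_TRI)[w2_ptm]

  # reversible-Cys-oxidation peptides: guarantee a Cys
  for (i in i_rx) {
    if (!grepl("C", peptide[i], fixed = TRUE)) peptide[i] <- .inject_residue(peptide[i], "C")
  }
  rx_site <- vapply(i_rx, function(i) .site_of(peptide[i], "C"), integer(1))

  # re-deduplicate after residue injection
  dup <- which(duplicated(peptide))
  while (length(dup) > 0L) {
    for (i in dup) peptide[i] <- .inject_residue(peptide[i], sample(c("A", "S", "L", "E"), 1L))
    dup <- which(duplicated(peptide))
  }

  class_ <- rep("unmod", npep)
  class_[i_w1] <- "wave1"
  class_[i_w2] <- "wave2"
  class_[i_rx] <- "redox"

  peptides <- data.table::data.table(peptide = peptide, protein = parent,
                                     class = class_)

  modified_peptide_truth <- data.table::data.table(
    peptide = c(peptide[i_w1], peptide[i_w2]),
    protein = c(parent[i_w1], parent[i_w2]),
    wave_id = rep(c("wave1", "wave2"), c(n_w1, n_w2)),
    ptm_name = c(rep("Oxidation", n_w1), w2_ptm),
    ptm_delta = c(rep(.OX_MONO, n_w1), unname(w2_delta)),
    site_residue = c(w1_res, w2_res),
    site_position = c(w1_site, w2_site)
  )

  # per-time oxidized fraction of redox peptides: the log2 change of the
  # oxidized form tracks the template on the Zp scale
  fr <- pmin(config$redox_f_base *
               2^matrix(config$redox_wave_template * zp_effect_scale(config),
                        n_redox, K, byrow = TRUE), 1)
  redox_truth <- data.table::data.table(
    peptide = peptide[i_rx], protein = parent[i_rx],
    cys_position = rx_site, f_base = rep(config$redox_f_base, n_redox)
  )
  if (n_redox > 0L) {
    for (t in seq_len(K)) data.table::set(redox_truth, j = sprintf("f_%d", t),
                                          value = fr[, t])
  } else {
    for (t in seq_len(K)) data.table::set(redox_truth, j = sprintf("f_%d", t),
                                          value = numeric(0))
  }

  has_cys <- grepl("C", peptide, fixed = TRUE)
  injected <- unique(c(
    0,
    if (n_w1 > 0L) .OX_MONO,
    if (n_w2 > 0L) unique(unname(w2_delta)),
    if (any(has_cys & class_ != "wave2")) .TAG_REDUCED,
    if (n_redox > 0L) .TAG_OXIDIZED,
    if (config$artifact_fraction > 0) config$artifact_deltams
  ))

  structure(list(
    config = config,
    proteins = data.table::data.table(protein = proteins, category = category),
    protein_log2fc = protein_log2fc,
    peptides = peptides,
    modified_peptide_truth = modified_peptide_truth,
    redox_truth = redox_truth,
    injected_deltam_peaks = injected,
    decoy_ids = paste0("DECOY_", proteins)
  ), class = "oxwave_ground_truth")
}

#' Build the default plex design for a configuration
#'
#' One plex per biological replicate. Channel 1 carries the pooled-baseline
#' reference, channel 2 the baseline sample, channels 3..(2+K) the K time
#' points, and any leftover channels a pooled QC sample (group `pool`,
#' ignored by time-course analyses).
#'
#' @param config An [sim_config()] object.
#' @return A design `data.table` (see [read_design()]).
#' @export
simulate_design <- function(config) {
  K <- config$n_timepoints
  tp <- sprintf("t%d", seq_len(K))
  rows <- list()
  for (p in seq_len(config$n_replicates)) {
    plex <- sprintf("plex%d", p)
    grp <- c("reference", "baseline", tp,
             rep("pool", config$channels_per_plex - K - 2L))
    tlab <- c("", "baseline", tp, rep("", config$channels_per_plex - K - 2L))
    ch <- seq_len(config$channels_per_plex)
    sid <- ifelse(grp == "reference", paste0(plex, "_ref"),
                  ifelse(grp == "pool", sprintf("%s_pool%d", plex, ch),
                         sprintf("%s_r%d", grp, p)))
    rows[[p]] <- data.table::data.table(
      plex_id = plex, channel_index = ch, sample_id = sid,
      group_label = grp, timepoint_label = tlab,
      is_reference = grp == "reference"
    )
  }
  design <- data.table::rbindlist(rows)
  validate_design(design)
  design
}

#' Simulate the open-search PSM table of a ground-truth experiment
#'
#' Emulates the PSM-level output of an open search on the synthetic
#' experiment: each PSM carries observed mass = theoretical + true delta
#' mass, distorted by the systematic ppm offset and Gaussian ppm noise;
#' reporter intensities are lognormal around channel means encoding the
#' injected protein and peptide-level effects; reversibly oxidized Cys
#' forms carry the methylthio tag mass and reduced forms the
#' carbamidomethyl tag mass as their delta mass; decoy and false-target
#' PSMs carry uniform delta masses and decoy-level scores. Ground-truth
#' sidecar columns (`truth_*`) identify each PSM's origin; analysis stages
#' never read them.
#'
#' @param truth An [generate_ground_truth()] object.
#' @param config The same [sim_config()] the truth was generated from.
#' @return A `data.table` of PSM records (see [read_psm_table()]).
#' @export
simulate_psm_table <- function(truth, config) {
  stopifnot(inherits(truth, "oxwave_ground_truth"))
  if (!identical(truth$config, config)) {
    stop("config does not match the one the ground truth was generated from")
  }
  set.seed(config$seed + 500011L)
  K <- config$n_timepoints
  design <- simulate_design(config)
  pep <- truth$peptides
  npep <- nrow(pep)
  has_cys <- grepl("C", pep$peptide, fixed = TRUE)
  first_cys <- ifelse(has_cys,
                      vapply(strsplit(pep$peptide, ""), function(a) {
                        h <- which(a == "C"); if (length(h)) h[1] else NA_integer_
                      }, integer(1)), NA_integer_)

  mpt <- truth$modified_peptide_truth
  mod_idx <- match(mpt$peptide, pep$peptide)
  rx <- truth$redox_truth
  rx_idx <- match(rx$peptide, pep$peptide)

  # ---- peptidoform table: one row per distinct (peptide, deltam) form ----
  forms <- list()
  # base form of every peptide: delta 0, or the reduced alkylation tag at Cys
  forms$base <- data.table::data.table(
    pep_idx = seq_len(npep),
    deltam = ifelse(has_cys & pep$class != "wave2", .TAG_REDUCED, 0),
    site = ifelse(has_cys & pep$class != "wave2", first_cys, NA_integer_),
    kind = ifelse(pep$peptide %in% rx$peptide, "redox_reduced",
                  ifelse(has_cys & pep$class != "wave2", "cys_reduced", "unmod"))
  )
  if (nrow(mpt) > 0L) {
    forms$modified <- data.table::data.table(
      pep_idx = mod_idx, deltam = mpt$ptm_delta, site = mpt$site_position,
      kind = mpt$wave_id
    )
  }
  if (nrow(rx) > 0L) {
    forms$oxidized <- data.table::data.table(
      pep_idx = rx_idx, deltam = .TAG_OXIDIZED, site = rx$cys_position,
      kind = "redox_oxidized"
    )
  }
  n_art <- round(config$artifact_fraction * npep)
  if (n_art > 0L && length(config$artifact_deltams) > 0L) {
    forms$artifact <- data.table::rbindlist(lapply(config$artifact_deltams, function(dm) {
      data.table::data.table(pep_idx = sample(npep, n_art), deltam = dm,
                             site = NA_integer_, kind = "artifact")
    }))
  }
  forms <- data.table::rbindlist(forms)
  forms[, `:=`(peptide = pep$peptide[pep_idx], protein = pep$protein[pep_idx])]
  forms[, theo := peptide_mass(peptide)]
  forms[, ptm := data.table::fcase(
    kind == "wave1", "Oxidation",
    kind == "wave2", c(Oxidation = "Oxidation", Dioxidation = "Dioxidation",
                       Trioxidation = "Trioxidation")[
                         match(round(deltam, 3),
                               round(c(.OX_MONO, .OX_DI, .OX_TRI), 3))],
    kind %in% c("redox_reduced", "cys_reduced"), "Carbamidomethyl",
    kind == "redox_oxidized", "Methylthio",
    default = ""
  )]

  # ---- expand to PSM rows: forms x plex x spectra ------------------------
  nspec <- config$spectra_per_peptide
  n_forms <- nrow(forms)
  rows <- forms[rep(seq_len(n_forms), times = config$n_replicates * nspec)]
  rows[, plex := rep(sprintf("plex%d", seq_len(config$n_replicates)),
                     each = n_forms * nspec)]

  # decoys and false targets (incorrect matches), decoy-level scores,
  # uniform delta mass
  n_true <- nrow(rows)
  n_noise <- round(config$decoy_fraction * n_true)
  mk_noise <- function(n, decoy) {
    i <- sample(npep, n, replace = TRUE)
    peptide <- if (decoy) {
      # pseudo-reversed decoy sequences, C-terminal residue kept
      vapply(pep$peptide[i], function(s) {
        n_ <- nchar(s)
        paste0(paste(rev(strsplit(substr(s, 1, n_ - 1L), "")[[1]]), collapse = ""),
               substr(s, n_, n_))
      }, character(1), USE.NAMES = FALSE)
    } else pep$peptide[i]
    data.table::data.table(
      pep_idx = NA_integer_, peptide = peptide,
      protein = if (decoy) paste0("DECOY_", pep$protein[i]) else pep$protein[i],
      deltam = stats::runif(n, config$decoy_deltam_range[1], config$decoy_deltam_range[2]),
      site = pmax(1L, as.integer(ceiling(stats::runif(n) * (nchar(peptide) - 1L)))),
      kind = if (decoy) "decoy" else "false_target",
      theo = peptide_mass(peptide), ptm = "",
      plex = sample(sprintf("plex%d", seq_len(config$n_replicates)), n, replace = TRUE)
    )
  }
  noise_rows <- data.table::rbindlist(list(mk_noise(n_noise, TRUE),
                                           mk_noise(n_noise, FALSE)))
  rows <- data.table::rbindlist(list(rows, noise_rows), use.names = TRUE)
  n_rows <- nrow(rows)

  # ---- masses, scores ----------------------------------------------------
  ppm_err <- config$calib_offset_ppm + stats::rnorm(n_rows, 0, config$sigma_ppm)
  rows[, observed := (theo + deltam) * (1 + ppm_err * 1e-6)]
  rows[, delta_mass := observed - theo]
  is_wrong <- rows$kind %in% c("decoy", "false_target")
  rows[, score := stats::rnorm(n_rows,
                               ifelse(is_wrong, config$score_mean_decoy,
                                      config$score_mean_target),
                               config$score_sd)]
  rows[, charge := sample(2:3, n_rows, replace = TRUE)]
  rows[, spectrum_id := sprintf("sp%07d", seq_len(n_rows))]

  # ---- reporter intensities ---------------------------------------------
  # per-(protein, sample) biological noise, shared across the protein's
  # peptides
  samples <- design[!design$is_reference & design$group_label != "pool", ]
  bio <- matrix(stats::rnorm(config$n_proteins * nrow(samples), 0, config$sigma_bio),
                config$n_proteins, nrow(samples),
                dimnames = list(truth$proteins$protein, samples$sample_id))
  prot_i <- match(rows$protein, truth$proteins$protein)  # NA for decoys
  zscale <- zp_effect_scale(config)
  w1 <- config$wave1_template * zscale
  w2 <- config$wave2_template * zscale
  fr <- as.matrix(truth$redox_truth[, sprintf("f_%d", seq_len(K)), with = FALSE])
  rx_row <- match(rows$peptide, truth$redox_truth$peptide)  # NA if not redox

  plex1 <- design[design$plex_id == sprintf("plex%d", 1L), ]
  for (ch in seq_len(config$channels_per_plex)) {
    grp <- plex1$group_label[plex1$channel_index == ch]
    tl <- plex1$timepoint_label[plex1$channel_index == ch]
    t_idx <- if (startsWith(grp, "t")) match(tl, sprintf("t%d", seq_len(K))) else NA_integer_
    mu <- numeric(n_rows)
    if (!is.na(t_idx)) {
      # protein abundance effect + biological replicate noise
      fc <- truth$protein_log2fc[, t_idx]
      mu <- ifelse(is.na(prot_i), 0, fc[prot_i])
      sid <- paste0(tl, "_r", sub("plex", "", rows$plex))
      ok <- !is.na(prot_i)
      mu[ok] <- mu[ok] + bio[cbind(prot_i[ok], match(sid[ok], colnames(bio)))]
      mu <- mu + ifelse(rows$kind == "wave1", w1[t_idx],
                        ifelse(rows$kind == "wave2", w2[t_idx], 0))
      mu <- mu + data.table::fcase(
        rows$kind == "redox_oxidized", log2(fr[cbind(rx_row, rep(t_idx, n_rows))]),
        rows$kind == "redox_reduced", log2(1 - fr[cbind(rx_row, rep(t_idx, n_rows))]),
        default = 0
      )
    } else if (grp == "baseline") {
      sid <- paste0("baseline_r", sub("plex", "", rows$plex))
      ok <- !is.na(prot_i)
      mu[ok] <- bio[cbind(prot_i[ok], match(sid[ok], colnames(bio)))]
      mu <- mu + data.table::fcase(
        rows$kind == "redox_oxidized", log2(truth$redox_truth$f_base[rx_row]),
        rows$kind == "redox_reduced", log2(1 - truth$redox_truth$f_base[rx_row]),
        default = 0
      )
    } else {
      # reference / pool: pooled baseline, no biological noise
      mu <- data.table::fcase(
        rows$kind == "redox_oxidized", log2(truth$redox_truth$f_base[rx_row]),
        rows$kind == "redox_reduced", log2(1 - truth$redox_truth$f_base[rx_row]),
        default = 0
      )
    }
    intens <- config$base_intensity *
      2^(mu + stats::rnorm(n_rows, 0, config$sigma_log2))
    data.table::set(rows, j = .intensity_col(ch), value = intens)
  }

  out <- data.table::data.table(
    spectrum_id = rows$spectrum_id,
    peptide = rows$peptide,
    charge = rows$charge,
    theoretical_mass = rows$theo,
    observed_mass = rows$observed,
    delta_mass = rows$delta_mass,
    score = rows$score,
    is_decoy = rows$kind == "decoy",
    protein = rows$protein,
    site_position = rows$site,
    plex_id = rows$plex
  )
  for (ch in seq_len(config$channels_per_plex)) {
    data.table::set(out, j = .intensity_col(ch), value = rows[[.intensity_col(ch)]])
  }
  out[, `:=`(
    truth_class = rows$kind,
    truth_ptm = rows$ptm,
    truth_deltam = rows$deltam,
    truth_false_target = rows$kind == "false_target"
  )]
  out[]
}

#' Simulate a complete experiment
#'
#' Convenience wrapper: ground truth, design table and PSM table from one
#' configuration.
#'
#' @param config An [sim_config()] object.
#' @return List with `truth`, `design`, `psms`.
#' @export
simulate_experiment <- function(config) {
  truth <- generate_ground_truth(config)
  list(truth = truth, design = simulate_design(config),
       psms = simulate_psm_table(truth, config))
}
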