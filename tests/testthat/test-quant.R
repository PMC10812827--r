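test_that("spectrum log2 ratios follow the intensity contract", {
  cfg <- tiny_config(seed = 31L)
  design <- simulate_design(cfg)
  psms <- simulate_psm_table(generate_ground_truth(cfg), cfg)[1:3]
  # force known intensities on plex1: reference is channel 1
  psms$plex_id <- "plex1"
  psms$intensity_01 <- 100
  psms$intensity_02 <- c(100, 200, 0)
  r <- compute_log2_ratios(psms, design)
  ch2 <- r[r$sample_id == "baseline_r1", ]
  expect_equal(ch2$x, c(0, 1, NA_real_))
  # zero reference excludes the whole spectrum with a warning
  psms$intensity_01[1] <- 0
  expect_warning(r2 <- compute_log2_ratios(psms, design), "reference")
  expect_false(psms$spectrum_id[1] %in% r2$spectrum_id)
})

test_that("level integration computes weighted means and standardized deviations", {
  one <- integrate_level(5, 2)
  expect_equal(one$x, 5)
  expect_equal(one$z, 0)
  expect_equal(integrate_level(c(0, 4), c(1, 3))$x, 3)
  sym <- integrate_level(c(1, 3), c(1, 1))
  expect_equal(sym$x, 2)
  expect_equal(sym$z, c(-1, 1))
  expect_equal(sym$w, 2)
  # grand-total conservation: sum of w * (x - parent) is zero
  set.seed(1)
  x <- rnorm(50); w <- runif(50, 0.5, 2)
  fit <- integrate_level(x, w)
  expect_equal(sum(w * (x - fit$x)), 0, tolerance = 1e-10)
  expect_error(integrate_level(NA_real_, 1), "finite")
})

test_that("level-variance fixed point recovers a known extra variance", {
  set.seed(2)
  n_parent <- 250L
  per <- 20L
  prec <- rep(4, n_parent * per)          # lower-level variance 0.25
  parent <- rep(seq_len(n_parent), each = per)
  mu <- rnorm(n_parent, 0, 2)
  x <- mu[parent] + rnorm(length(parent), 0, sqrt(0.25 + 1 / prec))
  est <- estimate_level_variance(x, prec, parent)
  expect_true(est$converged)
  expect_gt(est$sigma2, 0.2)
  expect_lt(est$sigma2, 0.3)
  # zero dispersion: sigma2 is 0
  x0 <- mu[parent]
  expect_equal(estimate_level_variance(x0, prec, parent)$sigma2, 0)
  # permutation invariance
  p <- sample(length(x))
  est2 <- estimate_level_variance(x[p], prec[p], parent[p])
  expect_equal(est2$sigma2, est$sigma2, tolerance = 1e-6)
})

test_that("null simulation yields calibrated Zq and Zp", {
  cfg <- null_config(seed = 33L, n_proteins = 120L, peptides_per_protein = 5L)
  sim <- simulate_experiment(cfg)
  st <- run_shifts_stages(sim$psms)
  quant <- run_wspp(st$filtered, sim$design)
  zq <- quant$proteins$Zq
  zp <- quant$peptides$Zp[!quant$peptides$modified]
  expect_lt(abs(mean(zq)), 0.05)
  expect_gt(stats::var(zq), 0.9); expect_lt(stats::var(zq), 1.1)
  expect_lt(abs(mean(zp)), 0.05)
  expect_gt(stats::var(zp), 0.9); expect_lt(stats::var(zp), 1.1)
})

test_that("injected protein fold change is recovered within 3 standard errors", {
  cfg <- sim_config(n_proteins = 60L, peptides_per_protein = 5L,
                    category_effects = list(up = rep(1, 7)),
                    category_fraction = 0.25, seed = 34L)
  sim <- simulate_experiment(cfg)
  st <- run_shifts_stages(sim$psms)
  # flag modified peptidoforms as the pipeline does, so the protein
  # estimate rests on unmodified peptides only
  psms <- data.table::as.data.table(st$filtered)
  psms[, modified := abs(truth_deltam) > 1e-6]
  psms[, peptide_key := ifelse(modified, paste(peptide, truth_ptm, sep = "|"),
                               peptide)]
  quant <- run_wspp(psms, sim$design)
  up <- sim$truth$proteins$protein[sim$truth$proteins$category == "up"]
  prot <- quant$proteins[quant$proteins$protein %in% up &
                           grepl("^t", quant$proteins$timepoint_label), ]
  # proteins are the independent replication unit (reporter noise of one
  # spectrum is shared across its sample ratios), so the standard error
  # comes from per-protein means
  per_prot <- tapply(prot$x, prot$protein, mean)
  se <- stats::sd(per_prot) / sqrt(length(per_prot))
  expect_lt(abs(mean(per_prot) - 1), 3 * se)
})

test_that("pass 2 never changes protein values and flags anchorless peptides", {
  cfg <- tiny_config(seed = 35L)
  sim <- simulate_experiment(cfg)
  st <- run_shifts_stages(sim$psms)
  psms <- data.table::as.data.table(st$filtered)
  psms[, modified := abs(truth_deltam) > 1e-6]
  psms[, peptide_key := ifelse(modified, paste(peptide, truth_ptm, sep = "|"),
                               peptide)]
  both <- run_wspp(psms, sim$design)
  unmod_only <- run_wspp(psms[modified == FALSE], sim$design)
  expect_identical(both$proteins, unmod_only$proteins)
  expect_identical(both$variances, unmod_only$variances)
  expect_true(any(both$peptides$modified))
  # a modified peptidoform whose protein has no unmodified anchor is dropped
  orphan <- data.table::copy(psms[modified == TRUE][1:8])
  orphan[, `:=`(protein = "GHOST", peptide_key = "GHOSTPEP|Oxidation")]
  expect_message(
    q2 <- run_wspp(data.table::rbindlist(list(psms, orphan)), sim$design),
    "anchor"
  )
  expect_false("GHOSTPEP|Oxidation" %in% q2$peptides$peptide_key)
})

test_that("modified-peptide Zp grows with the injected peptide-level effect", {
  grab_zp <- function(w1_peak) {
    cfg <- sim_config(n_proteins = 40L, peptides_per_protein = 4L,
                      wave1_template = c(w1_peak, rep(0, 6)),
                      wave2_template = rep(0, 7),
                      redox_wave_template = rep(0, 7),
                      category_effects = list(), seed = 36L)
    sim <- simulate_experiment(cfg)
    st <- run_shifts_stages(sim$psms)
    psms <- data.table::as.data.table(st$filtered)
    psms[, modified := abs(truth_deltam) > 1e-6]
    psms[, peptide_key := ifelse(modified, paste(peptide, truth_ptm, sep = "|"),
                                 peptide)]
    quant <- run_wspp(psms, sim$design)
    w1 <- sim$truth$modified_peptide_truth$peptide[
      sim$truth$modified_peptide_truth$wave_id == "wave1"]
    zp <- quant$peptides[quant$peptides$modified &
                           quant$peptides$timepoint_label == "t1" &
                           sub("\\|.*$", "", quant$peptides$peptide_key) %in% w1, ]
    list(zp = mean(zp$Zp),
         zq = quant$proteins[quant$proteins$timepoint_label == "t1" &
                               quant$proteins$protein %in%
                                 unique(zp$protein), ]$Zq)
  }
  low <- grab_zp(1)
  high <- grab_zp(3)
  expect_gt(low$zp, 0.5)
  expect_gt(high$zp, low$zp)
  # protein Zq stays at the null despite the peptide-level effect
  expect_lt(abs(mean(high$zq)), 0.5)
})
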