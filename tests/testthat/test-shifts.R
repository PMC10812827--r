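test_that("recalibration removes an injected systematic ppm offset", {
  cfg <- tiny_config(seed = 21L, calib_offset_ppm = 8)
  psms <- simulate_psm_table(generate_ground_truth(cfg), cfg)
  cal <- recalibrate(psms)
  expect_equal(attr(cal, "ppm_offset"), 8, tolerance = 0.15)
  tgt <- !cal$is_decoy & !cal$truth_false_target
  err <- (cal$delta_mass - cal$truth_deltam) / cal$observed_mass * 1e6
  expect_lt(stats::median(abs(err[tgt])), 1)
  # low-score PSMs are excluded from the subset but still corrected
  low <- data.table::copy(psms)
  low$score[1] <- 0.10
  cal2 <- recalibrate(low)
  expect_lt(abs(cal2$observed_mass[1] - psms$observed_mass[1] /
                  (1 + attr(cal2, "ppm_offset") * 1e-6)), 1e-9)
  # idempotence: a second pass changes nothing beyond numerical tolerance
  cal3 <- recalibrate(cal)
  expect_equal(cal3$observed_mass, cal$observed_mass, tolerance = 1e-7)
  expect_lt(abs(attr(cal3, "ppm_offset")), 0.2)
})

test_that("recalibration is the identity at zero offset and guards small inputs", {
  cfg <- noisefree_config(seed = 22L)
  psms <- simulate_psm_table(generate_ground_truth(cfg), cfg)
  cal <- recalibrate(psms)
  expect_equal(cal$observed_mass, psms$observed_mass, tolerance = 1e-9)
  expect_warning(recalibrate(psms[1:10, ]), "quality gate")
  expect_error(recalibrate(psms[0, ]), "empty")
})

test_that("delta-mass histogram conserves counts in half-open bins", {
  cfg <- tiny_config(seed = 23L)
  psms <- simulate_psm_table(generate_ground_truth(cfg), cfg)
  h <- build_deltam_histogram(psms, bin_width = 0.001)
  expect_equal(sum(h$count), nrow(psms))
  expect_true(all(h$bin_high > h$bin_low))

  one <- data.frame(delta_mass = rep(0, 50))
  h1 <- build_deltam_histogram(one, bin_width = 0.001)
  expect_equal(nrow(h1), 1L)
  expect_true(h1$bin_low <= 0 && 0 < h1$bin_high)

  # two populations occupy two regions separated by empty bins
  two <- data.frame(delta_mass = c(rep(15.995, 30), rep(31.990, 30)))
  h2 <- build_deltam_histogram(two, bin_width = 0.001)
  expect_equal(nrow(h2), 2L)
  expect_true(all(h2$bin_low <= two$delta_mass[c(1, 31)] &
                    two$delta_mass[c(1, 31)] < h2$bin_high))
  expect_gt(diff(h2$bin_index), 1)
  expect_error(build_deltam_histogram(two, bin_width = 0), "bin_width")
})

test_that("peak detection finds spikes, plateaus, and injected populations", {
  spike <- data.frame(delta_mass = rep(0.0205, 20))
  pk <- detect_peaks(build_deltam_histogram(spike), min_count = 5)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$apex_deltam, 0.0205, tolerance = 5e-4)

  # a two-bin plateau at the apex is still one peak
  h <- data.table::data.table(bin_index = 10:14, count = c(3L, 9L, 9L, 4L, 1L))
  h[, `:=`(bin_low = bin_index * 0.001, bin_high = (bin_index + 1) * 0.001)]
  data.table::setattr(h, "bin_width", 0.001)
  pk2 <- detect_peaks(h, min_count = 5)
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$psm_count, 26L)

  # injected Gaussian cluster over uniform noise: apex within one bin width
  set.seed(77)
  dm <- c(stats::rnorm(500, 15.9949, 0.002), stats::runif(2000, -50, 50))
  h3 <- build_deltam_histogram(data.frame(delta_mass = dm))
  pk3 <- detect_peaks(h3)
  expect_true(any(abs(pk3$apex_deltam - 15.9949) <= 0.001))

  # flat uniform noise below min_count: no peaks
  set.seed(78)
  flat <- data.frame(delta_mass = stats::runif(2000, -100, 100))
  pk4 <- detect_peaks(build_deltam_histogram(flat))
  expect_equal(nrow(pk4), 0L)
})

test_that("PSM-to-peak assignment respects half-open bounds and disjointness", {
  peaks <- data.table::data.table(
    peak_id = c("a", "b"), apex_deltam = c(0.0005, 1.0005),
    bin_low = c(0, 1), bin_high = c(0.01, 1.01), psm_count = c(5L, 5L)
  )
  psms <- data.frame(delta_mass = c(0.005, 0.01, 1.0, 0.5))
  out <- assign_psms_to_peaks(psms, peaks)
  expect_equal(out$peak_id, c("a", NA, "b", NA))  # upper bound excluded

  overlapping <- data.table::copy(peaks)
  overlapping$bin_high[1] <- 1.005
  expect_error(assign_psms_to_peaks(psms, overlapping), "disjoint")

  # counts per peak equal generator truth in the noise-free simulation
  # (every population sits in a single bin, so min_count is set explicitly)
  cfg <- noisefree_config(seed = 24L, decoy_fraction = 0)
  sim <- simulate_psm_table(generate_ground_truth(cfg), cfg)
  st <- run_shifts_stages(sim, min_count = 5)
  tab <- table(st$psms$peak_id)
  for (dm in unique(sim$truth_deltam)) {
    pid <- st$peaks$peak_id[st$peaks$bin_low <= dm & dm < st$peaks$bin_high]
    expect_equal(unname(tab[pid]), sum(sim$truth_deltam == dm))
  }
})

test_that("q-values are monotone in score and behave at the symmetry limits", {
  set.seed(31)
  n <- 4000
  psms <- data.table::data.table(
    score = c(stats::rnorm(n, 3, 0.5), stats::rnorm(n, 3, 0.5)),
    is_decoy = rep(c(FALSE, TRUE), each = n),
    delta_mass = stats::runif(2 * n, -5, 5)
  )
  q <- quiet_fdr(psms)
  # identically distributed scores: q at the full list is ~1
  expect_gt(min(q$q_global[order(q$score)][1:100]), 0.8)
  # monotone non-increasing with score within every scope
  o <- order(-q$score)
  expect_true(all(diff(q$q_global[o]) >= -1e-12))
  for (b in unique(floor(q$delta_mass + 0.5))) {
    sub <- q[floor(q$delta_mass + 0.5) == b, ]
    o <- order(-sub$score)
    expect_true(all(diff(sub$q_local[o]) >= -1e-12))
  }
  # no decoys: all q-values 0
  clean <- data.table::data.table(score = stats::rnorm(100, 3),
                                  is_decoy = FALSE,
                                  delta_mass = 0)
  expect_true(all(quiet_fdr(clean)$q_global == 0))
  bad <- data.table::copy(clean)
  bad$is_decoy <- NA
  expect_error(compute_fdr(bad), "target or decoy")
})

test_that("peak annotation picks the nearest known shift within tolerance", {
  mods <- default_modifications()
  peaks <- data.table::data.table(
    peak_id = c("p1", "p2", "p3", "p4"),
    apex_deltam = c(15.9949, 0.0000, 47.9847, 5.5),
    bin_low = c(15.99, -0.005, 47.98, 5.49),
    bin_high = c(16.00, 0.005, 47.99, 5.51),
    psm_count = rep(10L, 4)
  )
  ann <- annotate_peaks(peaks, mods, match_tol = 0.01)
  expect_equal(ann$mod_name, c("Oxidation", "Unmodified", "Trioxidation", NA))
  # tie break: equidistant entries resolve by smaller difference then name
  ml <- data.table::data.table(
    name = c("B_mod", "A_mod"), delta_mass = c(10.000, 10.002),
    allowed_residues = list("K", "K"),
    is_artifact = FALSE, is_combination = FALSE
  )
  tie <- data.table::data.table(peak_id = "t", apex_deltam = 10.001,
                                bin_low = 10, bin_high = 10.01, psm_count = 5L)
  expect_equal(annotate_peaks(tie, ml, 0.01)$mod_name, "A_mod")
})

test_that("truncation explanations match the brute-force terminal oracle", {
  rm <- residue_masses()
  res <- check_truncation("ACDEFK", -rm[["A"]])
  expect_equal(res$terminus, "N")
  expect_equal(res$residues, "A")
  expect_equal(res$type, "loss")
  expect_null(check_truncation("ACDEFK", 0))
  res2 <- check_truncation("ACDEFK", -(rm[["K"]] + rm[["F"]]))
  expect_equal(res2$terminus, "C")
  expect_equal(res2$residues, "FK")

  set.seed(41)
  peptides <- c("ACDEFK", "MKWCR", "GGSTPK", "LNDQER", "WYHMAK")
  for (pep in peptides) {
    aa <- strsplit(pep, "")[[1]]
    targets <- c(-cumsum(rm[aa])[1:3], cumsum(rm[rev(aa)])[1:3],
                 stats::runif(3, -300, 300))
    for (dm in targets) {
      got <- check_truncation(pep, dm, tol = 0.005, max_depth = nchar(pep) - 1L)
      want <- oracle_truncation(pep, dm, tol = 0.005)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_equal(got[c("terminus", "residues", "type")],
                     want[c("terminus", "residues", "type")])
      }
    }
  }
})

test_that("site-position checks honour residues, termini and missing sites", {
  expect_true(check_site_position("AMK", 2L, c("M", "W")))
  expect_false(check_site_position("AGK", 2L, c("M", "W", "C", "K", "F", "N", "D")))
  expect_true(check_site_position("AGK", 0L, "N-term"))
  expect_true(check_site_position("AGK", 4L, "C-term"))
  expect_true(is.na(check_site_position("AGK", NA_integer_, "K")))
  expect_true(check_site_position("AGK", 2L, "*"))
})

test_that("curation keeps exactly the generator's modified peptides when noise-free", {
  cfg <- noisefree_config(seed = 25L, decoy_fraction = 0)
  truth <- generate_ground_truth(cfg)
  sim <- simulate_psm_table(truth, cfg)
  design <- simulate_design(cfg)
  st <- run_shifts_stages(sim, min_count = 5)
  peaks <- annotate_peaks(st$peaks, default_modifications())
  cur <- curate_modified_peptides(st$filtered, peaks, design)
  got <- cur[, c("peptide", "ptm", "site_position")]
  want <- truth$modified_peptide_truth[, c("peptide", "ptm_name", "site_position")]
  names(want)[2] <- "ptm"
  data.table::setorder(got, peptide, ptm, site_position)
  data.table::setorder(want, peptide, ptm, site_position)
  expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
  # artifact and combination populations were all excluded
  expect_false(any(cur$ptm %in% c("Isotope+1", "Isotope+2", "Oxidation+Acetyl",
                                  "Carbamidomethyl", "Methylthio")))
  # row-order invariance
  shuffled <- st$filtered[sample(nrow(st$filtered)), ]
  cur2 <- curate_modified_peptides(shuffled, peaks, design)
  expect_equal(cur, cur2)
})

test_that("curation drops peptidoforms missing from one biological replicate", {
  cfg <- noisefree_config(seed = 26L, decoy_fraction = 0)
  truth <- generate_ground_truth(cfg)
  sim <- simulate_psm_table(truth, cfg)
  design <- simulate_design(cfg)
  victim <- truth$modified_peptide_truth$peptide[1]
  sim <- sim[!(sim$peptide == victim & sim$plex_id == "plex1" &
                 sim$truth_class %in% c("wave1", "wave2")), ]
  st <- run_shifts_stages(sim, min_count = 5)
  peaks <- annotate_peaks(st$peaks, default_modifications())
  cur <- curate_modified_peptides(st$filtered, peaks, design, min_replicates = 4L)
  expect_false(victim %in% cur$peptide)
  cur3 <- curate_modified_peptides(st$filtered, peaks, design, min_replicates = 3L)
  expect_true(victim %in% cur3$peptide)
})
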