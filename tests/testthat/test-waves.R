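test_that("time-course matrices average replicates and drop empty rows", {
  cfg <- tiny_config()
  design <- simulate_design(cfg)
  zt <- data.table::data.table(
    id = "pep1",
    sample_id = sprintf("t1_r%d", 1:4),
    z = c(1, 1, 1, 1)
  )
  zt2 <- data.table::data.table(id = "pep2",
                                sample_id = c("t1_r1", "t1_r2"),
                                z = c(0, 2))
  suppressMessages({
    tc <- build_timecourse_matrix(rbind(zt, zt2), design, timepoints = "t1")
  })
  expect_equal(unname(tc$values["pep1", "t1"]), 1)
  expect_equal(unname(tc$values["pep2", "t1"]), 1)     # mean of (0, 2)
  expect_equal(unname(tc$n["pep2", "t1"]), 2L)
  # full matrix has one column per time point
  full <- data.table::data.table(
    id = "p", sample_id = design$sample_id[grepl("^t", design$group_label)],
    z = 1)
  tc2 <- build_timecourse_matrix(full, design)
  expect_equal(ncol(tc2$values), 7L)
  # a row with an all-missing time point is dropped with a message
  expect_message(
    tc3 <- build_timecourse_matrix(rbind(full, zt2), design),
    "dropped"
  )
  expect_equal(rownames(tc3$values), "p")
})

test_that("Pearson-distance HCA honours the distance definition", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
             c = c(4, 3, 2, 1), d = c(0.5, 0.4, 0.3, 0.2))
  cl <- hca_pearson(m, k = 2)
  dm <- as.matrix(cl$distance)
  expect_equal(dm["a", "b"], 0, tolerance = 1e-12)   # perfectly correlated
  expect_equal(dm["a", "c"], 2, tolerance = 1e-12)   # perfectly anti-correlated
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
  expect_false(cl$labels[["a"]] == cl$labels[["c"]])
  # identical rows merge first
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))
  # constant rows are dropped with a warning
  mc <- rbind(m, e = c(1, 1, 1, 1))
  expect_warning(cl2 <- hca_pearson(mc, k = 2), "constant")
  expect_false("e" %in% names(cl2$labels))
  expect_error(hca_pearson(m[1, , drop = FALSE]), "2 rows")
  expect_error(hca_pearson(m[, 1:2]), "3 time points")
})

test_that("HCA separates two injected wave templates and is order-invariant", {
  skip_if_no_mclust()
  set.seed(71)
  w1 <- c(2.5, 1.5, 0.8, 0.3, 0.1, 0, 0)
  w2 <- c(0, 0.1, 0.4, 1.2, 2.5, 2.2, 1.5)
  n <- 100L
  truth_lab <- rep(1:2, each = n)
  m <- rbind(
    matrix(rep(w1, n), n, byrow = TRUE),
    matrix(rep(w2, n), n, byrow = TRUE)
  ) + matrix(rnorm(2 * n * 7, 0, 0.3), 2 * n)
  rownames(m) <- sprintf("r%03d", seq_len(2 * n))
  cl <- hca_pearson(m, k = 2)
  expect_gte(mclust::adjustedRandIndex(cl$labels, truth_lab), 0.9)
  # row order only permutes the labels
  perm <- sample(nrow(m))
  cl2 <- hca_pearson(m[perm, ], k = 2)
  expect_equal(mclust::adjustedRandIndex(cl2$labels[rownames(m)], cl$labels), 1)
})

test_that("wave-cluster extraction applies the profile filters", {
  m <- rbind(up = c(0.2, 0.6, 0.1), flat = c(-0.5, -0.1, 0),
             high = c(0.1, 0.9, 0.4))
  labels <- c(up = 1L, flat = 1L, high = 1L)
  # the maximum-above-zero rule excludes the series that never rises
  f0 <- extract_wave_cluster(m, labels, 1L, "max_gt", 0)
  expect_setequal(f0$ids, c("up", "high"))
  # the stricter averaged rule at 0.5 keeps series peaking above it
  f5 <- extract_wave_cluster(m, labels, 1L, "avg_gt", 0.5)
  expect_setequal(f5$ids, c("up", "high"))
  expect_equal(f5$mean_series, colMeans(m[c("up", "high"), ]))
  # threshold -Inf is the identity
  fi <- extract_wave_cluster(m, labels, 1L, "max_gt", -Inf)
  expect_setequal(fi$ids, rownames(m))
  expect_message(
    fe <- extract_wave_cluster(m, labels, 1L, "max_gt", 10),
    "no rows"
  )
  expect_equal(fe$n_rows, 0L)
})

test_that("PCA scores separate templates, dedupe identically, conserve variance", {
  set.seed(72)
  w1 <- c(2.5, 1.5, 0.8, 0.3, 0.1, 0, 0)
  w2 <- c(0, 0.1, 0.4, 1.2, 2.5, 2.2, 1.5)
  m <- rbind(matrix(rep(w1, 40), 40, byrow = TRUE),
             matrix(rep(w2, 40), 40, byrow = TRUE)) +
    matrix(rnorm(80 * 7, 0, 0.3), 80)
  pc <- pca_scores(m)
  # the two templates are separable by a threshold on PC1
  s1 <- pc$scores[1:40, 1]; s2 <- pc$scores[41:80, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  # duplicated rows get identical scores
  md <- rbind(m, m[1, ])
  pc2 <- pca_scores(md)
  expect_equal(pc2$scores[81, ], pc2$scores[1, ], ignore_attr = TRUE)
  # total variance is conserved across all components
  expect_equal(sum(pc$sdev^2),
               sum(apply(m, 2, var)), tolerance = 1e-10)
  expect_warning(pca_scores(m[, 1:2], n_comp = 5), "components")
})

test_that("hypergeometric enrichment matches hand and exhaustive oracles", {
  # N = 10, K = 5, n = 4, k = 4 -> C(5,4)/C(10,4) = 5/210
  pop <- data.table::data.table(
    ptm = rep(c("Oxidation", "Other"), each = 5), residue = "K")
  cl <- pop[c(1:4), ]
  res <- ptm_enrichment(cl, pop, min_psms = 0L)
  expect_equal(res[res$ptm == "Oxidation", ]$p, 5 / 210, tolerance = 1e-12)
  # K = N: certainty, p = 1 for any k
  pop2 <- data.table::data.table(ptm = "Oxidation", residue = rep("K", 8))
  expect_equal(ptm_enrichment(pop2[1:3, ], pop2, min_psms = 0L)$p, 1)
  # exhaustive enumeration for N <= 12
  set.seed(73)
  for (i in 1:5) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    pop3 <- data.table::data.table(
      ptm = c(rep("A", K), rep("B", N - K)), residue = "X")
    ix <- sample(N, n)
    res3 <- ptm_enrichment(pop3[ix, ], pop3, min_psms = 0L)
    k <- sum(ix <= K)
    expect_equal(res3[res3$ptm == "A", ]$p,
                 oracle_hyper_enum(N, K, n, k), tolerance = 1e-12)
  }
  # inconsistent counts are rejected
  expect_error(ptm_enrichment(pop2, pop2[1:3, ], min_psms = 0L), "inconsistent")
  # the reporting threshold hides small populations
  expect_equal(nrow(ptm_enrichment(cl, pop, min_psms = 50L)), 0L)
})

test_that("protein-level oxidized enrichment flags fully oxidized proteins", {
  counts <- data.table::data.table(
    protein = sprintf("P%02d", 1:11),
    total = c(rep(9L, 10), 10L),
    oxidized = c(rep(1L, 10), 10L)   # global fraction 20%, one outlier
  )
  res <- oxidized_protein_enrichment(counts)
  expect_lt(res$p[res$protein == "P11"], 0.01)
  expect_gt(min(res$p[res$protein != "P11"]), 0.4)
  expect_true(all(res$q >= res$p))
  expect_error(oxidized_protein_enrichment(
    data.table::data.table(protein = "P", total = 2L, oxidized = 5L)),
    "exceeds")
})

test_that("rank tests reproduce hand values and exact permutation oracles", {
  # identical distributions: H = 0, p = 1
  same <- list(c(1, 2, 3), c(1, 2, 3))
  kw0 <- group_difference_tests(same, "kruskal_wallis")
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p, 1)
  # Mann-Whitney {1,2,3} vs {4,5,6}: U = 0, exact two-sided p = 0.1
  mw <- group_difference_tests(list(c(1, 2, 3), c(4, 5, 6)), "mann_whitney")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")
  expect_error(group_difference_tests(list(1:3, numeric(0)), "mann_whitney"),
               "at least one value")

  set.seed(74)
  # Mann-Whitney agrees with the full-permutation oracle (with ties)
  for (i in 1:4) {
    x <- sample(1:5, 4, replace = TRUE)
    y <- sample(2:7, 4, replace = TRUE)
    got <- group_difference_tests(list(x, y), "mann_whitney")
    expect_equal(got$p, oracle_mw_perm(x, y), tolerance = 1e-12)
  }
  # Kruskal-Wallis agrees with the n! label-permutation oracle
  groups <- list(c(1.2, 3.4, 2.2), c(5.1, 4.4), c(0.3, 2.9))
  got <- group_difference_tests(groups, "kruskal_wallis")
  expect_equal(got$method, "exact")
  expect_equal(got$p, oracle_kw_perm(groups), tolerance = 1e-9)
  # tied variant
  groups2 <- list(c(1, 2, 2), c(3, 3), c(1, 4))
  got2 <- group_difference_tests(groups2, "kruskal_wallis")
  expect_equal(got2$p, oracle_kw_perm(groups2), tolerance = 1e-9)

  # large-sample approximations agree with the stats package cross-checks
  set.seed(75)
  x <- rnorm(30); y <- rnorm(30, 0.8)
  approx_mw <- group_difference_tests(list(x, y), "mann_whitney")
  expect_equal(approx_mw$method, "approximate")
  expect_equal(approx_mw$p,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 0.02)
  g3 <- list(rnorm(12), rnorm(12, 0.5), rnorm(12, 1))
  approx_kw <- group_difference_tests(g3, "kruskal_wallis")
  pooled <- unlist(g3)
  lab <- factor(rep(1:3, each = 12))
  expect_equal(approx_kw$p, stats::kruskal.test(pooled, lab)$p.value,
               tolerance = 1e-9)
})
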