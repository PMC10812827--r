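# Time-course analysis: replicate-averaged standardized matrices,
# Pearson-distance hierarchical clustering, PCA, oxidation-wave cluster
# extraction, hypergeometric enrichment on PSM counts, and rank-based
# group-difference tests with exact small-sample p-values.

#' Replicate-averaged time-course matrix
#'
#' Averages standardized values (Zp/Zq/Zc) over the biological replicates
#' of each time point. Rows with an entirely missing time point are
#' dropped with a message.
#'
#' @param z_table Long table with columns `id`, `sample_id`, `z`.
#' @param design Design table mapping samples to time points.
#' @param timepoints Ordered time-point labels; default: order of first
#'   appearance among non-reference, non-pool, non-baseline design rows.
#' @return List of class `oxwave_timecourse`: `values` (row x time matrix
#'   of means), `n` (replicate counts per cell), `timepoints`.
#' @export
build_timecourse_matrix <- function(z_table, design, timepoints = NULL) {
  zt <- data.table::as.data.table(z_table)
  stopifnot(all(c("id", "sample_id", "z") %in% names(zt)))
  des <- data.table::as.data.table(design)
  smap <- des[!is_reference & !(group_label %in% c("pool", "reference"))]
  if (is.null(timepoints)) {
    tp <- unique(smap$timepoint_label)
    timepoints <- tp[tp != "baseline" & nzchar(tp)]
  }
  zt <- merge(zt, smap[, .(sample_id, timepoint_label)], by = "sample_id")
  zt <- zt[timepoint_label %in% timepoints & is.finite(z)]
  agg <- zt[, .(m = mean(z), n = .N), by = .(id, timepoint_label)]
  ids <- unique(agg$id)
  values <- matrix(NA_real_, length(ids), length(timepoints),
                   dimnames = list(ids, timepoints))
  nmat <- matrix(0L, length(ids), length(timepoints),
                 dimnames = list(ids, timepoints))
  values[cbind(match(agg$id, ids), match(agg$timepoint_label, timepoints))] <- agg$m
  nmat[cbind(match(agg$id, ids), match(agg$timepoint_label, timepoints))] <- agg$n
  incomplete <- apply(values, 1L, anyNA)
  if (any(incomplete)) {
    message(sum(incomplete), " row(s) dropped for an all-missing time point")
    values <- values[!incomplete, , drop = FALSE]
    nmat <- nmat[!incomplete, , drop = FALSE]
  }
  structure(list(values = values, n = nmat, timepoints = timepoints),
            class = "oxwave_timecourse")
}

#' Hierarchical clustering with Pearson-correlation distance
#'
#' Pairwise distance between rows is `1 - Pearson r`; rows are merged
#' agglomeratively under `linkage` (average by default). Constant rows
#' (zero variance, correlation undefined) are dropped with a warning.
#' `stats::hclust` merge order is deterministic.
#'
#' @param matrix A time-course object from [build_timecourse_matrix()] or
#'   a numeric matrix (rows = series).
#' @param linkage Agglomeration rule passed to [stats::hclust()].
#' @param k Number of clusters to cut (default 2, mirroring the two main
#'   oxidation-wave clusters).
#' @return List of class `oxwave_clustering`: `labels` (named cluster
#'   labels), `hclust` (the dendrogram), `distance` (the `dist` object).
#' @export
hca_pearson <- function(matrix, linkage = "average", k = 2L) {
  m <- if (inherits(matrix, "oxwave_timecourse")) matrix$values else matrix
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  if (ncol(m) < 3L) stop("need at least 3 time points to cluster")
  rvar <- apply(m, 1L, stats::var)
  if (any(rvar == 0 | is.na(rvar))) {
    warning(sum(rvar == 0 | is.na(rvar)),
            " constant row(s) dropped (correlation undefined)")
    m <- m[rvar > 0 & !is.na(rvar), , drop = FALSE]
    if (nrow(m) < 2L) stop("fewer than 2 non-constant rows remain")
  }
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, k = min(k, nrow(m)))
  structure(list(labels = labels, hclust = hc, distance = d),
            class = "oxwave_clustering")
}

#' Extract an oxidation-wave cluster under a profile filter
#'
#' Keeps the rows of one cluster whose series exceed the threshold in at
#' least one time point, and returns the cluster's mean series with
#' per-time dispersion. The two filter rules differ only in what the row
#' values are expected to be: `max_gt` is the maximum-Zp-above-zero rule
#' applied to any series, `avg_gt` the stricter rule on replicate-averaged
#' series (threshold 0.5 in the source workflow); on a
#' [build_timecourse_matrix()] object both operate on the averaged values.
#'
#' @param matrix Time-course object or numeric matrix.
#' @param labels Cluster labels (e.g. from [hca_pearson()]).
#' @param cluster Which cluster label to extract.
#' @param filter_rule `"max_gt"` or `"avg_gt"`.
#' @param threshold Filter threshold (default 0: the early/late-wave rule;
#'   use 0.5 with `avg_gt` for the stricter rule).
#' @return List: `ids` (surviving rows), `mean_series`, `sd_series`,
#'   `n_rows`.
#' @export
extract_wave_cluster <- function(matrix, labels, cluster,
                                 filter_rule = c("max_gt", "avg_gt"),
                                 threshold = 0) {
  filter_rule <- match.arg(filter_rule)
  m <- if (inherits(matrix, "oxwave_timecourse")) matrix$values else matrix
  ids <- names(labels)[labels == cluster]
  m <- m[rownames(m) %in% ids, , drop = FALSE]
  keep <- switch(filter_rule,
    max_gt = apply(m, 1L, max, na.rm = TRUE) > threshold,
    avg_gt = apply(m, 1L, max, na.rm = TRUE) > threshold
  )
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) {
    message("no rows of cluster ", cluster, " pass the ", filter_rule,
            "(", threshold, ") filter")
    return(list(ids = character(), mean_series = rep(NA_real_, ncol(m)),
                sd_series = rep(NA_real_, ncol(m)), n_rows = 0L))
  }
  list(ids = rownames(m),
       mean_series = colMeans(m, na.rm = TRUE),
       sd_series = apply(m, 2L, stats::sd, na.rm = TRUE),
       n_rows = nrow(m))
}

#' PCA scores of time-course rows
#'
#' Column-centred principal component decomposition of the row series.
#' Component signs follow the convention that each component's
#' largest-magnitude loading is positive. If fewer components are available
#' than requested, the count is reduced with a warning.
#'
#' @param matrix Time-course object or numeric matrix.
#' @param n_comp Number of leading components (default 2).
#' @return List: `scores` (rows x components), `loadings`, `sdev`
#'   (all components' standard deviations).
#' @export
pca_scores <- function(matrix, n_comp = 2L) {
  m <- if (inherits(matrix, "oxwave_timecourse")) matrix$values else matrix
  if (nrow(m) < 2L) stop("need at least 2 rows for PCA")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  avail <- ncol(pc$x)
  if (avail < n_comp) {
    warning("only ", avail, " components available; reducing from ", n_comp)
    n_comp <- avail
  }
  flip <- vapply(seq_len(n_comp), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(n_comp), drop = FALSE], 2L, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(n_comp), drop = FALSE], 2L, flip, `*`)
  list(scores = scores, loadings = loadings, sdev = pc$sdev)
}

#' Hypergeometric PTM enrichment of a cluster
#'
#' For each (PTM type, residue) pair, tests whether the cluster contains
#' more PSMs of that pair than expected from the reference population:
#' p = P(X >= k) with X ~ Hypergeometric(N = population PSMs, K =
#' population PSMs of the pair, n = cluster PSMs). Only pairs with more
#' than `min_psms` population PSMs are reported.
#'
#' @param cluster_psms,all_psms Tables with one row per PSM and columns
#'   `ptm` and `residue`; `all_psms` is the reference population (it must
#'   contain the cluster).
#' @param min_psms Minimum population PSM count per pair (default 50).
#' @return `data.table`: `ptm`, `residue`, `k` (cluster count), `K`
#'   (population count), `n`, `N`, `p`.
#' @export
ptm_enrichment <- function(cluster_psms, all_psms, min_psms = 50L) {
  cl <- data.table::as.data.table(cluster_psms)
  pop <- data.table::as.data.table(all_psms)
  stopifnot(all(c("ptm", "residue") %in% names(cl)),
            all(c("ptm", "residue") %in% names(pop)))
  N <- nrow(pop)
  n <- nrow(cl)
  popc <- pop[, .(K = .N), by = .(ptm, residue)]
  clc <- cl[, .(k = .N), by = .(ptm, residue)]
  res <- merge(popc, clc, by = c("ptm", "residue"), all.x = TRUE)
  res[is.na(k), k := 0L]
  if (any(res$k > pmin(res$K, n))) {
    stop("inconsistent counts: cluster exceeds population for some PTM/residue")
  }
  res <- res[K > min_psms]
  res[, `:=`(n = n, N = N)]
  res[, p := stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)]
  data.table::setorder(res, p)
  res[]
}

#' Per-protein oxidized-PSM enrichment
#'
#' Tests each protein for enrichment in oxidized PSMs: with the total
#' oxidized-PSM count as the population frequency and each protein's total
#' PSM count as its draw, p = P(X >= k_oxidized). BH-adjusted across
#' proteins.
#'
#' @param protein_psm_counts Table with columns `protein`, `total`,
#'   `oxidized`.
#' @return `data.table` with `p` and `q` per protein.
#' @export
oxidized_protein_enrichment <- function(protein_psm_counts) {
  dt <- data.table::as.data.table(protein_psm_counts)
  stopifnot(all(c("protein", "total", "oxidized") %in% names(dt)))
  if (any(dt$oxidized > dt$total)) stop("oxidized count exceeds total for some protein")
  N <- sum(dt$total)
  K <- sum(dt$oxidized)
  out <- data.table::copy(dt)
  out[, p := stats::phyper(oxidized - 1L, K, N - K, total, lower.tail = FALSE)]
  out[, q := stats::p.adjust(p, method = "BH")]
  data.table::setorder(out, p)
  out[]
}

# tie-corrected Kruskal-Wallis H statistic from pooled values and labels
.kw_stat <- function(values, g) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) return(0)  # all values identical
  h / corr
}

# Mann-Whitney U of group 1 vs group 2 from ranks
.mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# enumerate all assignments of n items into groups of given sizes;
# returns a list of label vectors (group index per item)
.enumerate_groupings <- function(sizes) {
  n <- sum(sizes)
  out <- list()
  recurse <- function(remaining, labels, gi) {
    if (gi == length(sizes)) {
      labels[remaining] <- gi
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (cmb in utils::combn(remaining, sizes[gi], simplify = FALSE)) {
      lab <- labels
      lab[cmb] <- gi
      recurse(setdiff(remaining, cmb), lab, gi + 1L)
    }
  }
  recurse(seq_len(n), integer(n), 1L)
  out
}

# H statistic from precomputed ranks and tie-correction factor
.kw_stat_ranks <- function(r, g, corr) {
  n <- length(r)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  if (corr <= 0) return(0)
  h / corr
}

#' Rank-based group-difference tests
#'
#' Mann-Whitney (2 groups) or Kruskal-Wallis (>= 2 groups) with tie
#' correction. Exact p-values by complete enumeration of group assignments
#' when the total sample size is at most `exact_max_n` (Mann-Whitney:
#' two-sided p = 2 x min(tail probabilities), capped at 1; Kruskal-Wallis:
#' P(H >= H_obs)); otherwise the normal (Mann-Whitney, with continuity
#' correction) or chi-squared (Kruskal-Wallis) approximation.
#'
#' @param z_values_by_group List of numeric vectors, one per group (each
#'   non-empty).
#' @param test `"kruskal_wallis"` or `"mann_whitney"`.
#' @param exact_max_n Largest total n for exact enumeration (default 10
#'   for Mann-Whitney per spec'd small-sample regime, 8 for
#'   Kruskal-Wallis; pass a single number to override both).
#' @return List: `statistic`, `p`, `method` ("exact" or "approximate").
#' @export
group_difference_tests <- function(z_values_by_group,
                                   test = c("kruskal_wallis", "mann_whitney"),
                                   exact_max_n = NULL) {
  test <- match.arg(test)
  g <- z_values_by_group
  if (any(lengths(g) == 0L)) stop("every group must contain at least one value")
  sizes <- lengths(g)
  pooled <- unlist(g, use.names = FALSE)
  n <- length(pooled)
  if (test == "mann_whitney") {
    if (length(g) != 2L) stop("mann_whitney requires exactly 2 groups")
    if (is.null(exact_max_n)) exact_max_n <- 20L  # i.e. up to 10 per group
    u_obs <- .mw_u(g[[1]], g[[2]])
    if (n <= exact_max_n && max(sizes) <= 10L) {
      r <- rank(pooled)
      off <- sizes[1] * (sizes[1] + 1) / 2
      labelings <- .enumerate_groupings(sizes)
      u_all <- vapply(labelings, function(lab) sum(r[lab == 1L]) - off,
                      numeric(1))
      p <- min(1, 2 * min(mean(u_all <= u_obs + 1e-9),
                          mean(u_all >= u_obs - 1e-9)))
      return(list(statistic = u_obs, p = p, method = "exact"))
    }
    n1 <- sizes[1]; n2 <- sizes[2]
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(statistic = u_obs, p = 1, method = "approximate"))
    zstat <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(abs(zstat), lower.tail = FALSE)
    return(list(statistic = u_obs, p = min(1, p), method = "approximate"))
  }
  # Kruskal-Wallis
  if (is.null(exact_max_n)) exact_max_n <- 8L
  glab <- rep(seq_along(g), sizes)
  h_obs <- .kw_stat(pooled, glab)
  if (h_obs == 0) return(list(statistic = 0, p = 1,
                              method = if (n <= exact_max_n) "exact" else "approximate"))
  if (n <= exact_max_n) {
    r <- rank(pooled)
    ties <- table(pooled)
    corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    labelings <- .enumerate_groupings(sizes)
    h_all <- vapply(labelings, function(lab) .kw_stat_ranks(r, lab, corr),
                    numeric(1))
    p <- mean(h_all >= h_obs - 1e-9)
    return(list(statistic = h_obs, p = p, method = "exact"))
  }
  p <- stats::pchisq(h_obs, df = length(g) - 1L, lower.tail = FALSE)
  list(statistic = h_obs, p = p, method = "approximate")
}
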