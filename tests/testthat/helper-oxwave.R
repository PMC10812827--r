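# shared fixtures and independent oracles for the test suite

# build a config from defaults with overrides allowed for any field
.config_with <- function(defaults, extra) {
  defaults[names(extra)] <- extra
  do.call(sim_config, defaults)
}

# a small, fast simulation configuration
tiny_config <- function(seed = 42L, ...) {
  .config_with(list(n_proteins = 30L, peptides_per_protein = 4L, seed = seed),
               list(...))
}

# a noise-free configuration: exact delta masses
noisefree_config <- function(seed = 42L, ...) {
  .config_with(list(n_proteins = 30L, peptides_per_protein = 4L,
                    calib_offset_ppm = 0, sigma_ppm = 0, seed = seed),
               list(...))
}

# a null configuration: no injected effects anywhere
null_config <- function(seed = 42L, ...) {
  K <- 7L
  .config_with(list(n_proteins = 60L, peptides_per_protein = 4L,
                    wave1_template = rep(0, K), wave2_template = rep(0, K),
                    redox_wave_template = rep(0, K),
                    category_effects = list(), seed = seed),
               list(...))
}

quiet_fdr <- function(psms) suppressWarnings(compute_fdr(psms))

run_shifts_stages <- function(psms, fdr = 0.01, min_count = NULL) {
  cal <- recalibrate(psms)
  h <- build_deltam_histogram(cal)
  pk <- detect_peaks(h, min_count = min_count)
  cal <- assign_psms_to_peaks(cal, pk)
  cal <- quiet_fdr(cal)
  list(psms = cal, peaks = pk,
       filtered = cal[cal$q_global <= fdr & !cal$is_decoy, ])
}

# --- independent oracles --------------------------------------------------

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
oracle_hyper_enum <- function(N, K, n, k) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2L, function(ix) sum(pop[ix]))
  mean(hits >= k)
}

# truncation explanation by brute force over every terminal run (any depth)
# and both signs; minimal depth preferred, N-terminus before C at tie
oracle_truncation <- function(peptide, delta_mass, tol = 0.01) {
  aa <- strsplit(peptide, "")[[1]]
  rm <- residue_masses()
  if (abs(delta_mass) <= tol) return(NULL)
  best <- NULL
  for (d in seq_len(length(aa) - 1L)) {
    for (term in c("N", "C")) {
      run <- if (term == "N") aa[1:d] else aa[(length(aa) - d + 1L):length(aa)]
      m <- sum(rm[run])
      for (type in c("loss", "gain")) {
        target <- if (type == "loss") -m else m
        if (abs(delta_mass - target) <= tol) {
          return(list(terminus = term, residues = paste(run, collapse = ""),
                      type = type))
        }
      }
    }
  }
  best
}

# all permutations of seq_len(n) (recursive, independent of utils::combn)
oracle_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- oracle_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos)
    }
  }
  out
}

# exact Kruskal-Wallis p by full n! label permutation, statistic from
# stats::kruskal.test (tie-corrected H)
oracle_kw_perm <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  labels <- rep(seq_along(groups), lengths(groups))
  h_obs <- unname(stats::kruskal.test(pooled, factor(labels))$statistic)
  perms <- oracle_permutations(length(pooled))
  h_all <- vapply(perms, function(p) {
    unname(stats::kruskal.test(pooled[p], factor(labels))$statistic)
  }, numeric(1))
  mean(h_all >= h_obs - 1e-9)
}

# exact two-sided Mann-Whitney p by full permutation of labels
oracle_mw_perm <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  sets <- utils::combn(length(pooled), n1, simplify = FALSE)
  u_all <- vapply(sets, u_of, numeric(1))
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

skip_if_no_mclust <- function() {
  testthat::skip_if_not_installed("mclust")
}

# adjusted Rand index from the contingency-table formula
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) sum(x * (x - 1) / 2)
  sum_ij <- ch2(tab)
  sum_a <- ch2(rowSums(tab))
  sum_b <- ch2(colSums(tab))
  n2 <- ch2(sum(tab))
  exp_ij <- sum_a * sum_b / n2
  (sum_ij - exp_ij) / ((sum_a + sum_b) / 2 - exp_ij)
}

# recode curated-PSM composition into the two oxidation-wave residue
# classes used for cluster enrichment
wave_class_pop <- function(curated) {
  cur <- data.table::as.data.table(curated)
  cur[, key := paste(peptide, ptm, site_position, sep = "|")]
  pop <- cur[, .(ptm = rep(ptm, n_psms), residue = rep(site_residue, n_psms),
                 key = rep(key, n_psms))]
  pop[, class := data.table::fcase(
    ptm == "Oxidation" & residue %in% c("K", "F", "N", "D"), "kfnd_monoox",
    ptm %in% c("Oxidation", "Dioxidation", "Trioxidation") &
      residue %in% c("C", "W"), "cw_multiox",
    default = "other"
  )]
  pop
}
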