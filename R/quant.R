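# Hierarchical standardized quantification: spectrum -> peptide -> protein
# -> grand mean, weighted by inverse total variance at each level, with the
# level variances estimated by a unit-variance-of-z fixed point. Produces
# Zp (peptide vs its protein) and Zq (protein vs grand mean). Modified
# peptides are quantified in a second pass against protein values and
# variances frozen from the unmodified-peptide pass.

#' Spectrum-level log2 ratios against each plex reference channel
#'
#' For every PSM and every non-reference channel in the design, computes
#' x = log2(sample intensity / reference intensity). Spectra with a
#' non-positive reference intensity are excluded with a warning;
#' non-positive sample intensities yield missing values.
#'
#' @param psms PSM table (see [read_psm_table()]); extra columns
#'   `peptide_key` and `modified` are carried through when present.
#' @param design Design table (see [read_design()]).
#' @return Long `data.table`: `spectrum_id`, `peptide`, `peptide_key`,
#'   `protein`, `modified`, `plex_id`, `sample_id`, `group_label`,
#'   `timepoint_label`, `x`.
#' @export
compute_log2_ratios <- function(psms, design) {
  dt <- data.table::as.data.table(psms)
  des <- data.table::as.data.table(design)
  validate_design(des)
  if (!"peptide_key" %in% names(dt)) dt[, peptide_key := peptide]
  if (!"modified" %in% names(dt)) dt[, modified := FALSE]
  out <- vector("list", length(unique(des$plex_id)))
  n_badref <- 0L
  k <- 0L
  for (plex in unique(des$plex_id)) {
    sub <- dt[plex_id == plex]
    if (nrow(sub) == 0L) next
    dplex <- des[plex_id == plex]
    ref_col <- .intensity_col(dplex$channel_index[dplex$is_reference])
    ref <- sub[[ref_col]]
    bad <- is.na(ref) | ref <= 0
    n_badref <- n_badref + sum(bad)
    sub <- sub[!bad]
    ref <- ref[!bad]
    if (nrow(sub) == 0L) next
    for (i in which(!dplex$is_reference)) {
      v <- sub[[.intensity_col(dplex$channel_index[i])]]
      x <- ifelse(!is.na(v) & v > 0, log2(v / ref), NA_real_)
      k <- k + 1L
      out[[k]] <- data.table::data.table(
        spectrum_id = sub$spectrum_id, peptide = sub$peptide,
        peptide_key = sub$peptide_key, protein = sub$protein,
        modified = sub$modified, plex_id = plex,
        sample_id = dplex$sample_id[i], group_label = dplex$group_label[i],
        timepoint_label = dplex$timepoint_label[i], x = x
      )
    }
  }
  if (n_badref > 0L) {
    warning(n_badref, " spectra excluded for non-positive reference intensity")
  }
  res <- data.table::rbindlist(out[seq_len(k)])
  res[]
}

#' Weighted integration of one level into its parent
#'
#' Parent value is the weighted mean `sum(w * x) / sum(w)`; each child's
#' standardized deviation is `z = (x - parent) * sqrt(w)`. The parent's
#' precision (weight at the next level, before adding that level's
#' variance) is `sum(w)`.
#'
#' @param x Child values (finite).
#' @param w Child weights (> 0).
#' @return List with `x` (parent value), `w` (parent precision = sum of
#'   child weights) and `z` (per-child standardized deviations).
#' @export
integrate_level <- function(x, w) {
  keep <- is.finite(x) & is.finite(w)
  if (!any(keep)) stop("no children with finite value and weight")
  if (any(w[keep] <= 0)) stop("weights must be positive")
  x <- x[keep]; w <- w[keep]
  xp <- sum(w * x) / sum(w)
  z <- rep(NA_real_, length(keep))
  z[keep] <- (x - xp) * sqrt(w)
  list(x = xp, w = sum(w), z = z)
}

# grouped weighted means and z for a whole level at once
.integrate_grouped <- function(x, w, parent) {
  dt <- data.table::data.table(x = x, w = w, parent = parent)
  par <- dt[, .(x = sum(w * x) / sum(w), w = sum(w)), by = parent]
  z <- (x - par$x[match(parent, par$parent)]) * sqrt(w)
  list(parents = par, z = z)
}

#' Estimate a level variance by the unit-variance-of-z fixed point
#'
#' Finds `sigma2 >= 0` such that, with weights
#' `w = 1 / (sigma2 + 1 / prec)`, the sample variance of the standardized
#' deviations `z = (x - parent_mean) * sqrt(w)` (parent means re-fitted at
#' each candidate `sigma2`) equals 1. The variance of z is computed after
#' winsorizing z at its 1st and 99th percentiles to damp outliers. Solved
#' by bisection; monotonically decreasing in `sigma2`.
#'
#' @param x Child values.
#' @param prec Child precisions (inverse variance contributed by lower
#'   levels; `Inf` allowed).
#' @param parent Parent identifier per child.
#' @param max_iter Bisection iterations.
#' @return List with `sigma2` and `converged`.
#' @export
estimate_level_variance <- function(x, prec, parent, max_iter = 60L) {
  keep <- is.finite(x) & !is.na(parent) & prec > 0
  x <- x[keep]; prec <- prec[keep]; parent <- parent[keep]
  if (length(x) < 2L) return(list(sigma2 = 0, converged = FALSE))
  if (length(x) < 20L) {
    warning("fewer than 20 children for level-variance estimation; ",
            "estimate may be unstable")
  }
  # variance of z after 1-99% winsorization, rescaled by the expected
  # winsorized variance of a standard normal so the estimator stays
  # consistent under normality
  z0 <- stats::qnorm(0.99)
  wins_const <- 1 - 2 * z0 * stats::dnorm(z0) - 2 * stats::pnorm(z0, lower.tail = FALSE) +
    2 * z0^2 * stats::pnorm(z0, lower.tail = FALSE)
  vz <- function(s2) {
    w <- 1 / (s2 + 1 / prec)
    z <- .integrate_grouped(x, w, parent)$z
    if (all(!is.finite(z))) return(0)
    z <- z[is.finite(z)]
    qs <- stats::quantile(z, c(0.01, 0.99), names = FALSE)
    stats::var(pmin(pmax(z, qs[1]), qs[2])) / wins_const
  }
  if (vz(0) <= 1) return(list(sigma2 = 0, converged = TRUE))
  hi <- stats::var(x)
  if (!is.finite(hi) || hi <= 0) hi <- 1
  it <- 0L
  while (vz(hi) > 1 && it < 40L) { hi <- hi * 4; it <- it + 1L }
  lo <- 0
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (vz(mid) > 1) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-10 * max(1, hi)) break
  }
  s2 <- (lo + hi) / 2
  converged <- abs(vz(s2) - 1) < 1e-3
  if (!converged) {
    warning("level-variance fixed point did not fully converge; ",
            "returning best iterate")
  }
  list(sigma2 = s2, converged = converged)
}

# one sample's spectrum -> peptide -> protein -> grand integration
.wspp_one_sample <- function(r, frozen = NULL) {
  # r: data.table with peptide_key, protein, modified, x (finite)
  unmod <- r[modified == FALSE]
  if (is.null(frozen)) {
    if (nrow(unmod) < 2L) stop("not enough unmodified spectra in a sample")
    # spectrum level: equal precisions, variance from the fixed point
    s2s <- estimate_level_variance(unmod$x, rep(Inf, nrow(unmod)),
                                   unmod$peptide_key)$sigma2
    if (s2s <= 0) s2s <- 1e-12
    pep <- unmod[, .(x = mean(x), n_spectra = .N, protein = protein[1]),
                 by = peptide_key]
    pep[, prec := n_spectra / s2s]
    s2p <- estimate_level_variance(pep$x, pep$prec, pep$protein)$sigma2
    pep[, w := 1 / (s2p + 1 / prec)]
    gp <- .integrate_grouped(pep$x, pep$w, pep$protein)
    pep[, Zp := gp$z]
    prot <- gp$parents
    data.table::setnames(prot, "parent", "protein")
    data.table::setnames(prot, "w", "prec")
    s2q <- estimate_level_variance(prot$x, prot$prec, rep("grand", nrow(prot)))$sigma2
    prot[, w := 1 / (s2q + 1 / prec)]
    grand <- sum(prot$w * prot$x) / sum(prot$w)
    prot[, Zq := (x - grand) * sqrt(w)]
    pep[, modified := FALSE]
    list(peptides = pep, proteins = prot, grand = grand,
         sigma2 = c(spectrum = s2s, peptide = s2p, protein = s2q))
  } else {
    # pass 2: modified peptidoforms against frozen protein values/variances
    mod <- r[modified == TRUE]
    if (nrow(mod) == 0L) return(NULL)
    pep <- mod[, .(x = mean(x), n_spectra = .N, protein = protein[1]),
               by = peptide_key]
    pep[, prec := n_spectra / frozen$sigma2[["spectrum"]]]
    pep[, w := 1 / (frozen$sigma2[["peptide"]] + 1 / prec)]
    px <- frozen$proteins$x[match(pep$protein, frozen$proteins$protein)]
    no_anchor <- is.na(px)
    if (any(no_anchor)) {
      message(sum(no_anchor), " modified peptidoform(s) without an ",
              "unmodified-peptide protein anchor were excluded")
    }
    pep[, Zp := (x - px) * sqrt(w)]
    pep <- pep[!no_anchor]
    pep[, modified := TRUE]
    pep
  }
}

#' Two-pass weighted spectrum-peptide-protein quantification
#'
#' Pass 1 integrates unmodified peptides spectrum -> peptide -> protein ->
#' grand mean for each sample, estimating the spectrum, peptide and protein
#' level variances by the unit-variance-of-z fixed point, and standardizes
#' protein values against the grand mean (Zq) and peptides against their
#' proteins (Zp). Pass 2 quantifies modified peptidoforms using the
#' variances and protein values frozen from pass 1, so adding modified
#' peptides never changes any protein's Zq. Modified peptidoforms whose
#' protein has no unmodified anchor are excluded with a message.
#'
#' @param psms FDR-filtered PSM table; optional columns `peptide_key`
#'   (peptidoform identifier, default the peptide sequence) and `modified`
#'   (logical; default all `FALSE`).
#' @param design Design table.
#' @param samples Optional character vector restricting which samples are
#'   quantified (default: all non-reference, non-pool samples).
#' @return List of class `oxwave_quant`: `peptides` (per sample: `x`, `w`,
#'   `Zp`, `modified`), `proteins` (per sample: `x`, `w`, `Zq`), `grand`
#'   (per-sample grand mean), `variances` (per-sample level variances).
#' @export
run_wspp <- function(psms, design, samples = NULL) {
  ratios <- compute_log2_ratios(psms, design)
  ratios <- ratios[is.finite(x)]
  ratios <- ratios[!(group_label %in% c("pool", "reference"))]
  if (!is.null(samples)) ratios <- ratios[sample_id %in% samples]
  if (nrow(ratios) == 0L) stop("no quantifiable spectra")
  peps <- list(); prots <- list(); grands <- list(); vars <- list()
  for (s in unique(ratios$sample_id)) {
    r <- ratios[sample_id == s]
    p1 <- .wspp_one_sample(r)
    p2 <- .wspp_one_sample(r, frozen = p1)
    pep <- data.table::rbindlist(list(p1$peptides, p2), fill = TRUE)
    pep[, sample_id := s]
    p1$proteins[, sample_id := s]
    peps[[s]] <- pep
    prots[[s]] <- p1$proteins
    grands[[s]] <- data.table::data.table(sample_id = s, grand = p1$grand)
    vars[[s]] <- data.table::data.table(
      sample_id = s, level = names(p1$sigma2), sigma2 = unname(p1$sigma2))
  }
  meta <- unique(ratios[, .(sample_id, group_label, timepoint_label, plex_id)])
  out <- list(
    peptides = merge(data.table::rbindlist(peps), meta, by = "sample_id"),
    proteins = merge(data.table::rbindlist(prots), meta, by = "sample_id"),
    grand = data.table::rbindlist(grands),
    variances = data.table::rbindlist(vars)
  )
  class(out) <- "oxwave_quant"
  out
}

#' @export
print.oxwave_quant <- function(x, ...) {
  cat("oxwave quantification:",
      data.table::uniqueN(x$proteins$protein), "proteins,",
      data.table::uniqueN(x$peptides$peptide_key), "peptidoforms across",
      data.table::uniqueN(x$proteins$sample_id), "samples\n")
  invisible(x)
}
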