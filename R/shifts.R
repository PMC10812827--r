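# Open-search delta-mass post-processing: recalibration, histogram peak
# modelling, PSM-to-peak assignment, three-scope target-decoy FDR,
# annotation against a known-modification list, truncation and
# site-position checks, and curation of modified peptides.

#' Recalibrate observed masses by a constant ppm offset
#'
#' Estimates one systematic ppm offset from a high-quality PSM subset
#' (score above `min_score` and delta mass within `ppm_window` ppm of the
#' nearest isotope-spacing hypothesis, i.e. a multiple of 1.003355 Da) and
#' divides all observed masses by it. The isotope grid keeps genuinely
#' modified populations (oxidation at ~16 Da, alkylation tags at ~57/46 Da)
#' out of the calibration subset while retaining unmodified and
#' isotope-error PSMs. Decoy PSMs never enter the subset. Idempotent to
#' numerical tolerance.
#'
#' @param psms PSM table (see [read_psm_table()]).
#' @param min_score Minimum corrected score for the calibration subset.
#' @param ppm_window Tolerance (ppm) around the nearest hypothesis.
#' @return The PSM table with corrected `observed_mass` and recomputed
#'   `delta_mass`; the estimated offset is attached as attribute
#'   `ppm_offset`. If fewer than 30 PSMs pass the quality gate the input is
#'   returned unchanged with a warning.
#' @export
recalibrate <- function(psms, min_score = 0.15, ppm_window = 20) {
  if (nrow(psms) == 0L) stop("empty PSM table")
  hyp <- round(psms$delta_mass / .MASS_ISOTOPE) * .MASS_ISOTOPE
  ppm_err <- (psms$delta_mass - hyp) / psms$observed_mass * 1e6
  gate <- psms$score >= min_score & abs(ppm_err) <= ppm_window & !psms$is_decoy
  if (sum(gate) < 30L) {
    warning("only ", sum(gate), " PSMs pass the calibration quality gate; ",
            "skipping recalibration")
    out <- data.table::copy(data.table::as.data.table(psms))
    data.table::setattr(out, "ppm_offset", 0)
    return(out[])
  }
  offset <- stats::median(ppm_err[gate])
  out <- data.table::copy(data.table::as.data.table(psms))
  out[, observed_mass := observed_mass / (1 + offset * 1e-6)]
  out[, delta_mass := observed_mass - theoretical_mass]
  data.table::setattr(out, "ppm_offset", offset)
  out[]
}

#' Delta-mass histogram
#'
#' Bins delta masses into half-open bins `[low, high)` of width
#' `bin_width`, anchored at multiples of the bin width. Only occupied bins
#' are returned; bin counts sum to the PSM count.
#'
#' @param psms PSM table.
#' @param bin_width Bin width in Da (default 1 mDa).
#' @return `data.table` with `bin_index`, `bin_low`, `bin_high`, `count`,
#'   sorted by `bin_index`; `bin_width` attached as an attribute.
#' @export
build_deltam_histogram <- function(psms, bin_width = 0.001) {
  if (nrow(psms) == 0L) stop("empty PSM table")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  idx <- floor(psms$delta_mass / bin_width)
  tab <- table(idx)
  hist <- data.table::data.table(
    bin_index = as.numeric(names(tab)),
    count = as.integer(tab)
  )
  data.table::setorder(hist, bin_index)
  hist[, `:=`(bin_low = bin_index * bin_width,
              bin_high = (bin_index + 1) * bin_width)]
  data.table::setattr(hist, "bin_width", bin_width)
  hist[]
}

#' Detect peaks in a delta-mass histogram
#'
#' A peak apex is a bin whose count reaches `min_count` and exceeds both
#' neighbouring counts (missing bins count 0), i.e. the bin-to-bin slope
#' changes sign from rise to fall. Each peak then extends outward over
#' contiguous occupied bins while counts decrease monotonically; peaks are
#' disjoint (apices claimed in decreasing count order, ties by lower bin
#' index).
#'
#' @param histogram Output of [build_deltam_histogram()].
#' @param min_count Minimum apex count; default 5 times the median occupied
#'   bin count.
#' @return `data.table` of peaks: `peak_id`, `apex_deltam` (count-weighted
#'   centre of the peak extent), `bin_low`, `bin_high` (half-open extent),
#'   `psm_count`.
#' @export
detect_peaks <- function(histogram, min_count = NULL) {
  if (nrow(histogram) == 0L) stop("empty histogram")
  bw <- attr(histogram, "bin_width")
  if (is.null(bw)) bw <- stats::median(histogram$bin_high - histogram$bin_low)
  if (is.null(min_count)) min_count <- 5 * stats::median(histogram$count)
  h <- data.table::as.data.table(histogram)
  data.table::setorder(h, bin_index)
  n <- nrow(h)
  idx <- h$bin_index
  cnt <- h$count
  left <- c(NA, cnt[-n]); left[c(TRUE, diff(idx) != 1)] <- 0
  right <- c(cnt[-1], NA); right[c(diff(idx) != 1, TRUE)] <- 0
  # an apex is a bin (or the first bin of a plateau of equal counts over
  # contiguous bins) where the slope changes sign: rise on the left, fall
  # after the plateau
  apex <- integer(0)
  i <- 1L
  while (i <= n) {
    if (cnt[i] >= min_count && left[i] < cnt[i]) {
      j <- i
      while (j < n && idx[j + 1L] == idx[j] + 1 && cnt[j + 1L] == cnt[i]) j <- j + 1L
      if (right[j] < cnt[i]) apex <- c(apex, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(apex) == 0L) {
    return(data.table::data.table(peak_id = character(), apex_deltam = numeric(),
                                  bin_low = numeric(), bin_high = numeric(),
                                  psm_count = integer()))
  }
  apex <- apex[order(-cnt[apex], idx[apex])]
  claimed <- rep(FALSE, n)
  peaks <- list()
  for (a in apex) {
    if (claimed[a]) next
    lo <- a
    while (lo > 1L && !claimed[lo - 1L] && idx[lo - 1L] == idx[lo] - 1 &&
           cnt[lo - 1L] <= cnt[lo] && cnt[lo - 1L] > 0L) lo <- lo - 1L
    hi <- a
    while (hi < n && !claimed[hi + 1L] && idx[hi + 1L] == idx[hi] + 1 &&
           cnt[hi + 1L] <= cnt[hi] && cnt[hi + 1L] > 0L) hi <- hi + 1L
    claimed[lo:hi] <- TRUE
    centers <- (idx[lo:hi] + 0.5) * bw
    peaks[[length(peaks) + 1L]] <- data.table::data.table(
      apex_deltam = sum(cnt[lo:hi] * centers) / sum(cnt[lo:hi]),
      bin_low = idx[lo] * bw,
      bin_high = (idx[hi] + 1) * bw,
      psm_count = sum(cnt[lo:hi])
    )
  }
  out <- data.table::rbindlist(peaks)
  data.table::setorder(out, apex_deltam)
  out[, peak_id := sprintf("peak_%03d", .I)]
  data.table::setcolorder(out, "peak_id")
  out[]
}

#' Assign PSMs to detected peaks
#'
#' A PSM is assigned to the unique peak whose half-open extent
#' `[bin_low, bin_high)` contains its delta mass, else left unassigned
#' (`NA`).
#'
#' @param psms PSM table.
#' @param peaks Output of [detect_peaks()]; extents must be disjoint.
#' @return The PSM table with a `peak_id` column (`NA` = unassigned).
#' @export
assign_psms_to_peaks <- function(psms, peaks) {
  out <- data.table::copy(data.table::as.data.table(psms))
  if (nrow(peaks) == 0L) {
    out[, peak_id := NA_character_]
    return(out[])
  }
  pk <- data.table::as.data.table(peaks)
  data.table::setorder(pk, bin_low)
  if (any(pk$bin_low[-1] < pk$bin_high[-nrow(pk)])) {
    stop("peaks must have disjoint extents")
  }
  i <- findInterval(out$delta_mass, pk$bin_low)
  hit <- i >= 1L & i <= nrow(pk)
  inside <- hit
  inside[hit] <- out$delta_mass[hit] < pk$bin_high[i[hit]]
  out[, peak_id := NA_character_]
  out[inside, peak_id := pk$peak_id[i[inside]]]
  out[]
}

# target-decoy FDR within one scope: sort by descending score, FDR at rank
# k = decoys/targets among the top k, then monotonized into q-values
.td_qvalue <- function(score, is_decoy, warn = TRUE) {
  n <- length(score)
  q <- rep(1, n)
  if (n == 0L) return(q)
  if (sum(!is_decoy) == 0L) {
    if (warn) warning("no target PSMs in an FDR scope; q-values set to 1")
    return(q)
  }
  o <- order(-score)
  d <- cumsum(is_decoy[o])
  t <- cumsum(!is_decoy[o])
  fdr <- ifelse(t == 0L, 1, d / t)
  qv <- rev(cummin(rev(pmin(fdr, 1))))
  q[o] <- qv
  q
}

#' Target-decoy FDR at global, local and peak scope
#'
#' Computes per-PSM q-values in three scopes: global (all PSMs), local
#' (1-Da delta-mass bins, half-open `[n - 0.5, n + 0.5)`), and per detected
#' peak (PSMs sharing a `peak_id`; unassigned PSMs get `NA`). Within each
#' scope, PSMs are ranked by descending score; FDR at each rank is
#' decoys/targets among higher-scoring PSMs, monotonized into q-values.
#'
#' @param psms PSM table; `peak_id` column (from
#'   [assign_psms_to_peaks()]) enables the peak scope.
#' @return The PSM table with `q_global`, `q_local`, `q_peak` columns.
#' @export
compute_fdr <- function(psms) {
  out <- data.table::copy(data.table::as.data.table(psms))
  if (!is.logical(out$is_decoy) || anyNA(out$is_decoy)) {
    stop("every PSM must be flagged target or decoy")
  }
  out[, q_global := .td_qvalue(score, is_decoy)]
  out[, .local_bin := floor(delta_mass + 0.5)]
  out[, q_local := .td_qvalue(score, is_decoy, warn = FALSE), by = .local_bin]
  empty_scopes <- out[, .(no_target = all(is_decoy)), by = .local_bin][no_target == TRUE, .N]
  out[, .local_bin := NULL]
  out[, q_peak := NA_real_]
  if ("peak_id" %in% names(out)) {
    out[!is.na(peak_id), q_peak := .td_qvalue(score, is_decoy, warn = FALSE),
        by = peak_id]
    empty_scopes <- empty_scopes +
      out[!is.na(peak_id), .(no_target = all(is_decoy)), by = peak_id][no_target == TRUE, .N]
  }
  if (empty_scopes > 0L) {
    warning(empty_scopes, " FDR scope(s) contain no target PSMs; ",
            "their q-values are 1")
  }
  out[]
}

#' Summarize target/decoy composition and FDR of each peak
#'
#' @param psms PSM table with `peak_id`.
#' @param peaks Peak table.
#' @return The peak table with `target_count`, `decoy_count` and
#'   `peak_fdr` (= decoys/targets, capped at 1).
#' @export
peak_fdr_summary <- function(psms, peaks) {
  pk <- data.table::copy(data.table::as.data.table(peaks))
  dt <- data.table::as.data.table(psms)
  cnt <- dt[!is.na(peak_id),
            .(target_count = sum(!is_decoy), decoy_count = sum(is_decoy)),
            by = peak_id]
  pk <- merge(pk, cnt, by = "peak_id", all.x = TRUE, sort = FALSE)
  pk[is.na(target_count), `:=`(target_count = 0L, decoy_count = 0L)]
  pk[, peak_fdr := pmin(1, ifelse(target_count == 0L, 1,
                                  decoy_count / target_count))]
  pk[]
}

#' Annotate peaks against a known-modification list
#'
#' Each peak is annotated with the modification whose delta mass is nearest
#' to the peak apex, provided the difference is within `match_tol`; ties
#' are broken by smaller absolute difference, then lexicographic name.
#'
#' @param peaks Peak table.
#' @param mod_list Modification table (see [read_modifications()]).
#' @param match_tol Match tolerance in Da (default 10 mDa).
#' @return The peak table with `mod_name`, `mod_delta`, `is_artifact`,
#'   `is_combination` (all `NA` when unannotated).
#' @export
annotate_peaks <- function(peaks, mod_list, match_tol = 0.01) {
  if (nrow(mod_list) == 0L) stop("empty modification list")
  pk <- data.table::copy(data.table::as.data.table(peaks))
  ml <- data.table::as.data.table(mod_list)
  ml <- ml[order(name)]
  pick <- function(apex) {
    # distances rounded to 0.1 uDa so that exact ties resolve by name
    d <- round(abs(apex - ml$delta_mass), 10)
    j <- which(d <= match_tol)
    if (length(j) == 0L) return(NA_integer_)
    j[order(d[j], ml$name[j])][1]
  }
  j <- vapply(pk$apex_deltam, pick, integer(1))
  pk[, `:=`(
    mod_name = ifelse(is.na(j), NA_character_, ml$name[j]),
    mod_delta = ifelse(is.na(j), NA_real_, ml$delta_mass[j]),
    is_artifact = ifelse(is.na(j), NA, ml$is_artifact[j]),
    is_combination = ifelse(is.na(j), NA, ml$is_combination[j])
  )]
  pk[]
}

#' Explain a delta mass as a terminal truncation
#'
#' Searches both termini for a run of up to `max_depth` residues whose
#' summed residue mass equals `-delta_mass` (residue loss) or `delta_mass`
#' (residue gain, e.g. a missed-cleavage extension by the same residues),
#' within `tol`. Explanations with fewer residues are preferred; N-terminal
#' before C-terminal at equal depth.
#'
#' @param peptide Residue string.
#' @param delta_mass Observed delta mass (Da).
#' @param tol Tolerance (Da).
#' @param max_depth Maximum number of terminal residues considered.
#' @return A list with `terminus` ("N" or "C"), `residues`, `type`
#'   ("loss"/"gain") and `mass`, or `NULL` when no truncation explains the
#'   delta mass (always for `delta_mass` = 0).
#' @export
check_truncation <- function(peptide, delta_mass, tol = 0.01, max_depth = 3L) {
  if (!nzchar(peptide)) stop("empty peptide")
  if (abs(delta_mass) <= tol) return(NULL)
  aa <- strsplit(peptide, "")[[1]]
  rm <- residue_masses()
  depth <- min(max_depth, length(aa) - 1L)
  if (depth < 1L) return(NULL)
  n_runs <- vapply(seq_len(depth), function(d) paste(aa[1:d], collapse = ""),
                   character(1))
  c_runs <- vapply(seq_len(depth), function(d) {
    paste(aa[(length(aa) - d + 1L):length(aa)], collapse = "")
  }, character(1))
  n_mass <- cumsum(rm[aa[seq_len(depth)]])
  c_mass <- cumsum(rm[rev(aa)[seq_len(depth)]])
  for (d in seq_len(depth)) {
    for (term in c("N", "C")) {
      m <- if (term == "N") n_mass[d] else c_mass[d]
      res <- if (term == "N") n_runs[d] else c_runs[d]
      if (abs(delta_mass + m) <= tol) {
        return(list(terminus = term, residues = res, type = "loss", mass = -m))
      }
      if (abs(delta_mass - m) <= tol) {
        return(list(terminus = term, residues = res, type = "gain", mass = m))
      }
    }
  }
  NULL
}

#' Check that a modification site matches its annotation
#'
#' `TRUE` when the residue at `site_position` (position 0 = N-terminus,
#' peptide length + 1 = C-terminus) is among the annotation's allowed
#' residues (`*` allows any). Missing site positions are indeterminate
#' (`NA`).
#'
#' @param peptide Residue string(s).
#' @param site_position 1-based position(s); 0/len+1 denote termini.
#' @param allowed_residues Character vector of allowed residue letters
#'   and/or `"N-term"`/`"C-term"` markers (a list of such vectors for the
#'   vectorized case).
#' @return Logical vector (`NA` = indeterminate).
#' @export
check_site_position <- function(peptide, site_position, allowed_residues) {
  if (!is.list(allowed_residues)) allowed_residues <- list(allowed_residues)
  n <- max(length(peptide), length(site_position), length(allowed_residues))
  peptide <- rep_len(peptide, n)
  site_position <- rep_len(site_position, n)
  allowed_residues <- rep_len(allowed_residues, n)
  vapply(seq_len(n), function(i) {
    pos <- site_position[i]
    if (is.na(pos)) return(NA)
    allowed <- allowed_residues[[i]]
    len <- nchar(peptide[i])
    at <- if (pos == 0L) "N-term"
          else if (pos == len + 1L) "C-term"
          else if (pos >= 1L && pos <= len) substr(peptide[i], pos, pos)
          else return(FALSE)
    "*" %in% allowed || at %in% allowed
  }, logical(1))
}

#' Curate the list of confidently modified peptides
#'
#' Applies the curation filter to FDR-filtered, peak-annotated PSMs: a
#' modified peptidoform is kept iff (a) its peak is annotated with a known
#' modification of non-zero mass, (b) the annotation is neither a known
#' artifact nor a known combination of modifications, (c) the modification
#' site matches the annotation's allowed residues, and (d) the peptidoform
#' is detected in at least `min_replicates` biological replicates of at
#' least one group. Output is sorted and invariant to input row order.
#'
#' @param psms PSM table already filtered to the identification FDR,
#'   carrying `peak_id` (from [assign_psms_to_peaks()]).
#' @param peaks Annotated peak table (from [annotate_peaks()]).
#' @param design Design table (see [read_design()]).
#' @param min_replicates Replicate-detection threshold (default 4).
#' @param mod_list Modification table providing allowed residues for the
#'   site check (default the shipped list).
#' @return `data.table` of curated peptidoforms: `peptide`, `protein`,
#'   `ptm`, `ptm_delta`, `site_position`, `site_residue`, `peak_id`,
#'   `n_replicates_detected`, `n_psms`.
#' @export
curate_modified_peptides <- function(psms, peaks, design, min_replicates = 4L,
                                     mod_list = default_modifications()) {
  empty <- data.table::data.table(
    peptide = character(), protein = character(), ptm = character(),
    ptm_delta = numeric(), site_position = integer(),
    site_residue = character(), peak_id = character(),
    n_replicates_detected = integer(), n_psms = integer()
  )
  dt <- data.table::as.data.table(psms)
  pk <- data.table::as.data.table(peaks)
  need <- c("mod_name", "is_artifact", "is_combination")
  if (!all(need %in% names(pk))) stop("peaks must be annotated (annotate_peaks)")
  dt <- merge(dt, pk[, .(peak_id, mod_name, mod_delta, is_artifact, is_combination)],
              by = "peak_id", all.x = FALSE, sort = FALSE)
  # (a) annotated, non-zero mass; (b) not artifact, not combination
  dt <- dt[!is.na(mod_name) & mod_delta != 0 &
             !is_artifact & !is_combination & !is_decoy]
  if (nrow(dt) == 0L) return(empty)
  # (c) site-position check against the annotation's allowed residues
  mods <- data.table::as.data.table(mod_list)
  allowed <- mods$allowed_residues[match(dt$mod_name, mods$name)]
  ok <- check_site_position(dt$peptide, dt$site_position, allowed)
  dt <- dt[!is.na(ok) & ok]
  if (nrow(dt) == 0L) return(empty)

  # (d) detection in >= min_replicates biological replicates of one group:
  # a peptidoform is detected in a sample when its plex holds a PSM with a
  # positive intensity in that sample's channel
  dt[, form := paste(peptide, mod_name, site_position, sep = "|")]
  des <- data.table::as.data.table(design)
  des <- des[!is_reference & !(group_label %in% c("pool", "reference"))]
  long <- data.table::rbindlist(lapply(seq_len(nrow(des)), function(i) {
    col <- .intensity_col(des$channel_index[i])
    sub <- dt[plex_id == des$plex_id[i] & !is.na(dt[[col]]) & dt[[col]] > 0,
              .(form)]
    if (nrow(sub) == 0L) return(NULL)
    unique(sub)[, `:=`(sample_id = des$sample_id[i], group = des$group_label[i])]
  }))
  if (is.null(long) || nrow(long) == 0L) {
    reps <- data.table::data.table(form = character(), n_rep = integer())
  } else {
    reps <- long[, .(n_samples = data.table::uniqueN(sample_id)),
                 by = .(form, group)][, .(n_rep = max(n_samples)), by = form]
  }
  dt <- merge(dt, reps, by = "form", all.x = TRUE, sort = FALSE)
  dt[is.na(n_rep), n_rep := 0L]
  dt <- dt[n_rep >= min_replicates]

  out <- dt[, .(
    protein = protein[1],
    ptm = mod_name[1],
    ptm_delta = mod_delta[1],
    site_position = site_position[1],
    site_residue = substr(peptide[1], site_position[1], site_position[1]),
    peak_id = peak_id[1],
    n_replicates_detected = n_rep[1],
    n_psms = .N
  ), by = .(peptide, form)][, form := NULL]
  data.table::setorder(out, peptide, ptm, site_position)
  out[]
}
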