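# Differential-alkylation redox readout: free Cys thiols are blocked with
# iodoacetamide (carbamidomethyl, +57.021464 Da) during extraction;
# reversibly oxidized Cys are reduced on-filter and alkylated with MMTS
# (methylthio, +45.987721 Da). The mass tag on each Cys peptide therefore
# encodes its original redox state.

#' Default alkylation tag masses (IAM / MMTS chemistry)
#'
#' @return Named numeric vector: `reduced` (carbamidomethyl, C2H3NO) and
#'   `reversibly_oxidized` (methylthio, CH2S) monoisotopic masses in Da.
#' @export
default_tag_masses <- function() {
  c(reduced = 57.021464, reversibly_oxidized = 45.987721)
}

#' Classify Cys redox state from the alkylation tag mass
#'
#' Each Cys-containing PSM is classified by matching its delta mass (the
#' tag mass in this workflow) against the two alkylator masses: the
#' first-alkylator mass means the thiol was free (reduced) at extraction,
#' the second-alkylator mass means it was reversibly oxidized. No match
#' within `tol` yields `indeterminate`.
#'
#' @param psms PSM table; every peptide must contain at least one Cys.
#' @param tag_masses Named numeric vector with entries `reduced` and
#'   `reversibly_oxidized` (default [default_tag_masses()]).
#' @param tol Match tolerance in Da (default 10 mDa).
#' @return `data.table` of redox calls: `spectrum_id`, `peptide`,
#'   `protein`, `cys_position`, `tag_mass`, `state`.
#' @export
classify_cys_state <- function(psms, tag_masses = default_tag_masses(),
                               tol = 0.01) {
  stopifnot(all(c("reduced", "reversibly_oxidized") %in% names(tag_masses)))
  dt <- data.table::as.data.table(psms)
  no_cys <- !grepl("C", dt$peptide, fixed = TRUE)
  if (any(no_cys)) {
    stop(sum(no_cys), " PSM(s) are not redox-informative peptides (no Cys): ",
         paste(utils::head(unique(dt$peptide[no_cys]), 5L), collapse = ", "))
  }
  tag <- dt$delta_mass
  state <- rep("indeterminate", nrow(dt))
  state[abs(tag - tag_masses[["reduced"]]) <= tol] <- "reduced"
  state[abs(tag - tag_masses[["reversibly_oxidized"]]) <= tol] <- "reversibly_oxidized"
  cys <- ifelse(
    !is.na(dt$site_position) &
      substr(dt$peptide, dt$site_position, dt$site_position) == "C",
    dt$site_position,
    vapply(strsplit(dt$peptide, "", fixed = TRUE),
           function(a) which(a == "C")[1], integer(1))
  )
  data.table::data.table(
    spectrum_id = dt$spectrum_id, peptide = dt$peptide, protein = dt$protein,
    cys_position = as.integer(cys), tag_mass = tag, state = state
  )
}

#' Time course of reversible Cys oxidation
#'
#' Selects the reversibly oxidized Cys peptidoforms from the pass-2
#' quantification and builds their replicate-averaged Zp time-course
#' matrix. Peptides whose parent protein lacked an unmodified-peptide
#' quantification were already excluded by [run_wspp()].
#'
#' @param redox_calls Output of [classify_cys_state()].
#' @param quant Output of [run_wspp()] in which oxidized peptidoforms were
#'   flagged `modified` and keyed by `peptide_key`.
#' @param design Design table.
#' @param timepoints Optional ordered time-point labels (default: from the
#'   design).
#' @return A time-course matrix object (see [build_timecourse_matrix()]).
#' @export
reversible_oxidation_timecourse <- function(redox_calls, quant, design,
                                            timepoints = NULL) {
  calls <- data.table::as.data.table(redox_calls)
  ox_pep <- unique(calls[state == "reversibly_oxidized", peptide])
  pep <- data.table::as.data.table(quant$peptides)
  # peptidoform keys are "<peptide>|<mod>|<site>"; select the
  # methylthio-tagged form of each reversibly oxidized peptide
  base_pep <- sub("\\|.*$", "", pep$peptide_key)
  sel <- pep[modified == TRUE & base_pep %in% ox_pep &
               (grepl("Methylthio", peptide_key, fixed = TRUE) |
                  peptide_key %in% ox_pep)]
  if (nrow(sel) == 0L) {
    stop("no reversibly oxidized peptidoforms found in the quantification")
  }
  build_timecourse_matrix(
    sel[, .(id = peptide_key, sample_id, z = Zp)],
    design, timepoints = timepoints
  )
}
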