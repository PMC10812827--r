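#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) of the 20 amino acid residues
#' (i.e. the mass each residue contributes to a peptide chain, water
#' excluded).
#'
#' @return Named numeric vector, names are one-letter residue codes.
#' @export
#' @examples
#' residue_masses()[["A"]]  # 71.03711
residue_masses <- function() {
  c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
  )
}

# monoisotopic mass of water (Da), completes a peptide's neutral mass
.MASS_WATER <- 18.010565

# monoisotopic spacing of the 13C isotope error (Da); the recalibration
# hypothesis grid is multiples of this value
.MASS_ISOTOPE <- 1.003355

#' Monoisotopic neutral peptide mass
#'
#' @param peptide Character vector of uppercase residue strings.
#' @return Numeric vector of neutral monoisotopic masses (Da). No fixed or
#'   variable modifications are included: in this pipeline modifications
#'   (including the Cys alkylation tags) are read off the precursor
#'   delta mass.
#' @export
#' @examples
#' peptide_mass("ACDEFK")
peptide_mass <- function(peptide) {
  stopifnot(is.character(peptide))
  rm <- residue_masses()
  vapply(strsplit(peptide, "", fixed = TRUE), function(aa) {
    m <- rm[aa]
    if (anyNA(m)) stop("unknown residue in peptide: ", paste(aa, collapse = ""))
    sum(m) + .MASS_WATER
  }, numeric(1))
}
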