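#' @import data.table
NULL

# ---- versioned TSV plumbing --------------------------------------------

# Every table this package writes starts with a one-line versioned header
# "#oxwave-<kind>-v1 rows=<n>" so readers can detect silent truncation by
# comparing the declared and parsed row counts.
.header_line <- function(kind, n) sprintf("#oxwave-%s-v1 rows=%d", kind, n)

.parse_header <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, "#oxwave-")) {
    return(list(kind = NA_character_, rows = NA_integer_, present = FALSE))
  }
  m <- regmatches(first, regexec("^#oxwave-([a-z]+)-v([0-9]+) rows=([0-9]+)$", first))[[1]]
  if (length(m) != 4L) stop("malformed oxwave header line in ", path)
  list(kind = m[2], rows = as.integer(m[4]), present = TRUE)
}

# format doubles so that read-back reproduces the value bit-identically
.fmt_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

.write_versioned_tsv <- function(df, path, kind) {
  dt <- data.table::as.data.table(df)
  for (col in names(dt)) {
    if (is.double(dt[[col]])) data.table::set(dt, j = col, value = .fmt_double(dt[[col]]))
  }
  writeLines(.header_line(kind, nrow(dt)), path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

.read_versioned_tsv <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- .parse_header(path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          skip = if (hdr$present) 1L else 0L,
                          colClasses = "character", na.strings = "NA")
  if (hdr$present) {
    if (!is.na(hdr$kind) && !identical(hdr$kind, kind)) {
      stop("expected an oxwave ", kind, " table, found: ", hdr$kind)
    }
    if (nrow(dt) != hdr$rows) {
      stop("truncated file: header declares ", hdr$rows, " rows but ",
           nrow(dt), " were parsed: ", path)
    }
  }
  dt
}

# convert a character column read from disk, raising a row-level error
# (with the 1-based data line number) on non-convertible values
.convert_col <- function(dt, col, fun, what, path) {
  raw <- dt[[col]]
  val <- suppressWarnings(fun(raw))
  bad <- which(is.na(val) & !is.na(raw) & nzchar(raw))
  if (length(bad) > 0L) {
    stop("non-", what, " value in column '", col, "' at data line ",
         bad[1], " of ", path, ": '", raw[bad[1]], "'")
  }
  data.table::set(dt, j = col, value = val)
}

.as_logical_strict <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "True", "true", "T", "1")] <- TRUE
  out[x %in% c("FALSE", "False", "false", "F", "0")] <- FALSE
  out
}

# ---- PSM tables ---------------------------------------------------------

.PSM_MANDATORY <- c("spectrum_id", "peptide", "charge", "theoretical_mass",
                    "observed_mass", "delta_mass", "score", "is_decoy",
                    "protein", "site_position", "plex_id")

#' Read / write PSM tables
#'
#' PSM tables are tab-delimited UTF-8 files with a versioned first line.
#' Mandatory columns: `spectrum_id`, `peptide`, `charge`,
#' `theoretical_mass`, `observed_mass`, `delta_mass`, `score`, `is_decoy`,
#' `protein`, `site_position`, `plex_id`, plus one `intensity_<k>` column
#' per reporter channel. Unknown columns are preserved as opaque extras.
#'
#' @param path File path.
#' @param validate If `TRUE`, rows whose `delta_mass` disagrees with
#'   `observed_mass - theoretical_mass` by more than 1e-6 Da trigger a
#'   warning listing the offending `spectrum_id`s.
#' @return A `data.table` of PSM records.
#' @export
read_psm_table <- function(path, validate = TRUE) {
  dt <- .read_versioned_tsv(path, "psm")
  missing <- setdiff(.PSM_MANDATORY, names(dt))
  if (length(missing) > 0L) {
    stop("PSM table is missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  if (!any(grepl("^intensity_", names(dt)))) {
    stop("PSM table is missing mandatory column(s): intensity_<k>")
  }
  num_cols <- c("theoretical_mass", "observed_mass", "delta_mass", "score",
                grep("^intensity_", names(dt), value = TRUE),
                intersect(c("truth_deltam"), names(dt)))
  for (col in num_cols) .convert_col(dt, col, as.numeric, "numeric", path)
  .convert_col(dt, "charge", as.integer, "integer", path)
  .convert_col(dt, "site_position", as.integer, "integer", path)
  .convert_col(dt, "is_decoy", .as_logical_strict, "logical", path)
  for (col in grep("^truth_.*(_flag|target)$", names(dt), value = TRUE)) {
    .convert_col(dt, col, .as_logical_strict, "logical", path)
  }
  if (validate) {
    resid <- abs(dt$delta_mass - (dt$observed_mass - dt$theoretical_mass))
    bad <- which(resid > 1e-6)
    if (length(bad) > 0L) {
      warning("delta_mass inconsistent with observed - theoretical for ",
              length(bad), " PSM(s): ",
              paste(utils::head(dt$spectrum_id[bad], 10L), collapse = ", "))
    }
  }
  dt[]
}

#' @param psms Data frame of PSM records (see [read_psm_table()]).
#' @rdname read_psm_table
#' @export
write_psm_table <- function(psms, path) {
  missing <- setdiff(.PSM_MANDATORY, names(psms))
  if (length(missing) > 0L) {
    stop("PSM table is missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  .write_versioned_tsv(psms, path, "psm")
}

# ---- FASTA --------------------------------------------------------------

#' Read a target-decoy FASTA database
#'
#' @param path FASTA file.
#' @param decoy_prefix Accession prefix marking decoy entries.
#' @return A data.frame with columns `accession`, `sequence`, `is_decoy`.
#'   The accession is the first whitespace-delimited token of the header.
#' @export
read_fasta <- function(path, decoy_prefix = "DECOY_") {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0L || !any(startsWith(txt, ">"))) {
    warning("empty FASTA file: ", path)
    return(data.frame(accession = character(), sequence = character(),
                      is_decoy = logical()))
  }
  aa <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(acc)) {
    stop("duplicate accession in FASTA: ", acc[duplicated(acc)][1])
  }
  data.frame(accession = acc, sequence = as.character(aa),
             is_decoy = startsWith(acc, decoy_prefix), row.names = NULL)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector (names are accessions) or a
#'   data.frame with `accession` and `sequence` columns.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    sequences <- stats::setNames(sequences$sequence, sequences$accession)
  }
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# ---- modification lists -------------------------------------------------

#' Read / write a modification (mass-shift) list
#'
#' A curated Unimod-style list: `name`, monoisotopic `delta_mass` (Da),
#' `allowed_residues` (comma-separated one-letter codes and/or the
#' terminus markers `N-term`/`C-term`; `*` means any residue),
#' `is_artifact` and `is_combination` flags.
#'
#' @param path File path.
#' @return A `data.table` with the columns above; `allowed_residues` is a
#'   list column of character vectors.
#' @export
read_modifications <- function(path) {
  dt <- .read_versioned_tsv(path, "modlist")
  need <- c("name", "delta_mass", "allowed_residues", "is_artifact", "is_combination")
  missing <- setdiff(need, names(dt))
  if (length(missing) > 0L) {
    stop("modification list is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  .convert_col(dt, "delta_mass", as.numeric, "numeric", path)
  .convert_col(dt, "is_artifact", .as_logical_strict, "logical", path)
  .convert_col(dt, "is_combination", .as_logical_strict, "logical", path)
  dt[, allowed_residues := strsplit(allowed_residues, ",", fixed = TRUE)]
  dt[]
}

#' @param mods Modification table as returned by [read_modifications()].
#' @rdname read_modifications
#' @export
write_modifications <- function(mods, path) {
  dt <- data.table::as.data.table(mods)
  if (is.list(dt$allowed_residues)) {
    dt[, allowed_residues := vapply(allowed_residues, paste, character(1), collapse = ",")]
  }
  .write_versioned_tsv(dt, path, "modlist")
}

#' Default modification list shipped with the package
#'
#' Oxidation mono/di/tri, the two alkylation tags (carbamidomethyl,
#' methylthio - flagged as preparation artifacts so they are excluded from
#' the curated PTM list and handled by the redox module), acetylation,
#' deamidation, isotope-error artifacts and one known modification
#' combination.
#'
#' @return A `data.table`, see [read_modifications()].
#' @export
default_modifications <- function() {
  read_modifications(system.file("extdata", "modifications.tsv", package = "oxwave"))
}

# ---- category annotations ----------------------------------------------

#' Read a protein-to-category annotation table
#'
#' Auto-detects two dialects: two-column TSV (`category`, `accession`; a
#' header row is recognized and skipped) or GMT
#' (`category<TAB>description<TAB>member1<TAB>member2...`).
#'
#' @param path File path.
#' @return Named list mapping category name to a character vector of
#'   accessions. A protein may appear in several categories.
#' @export
read_categories <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("empty category file: ", path)
    return(list())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf > 2L)) {
    # GMT: name, description, members...
    out <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(out) <- vapply(fields, `[`, character(1), 1L)
  } else {
    if (any(nf < 2L)) stop("malformed category line: ", lines[which(nf < 2L)[1]])
    first <- fields[[1]]
    if (tolower(first[1]) %in% c("category", "term") ) fields <- fields[-1]
    cat_names <- vapply(fields, `[`, character(1), 1L)
    acc <- vapply(fields, `[`, character(1), 2L)
    out <- lapply(split(acc, cat_names), unique)
  }
  # merge duplicate category lines (GMT dialect)
  if (anyDuplicated(names(out))) {
    out <- lapply(split(out, names(out)), function(x) unique(unlist(x)))
  }
  out
}

#' Write categories as a two-column TSV
#'
#' @param categories Named list of accession vectors.
#' @param path Output file.
#' @export
write_categories <- function(categories, path) {
  dt <- data.table::data.table(
    category = rep(names(categories), lengths(categories)),
    accession = unlist(categories, use.names = FALSE)
  )
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---- design tables ------------------------------------------------------

#' Read / write an experiment design table
#'
#' Maps isobaric channels to samples: columns `plex_id`, `channel_index`,
#' `sample_id`, `group_label`, `timepoint_label`, `is_reference`. Each
#' plex must contain exactly one reference channel; every non-reference
#' sample belongs to one group. Row order defines the time ordering used
#' by time-course functions.
#'
#' @param path File path.
#' @return A `data.table` design table.
#' @export
read_design <- function(path) {
  dt <- .read_versioned_tsv(path, "design")
  need <- c("plex_id", "channel_index", "sample_id", "group_label",
            "timepoint_label", "is_reference")
  missing <- setdiff(need, names(dt))
  if (length(missing) > 0L) {
    stop("design table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  .convert_col(dt, "channel_index", as.integer, "integer", path)
  .convert_col(dt, "is_reference", .as_logical_strict, "logical", path)
  validate_design(dt)
  dt[]
}

#' @param design Design table.
#' @rdname read_design
#' @export
write_design <- function(design, path) {
  validate_design(design)
  .write_versioned_tsv(design, path, "design")
}

#' Validate a design table's invariants
#'
#' @param design Design table (see [read_design()]).
#' @return The design, invisibly; errors on violation.
#' @export
validate_design <- function(design) {
  refs <- tapply(design$is_reference, design$plex_id, sum)
  if (any(refs != 1L)) {
    stop("each plex must have exactly one reference channel; offending plex: ",
         names(refs)[which(refs != 1L)[1]])
  }
  nonref <- design[!design$is_reference, ]
  if (any(is.na(nonref$group_label) | !nzchar(nonref$group_label))) {
    stop("every non-reference sample must map to one group")
  }
  if (anyDuplicated(design$sample_id[!design$is_reference])) {
    stop("duplicate sample_id among non-reference channels")
  }
  invisible(design)
}
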