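# Coordinated protein-abundance changes per functional category: the
# standardized category value Zc = sum(Zq) / sqrt(n) is N(0, 1) when the
# member Zq are independent standard normal, so categories behave like the
# protein level one tier up.

#' Standardized functional-category changes (Zc)
#'
#' For each sample and each category with a quantified membership between
#' `min_size` and `max_size`, computes `Zc = sum(Zq_members) / sqrt(n)` and
#' a two-sided normal p-value. Categories with no quantified proteins are
#' skipped.
#'
#' @param protein_zq Long table with columns `protein`, `sample_id`, `Zq`
#'   (the `proteins` element of [run_wspp()] works directly).
#' @param categories Named list mapping category name to protein
#'   accessions (see [read_categories()]).
#' @param min_size,max_size Bounds on the number of quantified member
#'   proteins.
#' @return `data.table`: `category`, `sample_id`, `n_proteins`, `Zc`, `p`.
#' @export
compute_category_z <- function(protein_zq, categories, min_size = 5L,
                               max_size = 500L) {
  zq <- data.table::as.data.table(protein_zq)
  stopifnot(all(c("protein", "sample_id", "Zq") %in% names(zq)))
  member <- data.table::data.table(
    category = rep(names(categories), lengths(categories)),
    protein = unlist(categories, use.names = FALSE)
  )
  dt <- merge(zq[, .(protein, sample_id, Zq)], member, by = "protein",
              allow.cartesian = TRUE)
  if (nrow(dt) == 0L) {
    message("no category has quantified proteins")
    return(data.table::data.table(category = character(), sample_id = character(),
                                  n_proteins = integer(), Zc = numeric(),
                                  p = numeric()))
  }
  res <- dt[, .(n_proteins = .N, Zc = sum(Zq) / sqrt(.N)),
            by = .(category, sample_id)]
  res <- res[n_proteins >= min_size & n_proteins <= max_size]
  res[, p := 2 * stats::pnorm(abs(Zc), lower.tail = FALSE)]
  data.table::setorder(res, sample_id, category)
  res[]
}

#' Benjamini-Hochberg control of category results
#'
#' Adds BH step-up q-values (adjusted across categories within each sample,
#' i.e. per time point) and a significance flag at `alpha`.
#'
#' @param results Output of [compute_category_z()].
#' @param alpha Significance threshold on q (default 0.05).
#' @return The results with `q` and `significant` columns.
#' @export
category_fdr <- function(results, alpha = 0.05) {
  res <- data.table::copy(data.table::as.data.table(results))
  if (any(res$p < 0 | res$p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  res[, q := stats::p.adjust(p, method = "BH"), by = sample_id]
  res[, significant := q < alpha]
  res[]
}
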