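#' Threshold criteria for calling an analysis above threshold
#'
#' The three-criterion gate of the screen, combined by Boolean AND: an
#' analysis (one gene in one study) is above threshold when it
#' simultaneously has `p_value < p_max`, `|fold_change| >= fold_min` and
#' `percentile <= percentile_max`. Defaults are the classic Oncomine search
#' settings: p < 0.05, 2-fold change, top 10% gene rank.
#'
#' Boundary conventions: the p cut-off is strict, the fold cut-off is
#' inclusive (a fold change of exactly 2 passes), and the percentile cut-off
#' is inclusive after the ceiling rounding of [rank_and_percentile()] (a
#' printed percentile of 10 passes).
#'
#' @param p_max Maximum p-value, exclusive. In (0, 1).
#' @param fold_min Minimum absolute linear fold change, inclusive. `>= 1`.
#' @param percentile_max Maximum gene rank percentile, inclusive. In
#'   1..100.
#' @return An object of class `threshold_criteria`.
#' @examples
#' threshold_criteria()
#' threshold_criteria(p_max = 0.01, fold_min = 1.5, percentile_max = 5)
#' @export
threshold_criteria <- function(p_max = 0.05, fold_min = 2,
                               percentile_max = 10) {
  if (!(is.numeric(p_max) && length(p_max) == 1 && p_max > 0 && p_max < 1)) {
    abort("`p_max` must be a single value in (0, 1).")
  }
  if (!(is.numeric(fold_min) && length(fold_min) == 1 && fold_min >= 1)) {
    abort("`fold_min` must be a single value >= 1.")
  }
  if (!(is.numeric(percentile_max) && length(percentile_max) == 1 &&
        percentile_max >= 1 && percentile_max <= 100)) {
    abort("`percentile_max` must be a single value in [1, 100].")
  }
  structure(
    list(p_max = p_max, fold_min = fold_min,
         percentile_max = as.integer(percentile_max)),
    class = "threshold_criteria"
  )
}

#' @export
print.threshold_criteria <- function(x, ...) {
  cat(sprintf(
    "<threshold_criteria> p < %g AND |fold change| >= %g AND percentile <= %d\n",
    x$p_max, x$fold_min, x$percentile_max))
  invisible(x)
}

#' Test per-gene results against the threshold gate
#'
#' Vectorised predicate: for each row of a per-gene results table, is the
#' analysis above threshold under `criteria`? All three criteria must hold
#' (Boolean AND).
#'
#' @param results A data frame with columns `p_value`, `fold_change` and
#'   `percentile` (e.g. from [analyze_study()]).
#' @param criteria A [threshold_criteria()].
#' @return Logical vector, one entry per row; `NA` fold changes never pass.
#' @examples
#' res <- tibble::tibble(p_value = c(5.89e-4, 0.04), fold_change = c(3.178, 1.9),
#'                       percentile = c(6L, 5L))
#' passes_threshold(res)
#' @export
passes_threshold <- function(results, criteria = threshold_criteria()) {
  stopifnot(inherits(criteria, "threshold_criteria"))
  need <- c("p_value", "fold_change", "percentile")
  miss <- setdiff(need, colnames(results))
  if (length(miss) > 0) {
    abort(sprintf("`results` lacks column(s): %s.", paste(miss, collapse = ", ")))
  }
  ok <- results$p_value < criteria$p_max &
    abs(results$fold_change) >= criteria$fold_min &
    results$percentile <= criteria$percentile_max
  ok & !is.na(ok)
}

#' Extract above-threshold analysis records
#'
#' Filters per-gene per-study results down to the analyses passing the
#' threshold gate, optionally restricted to a gene whitelist (e.g.
#' [kcnk_genes] when screening the K2P family). Each record corresponds to
#' one above-threshold (gene, study) comparison, carrying the columns of the
#' screen's report tables.
#'
#' @param results Per-gene per-study results tibble, as produced by
#'   [analyze_study()] or [analyze_studies()]; must also carry `gene_id`,
#'   `study_id`, `cancer_type`, `cancer_subtype`, `direction`.
#' @param criteria A [threshold_criteria()].
#' @param genes Optional character vector restricting the records to these
#'   gene identifiers.
#' @return A tibble of records with columns `gene_id`, `cancer_type`,
#'   `cancer_subtype`, `study_id`, `direction`, `p_value`, `fold_change`,
#'   `percentile`, sorted by (gene, cancer type, subtype, ascending p).
#' @export
filter_above_threshold <- function(results, criteria = threshold_criteria(),
                                   genes = NULL) {
  keep <- passes_threshold(results, criteria)
  rec <- results[keep, , drop = FALSE]
  if (!is.null(genes)) {
    rec <- rec[rec$gene_id %in% genes, , drop = FALSE]
  }
  rec <- select(rec, "gene_id", "cancer_type", "cancer_subtype", "study_id",
                "direction", "p_value", "fold_change", "percentile")
  attr(rec, "n_unmeasured") <- NULL
  arrange(as_tibble(rec), .data$gene_id, .data$cancer_type,
          .data$cancer_subtype, .data$p_value)
}
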