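#' Cross-study comparative meta-analysis by median p-value and median rank
#'
#' Summarises each (gene, cancer subtype) pair across all datasets in which
#' the gene was measured — not only those above threshold — by the median
#' two-sided p-value and the median gene rank. A pair is eligible for
#' meta-analysis when at least `min_datasets` datasets measured the gene
#' (the n >= 5 rule); an eligible pair is called significant when its median
#' p-value is at most 0.05: the expression trend is then likely altered in
#' that subtype.
#'
#' @param results Per-gene per-study results (from [analyze_studies()]),
#'   spanning all studies, ungated.
#' @param min_datasets Minimum number of datasets for eligibility
#'   (default 5).
#' @param alpha Significance level applied to the median p (default 0.05).
#' @return A tibble with one row per (gene, cancer type, subtype):
#'   `n_datasets`, `median_p`, `median_rank` (half-integers possible for
#'   even n), `eligible`, `significant` (`NA` when not eligible).
#' @details Medians over an even number of datasets are the mean of the two
#'   central order statistics. Median rank uses the raw integer ranks R, not
#'   percentiles, so its magnitude is comparable to the platform gene count.
#' @export
meta_summarize <- function(results, min_datasets = 5, alpha = 0.05) {
  need <- c("gene_id", "cancer_type", "cancer_subtype", "study_id",
            "p_value", "rank")
  miss <- setdiff(need, colnames(results))
  if (length(miss) > 0) {
    abort(sprintf("`results` lacks column(s): %s.", paste(miss, collapse = ", ")))
  }
  out <- results %>%
    group_by(.data$gene_id, .data$cancer_type, .data$cancer_subtype) %>%
    summarise(
      n_datasets = n_distinct(.data$study_id),
      median_p = median(.data$p_value),
      median_rank = median(.data$rank),
      .groups = "drop"
    ) %>%
    mutate(
      eligible = .data$n_datasets >= min_datasets,
      significant = ifelse(.data$eligible, .data$median_p <= alpha, NA)
    )
  arrange(out, .data$gene_id, .data$cancer_type, .data$cancer_subtype)
}

#' Aggregate above-threshold fold changes as mean and SEM
#'
#' For each (gene, cancer type, subtype, direction) group of above-threshold
#' records, the mean and standard error of the mean of the absolute linear
#' fold changes — the "mean +/- SEM fold" figures of the screen's report
#' tables. Direction is carried as a separate column, so a subtype with both
#' over- and under-expressed analyses yields two rows.
#'
#' @param records Above-threshold records from [filter_above_threshold()].
#' @return A tibble with columns `gene_id`, `cancer_type`, `cancer_subtype`,
#'   `direction`, `k` (number of above-threshold analyses), `mean_fold`,
#'   `sem_fold`. The SEM uses the k-1 sample standard deviation over
#'   `sqrt(k)` and is `NA` (undefined) when `k = 1`. Values are stored at
#'   full precision; round for display.
#' @examples
#' recs <- tibble::tibble(
#'   gene_id = "KCNK1", cancer_type = "Lung", cancer_subtype = "Adenocarcinoma",
#'   direction = "over", fold_change = c(3.984, 2.141, 4.641, 2.137))
#' aggregate_folds(recs)
#' @export
aggregate_folds <- function(records) {
  if (nrow(records) == 0) {
    abort("Cannot aggregate an empty record set.")
  }
  records %>%
    group_by(.data$gene_id, .data$cancer_type, .data$cancer_subtype,
             .data$direction) %>%
    summarise(
      k = n(),
      mean_fold = mean(abs(.data$fold_change)),
      sem_fold = ifelse(n() > 1,
                        sd(abs(.data$fold_change)) / sqrt(n()), NA_real_),
      .groups = "drop"
    ) %>%
    arrange(.data$gene_id, .data$cancer_type, .data$cancer_subtype,
            .data$direction)
}

#' Count above-threshold analyses
#'
#' Exact count of records matching optional gene, subtype, cancer-type and
#' direction filters.
#'
#' @param records Above-threshold records.
#' @param gene,cancer_type,cancer_subtype,direction Optional filters; `NULL`
#'   leaves the dimension unrestricted.
#' @return Integer count.
#' @export
count_above_threshold <- function(records, gene = NULL, cancer_type = NULL,
                                  cancer_subtype = NULL, direction = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(gene)) keep <- keep & records$gene_id %in% gene
  if (!is.null(cancer_type)) keep <- keep & records$cancer_type %in% cancer_type
  if (!is.null(cancer_subtype)) {
    keep <- keep & records$cancer_subtype %in% cancer_subtype
  }
  if (!is.null(direction)) keep <- keep & records$direction %in% direction
  sum(keep)
}

#' Over/under gene-by-cancer summary matrices
#'
#' Builds the gene summary view of the screen: for each direction
#' (over-expression, under-expression), a gene-by-cancer-type matrix whose
#' cell holds the best (lowest) gene rank percentile among that gene's
#' above-threshold analyses of that direction in that cancer, or `NA` when
#' none exists. For display, percentiles are binned into the classes
#' `1%` (percentile <= 1), `5%` (<= 5) and `10%` (<= 10), mirroring the
#' colour shading of a gene summary heatmap.
#'
#' @param records Above-threshold records gated at the standard criteria.
#' @param genes Ordered gene list for the rows (default: genes observed in
#'   `records`, sorted).
#' @param cancers Ordered cancer-type list for the columns (default:
#'   observed, sorted).
#' @return An object of class `gene_summary_matrix`: list with integer
#'   matrices `over` and `under` (best percentile or `NA`) and a long tibble
#'   `cells` (`gene_id`, `cancer_type`, `direction`, `best_percentile`,
#'   `bin`).
#' @seealso [autoplot.gene_summary_matrix()]
#' @export
build_summary_matrix <- function(records, genes = NULL, cancers = NULL) {
  if (is.null(genes)) genes <- sort(unique(records$gene_id))
  if (is.null(cancers)) cancers <- sort(unique(records$cancer_type))
  sub <- filter(records, .data$gene_id %in% genes,
                .data$cancer_type %in% cancers)
  cells <- if (nrow(sub) == 0) {
    tibble(gene_id = character(), cancer_type = character(),
           direction = character(), best_percentile = integer(),
           bin = bin_percentile(integer()))
  } else {
    sub %>%
      group_by(.data$gene_id, .data$cancer_type, .data$direction) %>%
      summarise(best_percentile = min(.data$percentile), .groups = "drop") %>%
      mutate(bin = bin_percentile(.data$best_percentile))
  }
  mk <- function(dir) {
    m <- matrix(NA_integer_, length(genes), length(cancers),
                dimnames = list(genes, cancers))
    sub <- cells[cells$direction == dir, , drop = FALSE]
    if (nrow(sub) > 0) {
      m[cbind(match(sub$gene_id, genes), match(sub$cancer_type, cancers))] <-
        as.integer(sub$best_percentile)
    }
    m
  }
  structure(
    list(over = mk("over"), under = mk("under"), cells = cells,
         genes = genes, cancers = cancers),
    class = "gene_summary_matrix"
  )
}

bin_percentile <- function(p) {
  factor(ifelse(p <= 1, "1%", ifelse(p <= 5, "5%", "10%")),
         levels = c("1%", "5%", "10%"))
}

#' @export
print.gene_summary_matrix <- function(x, ...) {
  cat(sprintf(
    "<gene_summary_matrix> %d genes x %d cancer types; %d over, %d under cells\n",
    length(x$genes), length(x$cancers),
    sum(!is.na(x$over)), sum(!is.na(x$under))))
  invisible(x)
}

#' Heatmap of a gene summary matrix
#'
#' Renders the over/under summary matrices as a two-panel tile plot, colour
#' depth encoding the best gene rank percentile class (1%, 5%, 10%) of the
#' highest-ranking above-threshold analysis, the standard gene summary view
#' for a family-wide cancer expression screen.
#'
#' @param object A [build_summary_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_summary_matrix
#' @export
autoplot.gene_summary_matrix <- function(object, ...) {
  cells <- object$cells %>%
    mutate(
      gene_id = factor(.data$gene_id, levels = rev(object$genes)),
      cancer_type = factor(.data$cancer_type, levels = object$cancers),
      direction = factor(.data$direction, levels = c("over", "under"),
                         labels = c("Over-expression", "Under-expression"))
    )
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data$cancer_type, y = .data$gene_id,
                               fill = .data$bin)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::facet_wrap(~direction) +
    ggplot2::scale_fill_manual(
      values = c("1%" = "#99000d", "5%" = "#ef3b2c", "10%" = "#fc9272"),
      name = "Best gene rank\npercentile", drop = FALSE) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::scale_y_discrete(drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
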