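# Row-wise pooled-variance Student's t on a genes x samples matrix.
# Returns per-gene t, df, p together with per-group counts and linear means.
# NAs are dropped per gene; a gene with < 2 finite values in either group is
# reported with measured = FALSE (it was not analysed on that platform).
row_t_stats <- function(values, is_cancer, log2_transform = TRUE,
                        var_equal = TRUE) {
  xc <- values[, is_cancer, drop = FALSE]
  xn <- values[, !is_cancer, drop = FALSE]
  mean_c_lin <- rowMeans(xc, na.rm = TRUE)
  mean_n_lin <- rowMeans(xn, na.rm = TRUE)
  if (log2_transform) {
    if (any(values <= 0, na.rm = TRUE)) {
      abort("log2 testing requires strictly positive intensities.")
    }
    xc <- log2(xc)
    xn <- log2(xn)
  }
  nc <- rowSums(!is.na(xc))
  nn <- rowSums(!is.na(xn))
  mc <- rowMeans(xc, na.rm = TRUE)
  mn <- rowMeans(xn, na.rm = TRUE)
  # sample variances via sum of squared deviations (NA-aware)
  ssc <- rowSums((xc - mc)^2, na.rm = TRUE)
  ssn <- rowSums((xn - mn)^2, na.rm = TRUE)
  measured <- nc >= 2 & nn >= 2
  if (var_equal) {
    df <- nc + nn - 2
    sp2 <- (ssc + ssn) / df
    se <- sqrt(sp2 * (1 / nc + 1 / nn))
  } else {
    vc <- ssc / (nc - 1)
    vn <- ssn / (nn - 1)
    se <- sqrt(vc / nc + vn / nn)
    df <- (vc / nc + vn / nn)^2 /
      ((vc / nc)^2 / (nc - 1) + (vn / nn)^2 / (nn - 1))
  }
  t_stat <- (mc - mn) / se
  # degenerate variance: identical groups are evidence of no difference
  zero_se <- measured & !is.na(se) & se == 0
  t_stat[zero_se & (mc == mn)] <- 0
  t_stat[zero_se & (mc != mn)] <- sign(mc - mn)[zero_se & (mc != mn)] * Inf
  p <- 2 * pt(-abs(t_stat), df)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  t_stat[!measured] <- NA_real_
  p[!measured] <- NA_real_
  tibble(
    gene_id = rownames(values),
    t_stat = unname(t_stat),
    df = unname(df),
    p_value = unname(p),
    n_cancer = unname(nc),
    n_normal = unname(nn),
    mean_cancer = unname(mean_c_lin),
    mean_normal = unname(mean_n_lin),
    measured = unname(measured)
  )
}

#' Two-sample Student's t-test for one gene
#'
#' Pooled-variance two-sided Student's t-test comparing cancer against normal
#' intensities for a single gene, the per-gene statistic underlying
#' [analyze_study()]. By default the test is applied to log2-transformed
#' intensities (the microarray convention, which stabilises variance), while
#' fold changes remain linear; set `log2_transform = FALSE` to test on the
#' values as given. Welch's unequal-variance form is available behind
#' `var_equal = FALSE`.
#'
#' @param cancer_values,normal_values Numeric vectors of linear intensities;
#'   `NA`s are removed.
#' @param log2_transform Test on log2 values (default `TRUE`).
#' @param var_equal Pooled variance (default `TRUE`); `FALSE` gives Welch.
#' @return A tibble with columns `t_stat`, `df`, `p_value`. Two identical
#'   constant groups give `t = 0`, `p = 1` (no evidence of change, not an
#'   error). A group with fewer than two finite values yields `NA`s: the gene
#'   is unmeasured for this comparison.
#' @examples
#' gene_t_test(c(4, 5, 6), c(1, 2, 3), log2_transform = FALSE)
#' @export
gene_t_test <- function(cancer_values, normal_values, log2_transform = TRUE,
                        var_equal = TRUE) {
  cancer_values <- cancer_values[is.finite(cancer_values)]
  normal_values <- normal_values[is.finite(normal_values)]
  m <- matrix(c(cancer_values, normal_values), nrow = 1,
              dimnames = list("gene", NULL))
  res <- row_t_stats(m, seq_len(ncol(m)) <= length(cancer_values),
                     log2_transform = log2_transform, var_equal = var_equal)
  res[, c("t_stat", "df", "p_value")]
}

#' Signed linear fold change
#'
#' The linear change in mean mRNA level in cancer relative to normal tissue:
#' the ratio `r = mean(cancer) / mean(normal)` of linear-scale intensities,
#' reported in the Oncomine signed convention — `r` when `r >= 1`
#' (over-expression) and `-1/r` when `r < 1` (under-expression, e.g. a ratio
#' of 1/9.574 is reported as -9.574). The magnitude is therefore always
#' `>= 1` and `fold_change(a, b) == -fold_change(b, a)`.
#'
#' @inheritParams gene_t_test
#' @return A single signed fold change, or `NA` (with a warning) when a group
#'   mean is not strictly positive, for which the linear ratio is undefined.
#' @examples
#' fold_change(c(22, 18), c(11, 9))   # +2
#' fold_change(c(11, 9), c(22, 18))   # -2
#' @export
fold_change <- function(cancer_values, normal_values) {
  mc <- mean(cancer_values, na.rm = TRUE)
  mn <- mean(normal_values, na.rm = TRUE)
  signed_fold(mc, mn)
}

signed_fold <- function(mean_cancer, mean_normal) {
  out <- rep(NA_real_, length(mean_cancer))
  ok <- is.finite(mean_cancer) & is.finite(mean_normal) &
    mean_cancer > 0 & mean_normal > 0
  if (any(!ok)) {
    warn("Fold change undefined for genes with a non-positive group mean.")
  }
  r <- mean_cancer[ok] / mean_normal[ok]
  out[ok] <- ifelse(r >= 1, r, -1 / r)
  out
}

#' Rank genes by p-value and convert to rank percentiles
#'
#' Ranks all measured genes of one study by their two-sided p-value (rank 1 =
#' smallest p, ties broken by gene identifier so results are deterministic)
#' and expresses each rank as an integer gene rank percentile
#' `ceiling(100 * R / N)`, where `N` is the number of genes analysed in the
#' study. The ceiling makes rank 1 of 14,000 print as percentile 1, and a
#' gene is "in the top 10%" exactly when its percentile is `<= 10`.
#'
#' @param p_values Numeric vector of two-sided p-values, one per measured
#'   gene.
#' @param gene_ids Optional character vector used for stable tie-breaking
#'   (defaults to the input order).
#' @return A tibble with columns `rank` (integer, 1..N) and `percentile`
#'   (integer, 1..100), in the input order.
#' @examples
#' rank_and_percentile(c(A = 0.001, B = 0.01, C = 0.0001))
#' @export
rank_and_percentile <- function(p_values, gene_ids = names(p_values)) {
  if (length(p_values) == 0) {
    abort("Cannot rank an empty p-value vector.")
  }
  if (anyNA(p_values)) {
    abort("Ranking requires a p-value for every measured gene.")
  }
  if (is.null(gene_ids)) gene_ids <- as.character(seq_along(p_values))
  n <- length(p_values)
  ord <- order(p_values, gene_ids)
  rk <- integer(n)
  rk[ord] <- seq_len(n)
  tibble(rank = rk, percentile = as.integer(ceiling(100 * rk / n)))
}

#' Rank-based false discovery Q-value
#'
#' The rank-based FDR correction `Q = N * P / R`, where `P` is a gene's
#' two-sided p-value, `N` the total number of genes analysed in the study and
#' `R` the gene's p-value rank. Since `N / R >= 1`, `Q >= P` always. The raw
#' formula is the default; `monotone = TRUE` additionally enforces step-up
#' monotonicity (running minimum from the largest rank downward) and caps at
#' 1, which makes Q coincide with the Benjamini-Hochberg adjusted p-value.
#'
#' @param p_value Numeric vector of p-values.
#' @param n_genes Total genes analysed, `N`.
#' @param rank Integer p-value ranks, `R` (same length as `p_value`).
#' @param monotone Apply the step-up monotone adjustment (default `FALSE`).
#' @return Numeric vector of Q-values.
#' @examples
#' fdr_q(1e-4, n_genes = 10000, rank = 5)  # 0.2
#' @export
fdr_q <- function(p_value, n_genes, rank, monotone = FALSE) {
  if (length(rank) != length(p_value)) {
    abort("`rank` and `p_value` must have the same length.")
  }
  if (any(rank < 1 | rank > n_genes)) {
    abort("Ranks must lie in [1, n_genes].")
  }
  q <- n_genes * p_value / rank
  if (monotone) {
    ord <- order(rank, decreasing = TRUE)
    q[ord] <- cummin(q[ord])
    q <- pmin(q, 1)
  }
  q
}

#' Differential-expression statistics for every gene of one study
#'
#' Runs the full per-study screen: a pooled-variance two-sided Student's
#' t-test on log2 intensities, signed linear fold change, p-value ranking
#' with integer rank percentiles, and the rank-based Q-value, for every
#' measured gene of an [expression_study()].
#'
#' Genes left with fewer than two finite values in either group are excluded
#' from the study's gene count `N` and from the output — they were not
#' analysed on this platform. Direction is `over` when the fold change is
#' positive (cancer mean at or above normal mean) and `under` otherwise.
#'
#' @param study An `expression_study`.
#' @param log2_transform,var_equal Passed to the t-test; see [gene_t_test()].
#' @param monotone_q Use the monotone (step-up) Q-value; default is the raw
#'   `NP/R` formula.
#' @return A tibble with one row per measured gene: `study_id`,
#'   `cancer_type`, `cancer_subtype`, `gene_id`, `t_stat`, `p_value`,
#'   `fold_change`, `direction`, `rank`, `n_genes`, `percentile`, `q_value`.
#'   Rows are ordered by rank. The number of unmeasured genes is attached as
#'   attribute `n_unmeasured`.
#' @export
analyze_study <- function(study, log2_transform = TRUE, var_equal = TRUE,
                          monotone_q = FALSE) {
  stopifnot(inherits(study, "expression_study"))
  if (nrow(study$values) == 0) {
    abort(sprintf("Study '%s' has no genes.", study$study_id))
  }
  is_cancer <- study$samples$group == "cancer"
  stats_tb <- row_t_stats(study$values, is_cancer,
                          log2_transform = log2_transform,
                          var_equal = var_equal)
  n_unmeasured <- sum(!stats_tb$measured)
  stats_tb <- stats_tb[stats_tb$measured, , drop = FALSE]
  if (nrow(stats_tb) == 0) {
    abort(sprintf("Study '%s' has no measurable genes.", study$study_id))
  }
  n <- nrow(stats_tb)
  rp <- rank_and_percentile(stats_tb$p_value, stats_tb$gene_id)
  fc <- signed_fold(stats_tb$mean_cancer, stats_tb$mean_normal)
  out <- tibble(
    study_id = study$study_id,
    cancer_type = study$cancer_type,
    cancer_subtype = study$cancer_subtype,
    gene_id = stats_tb$gene_id,
    t_stat = stats_tb$t_stat,
    p_value = stats_tb$p_value,
    fold_change = fc,
    direction = ifelse(is.na(fc), NA_character_,
                       ifelse(fc > 0, "over", "under")),
    rank = rp$rank,
    n_genes = n,
    percentile = rp$percentile,
    q_value = fdr_q(stats_tb$p_value, n, rp$rank, monotone = monotone_q)
  )
  out <- arrange(out, .data$rank)
  attr(out, "n_unmeasured") <- n_unmeasured
  out
}

#' Differential-expression statistics for a collection of studies
#'
#' Applies [analyze_study()] to each study and row-binds the per-gene
#' results, giving the long table consumed by [filter_above_threshold()] and
#' [meta_summarize()].
#'
#' @param studies List of `expression_study` objects.
#' @inheritParams analyze_study
#' @return A tibble of per-gene per-study results.
#' @export
analyze_studies <- function(studies, log2_transform = TRUE, var_equal = TRUE,
                            monotone_q = FALSE) {
  purrr::map_dfr(studies, analyze_study, log2_transform = log2_transform,
                 var_equal = var_equal, monotone_q = monotone_q)
}
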