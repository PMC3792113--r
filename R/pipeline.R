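#' Run the full expression screen
#'
#' Orchestrates the complete screen over a collection of studies: per-study
#' differential expression ([analyze_studies()]), threshold gating
#' ([filter_above_threshold()]), cross-study meta-analysis
#' ([meta_summarize()]), fold aggregation ([aggregate_folds()]) and the
#' over/under gene summary matrices ([build_summary_matrix()]), together
#' with a stage-by-stage run report. Identical inputs and settings produce
#' identical outputs.
#'
#' @param studies A manifest path, a [read_manifest()] result, a
#'   `study_collection` from [simulate_studies()], or a list of
#'   [expression_study()] objects.
#' @param criteria A [threshold_criteria()].
#' @param min_datasets Minimum datasets for meta-analysis eligibility
#'   (default 5).
#' @param genes Optional gene whitelist for gating (e.g. [kcnk_genes]).
#' @param out_dir Optional directory; when given, all result tables and the
#'   run report are written there as TSV/JSON.
#' @param monotone_q Use monotone step-up Q-values (default raw `NP/R`).
#' @param log2_transform,var_equal Per-gene test settings; see
#'   [gene_t_test()].
#' @return An object of class `onco_screen`: list with tibbles `results`,
#'   `records`, `meta`, `folds`, the `summary_matrix`, the `criteria`, and
#'   `report` (named list of stage counts and settings). An empty gated set
#'   is not an error; the report notes it.
#' @examples
#' sim <- simulate_studies(simulation_config(
#'   n_subtypes = 1, studies_per_subtype = 5, genes_per_platform = 200,
#'   samples_per_group = 5, seed = 7))
#' scr <- run_pipeline(sim)
#' scr
#' glance(scr)
#' @export
run_pipeline <- function(studies, criteria = threshold_criteria(),
                         min_datasets = 5, genes = NULL, out_dir = NULL,
                         monotone_q = FALSE, log2_transform = TRUE,
                         var_equal = TRUE) {
  study_list <- if (inherits(studies, "study_collection")) {
    studies$studies
  } else if (is.character(studies) ||
             (is.list(studies) && !is.null(studies$studies) &&
              is.data.frame(studies$studies))) {
    load_studies(studies)
  } else {
    studies
  }
  if (length(study_list) == 0) {
    abort("No studies to analyse.")
  }
  for (st in study_list) {
    if (!inherits(st, "expression_study")) {
      abort("`studies` must resolve to expression_study objects.")
    }
  }
  results <- analyze_studies(study_list, log2_transform = log2_transform,
                             var_equal = var_equal, monotone_q = monotone_q)
  records <- filter_above_threshold(results, criteria, genes = genes)
  meta <- meta_summarize(results, min_datasets = min_datasets)
  if (!is.null(genes)) meta <- meta[meta$gene_id %in% genes, , drop = FALSE]
  folds <- if (nrow(records) > 0) aggregate_folds(records) else
    tibble(gene_id = character(), cancer_type = character(),
           cancer_subtype = character(), direction = character(),
           k = integer(), mean_fold = double(), sem_fold = double())
  mat <- build_summary_matrix(records)
  report <- list(
    n_studies = length(study_list),
    n_results = nrow(results),
    n_records = nrow(records),
    n_meta_pairs = nrow(meta),
    n_meta_eligible = sum(meta$eligible),
    n_significant = sum(meta$significant, na.rm = TRUE),
    gated_set_empty = nrow(records) == 0,
    criteria = unclass(criteria),
    min_datasets = min_datasets,
    monotone_q = monotone_q,
    log2_transform = log2_transform,
    var_equal = var_equal,
    gene_whitelist = genes,
    package_version = as.character(utils::packageVersion("oncoscreen"))
  )
  scr <- structure(
    list(results = results, records = records, meta = meta, folds = folds,
         summary_matrix = mat, criteria = criteria, report = report),
    class = "onco_screen"
  )
  if (!is.null(out_dir)) write_screen(scr, out_dir)
  scr
}

#' Write all tables of a screen to a directory
#'
#' @param screen An `onco_screen`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `screen`.
#' @export
write_screen <- function(screen, dir) {
  stopifnot(inherits(screen, "onco_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(screen$results, file.path(dir, "results.tsv"))
  write_records_table(screen$records, file.path(dir, "records.tsv"))
  readr::write_tsv(screen$meta, file.path(dir, "meta_summary.tsv"),
                   na = "NA", progress = FALSE)
  readr::write_tsv(screen$folds, file.path(dir, "fold_aggregates.tsv"),
                   na = "NA", progress = FALSE)
  mat_tb <- function(m) as_tibble(m, rownames = "gene_id")
  readr::write_tsv(mat_tb(screen$summary_matrix$over),
                   file.path(dir, "summary_matrix_over.tsv"),
                   na = "", progress = FALSE)
  readr::write_tsv(mat_tb(screen$summary_matrix$under),
                   file.path(dir, "summary_matrix_under.tsv"),
                   na = "", progress = FALSE)
  jsonlite::write_json(screen$report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(screen)
}

#' @export
print.onco_screen <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("<onco_screen> %d studies -> %d gene-level results\n",
           "  above threshold: %d records; meta-analysis: %d/%d pairs ",
           "eligible, %d significant\n"),
    r$n_studies, r$n_results, r$n_records, r$n_meta_eligible,
    r$n_meta_pairs, r$n_significant))
  print(x$criteria)
  invisible(x)
}

#' Tidy an expression screen into its above-threshold records
#'
#' @param x An `onco_screen` from [run_pipeline()].
#' @param ... Unused.
#' @return The record tibble (one row per above-threshold analysis).
#' @method tidy onco_screen
#' @export
tidy.onco_screen <- function(x, ...) {
  x$records
}

#' One-row summary of an expression screen
#'
#' @param x An `onco_screen`.
#' @param ... Unused.
#' @return A one-row tibble of stage counts.
#' @method glance onco_screen
#' @export
glance.onco_screen <- function(x, ...) {
  r <- x$report
  tibble(
    n_studies = r$n_studies,
    n_results = r$n_results,
    n_records = r$n_records,
    n_meta_pairs = r$n_meta_pairs,
    n_meta_eligible = r$n_meta_eligible,
    n_significant = r$n_significant
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
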