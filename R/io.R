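record_cols <- c("gene_id", "cancer_type", "cancer_subtype", "study_id",
                 "direction", "p_value", "fold_change", "percentile")

#' Write and read above-threshold record tables
#'
#' Records are written as TSV with columns `gene_id`, `cancer_type`,
#' `cancer_subtype`, `study_id`, `direction`, `p_value`, `fold_change`,
#' `percentile`, rows sorted by (gene, cancer type, subtype, ascending p).
#' Numbers are written at full (shortest round-trip) precision, so
#' `read_records_table(write_records_table(x))` reproduces `x` exactly. An
#' empty record set writes a header-only file.
#'
#' @param records Record tibble (see [filter_above_threshold()]).
#' @param path Output TSV path.
#' @return `write_records_table()` invisibly returns the sorted records;
#'   `read_records_table()` returns the record tibble.
#' @export
write_records_table <- function(records, path) {
  miss <- setdiff(record_cols, colnames(records))
  if (length(miss) > 0) {
    abort(sprintf("`records` lacks column(s): %s.", paste(miss, collapse = ", ")))
  }
  out <- records[, record_cols] %>%
    as_tibble() %>%
    mutate(percentile = as.integer(.data$percentile)) %>%
    arrange(.data$gene_id, .data$cancer_type, .data$cancer_subtype,
            .data$p_value)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(out)
}

#' @rdname write_records_table
#' @export
read_records_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    cancer_type = readr::col_character(),
    cancer_subtype = readr::col_character(),
    study_id = readr::col_character(),
    direction = readr::col_character(),
    p_value = readr::col_double(),
    fold_change = readr::col_double(),
    percentile = readr::col_integer()
  ), na = c("", "NA"), progress = FALSE)
}

#' Write and read per-study differential-expression result tables
#'
#' Full-precision TSV serialisation of the per-gene per-study statistics
#' produced by [analyze_study()]; round-trips exactly.
#'
#' @param results Results tibble.
#' @param path TSV path.
#' @return The (re)read tibble; the writer returns its input invisibly.
#' @export
write_results_table <- function(results, path) {
  readr::write_tsv(results, path, na = "NA", progress = FALSE)
  invisible(results)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    study_id = readr::col_character(),
    cancer_type = readr::col_character(),
    cancer_subtype = readr::col_character(),
    gene_id = readr::col_character(),
    direction = readr::col_character(),
    rank = readr::col_integer(),
    n_genes = readr::col_integer(),
    percentile = readr::col_integer(),
    .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE)
}

#' Read a study manifest
#'
#' A manifest is a YAML file listing the studies of a collection and,
#' optionally, analysis options. Layout:
#'
#' ```yaml
#' studies:
#'   - study_id: S1
#'     matrix: s1_matrix.tsv
#'     annotation: s1_annotation.tsv
#'     cancer_type: Brain
#'     cancer_subtype: Glioblastoma
#'     scale_hint: linear      # optional
#' options:                    # optional; mirrors threshold_criteria etc.
#'   p_max: 0.05
#' ```
#'
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest YAML path.
#' @return A list with `studies` (tibble of entries, absolute paths) and
#'   `options` (named list, possibly empty).
#' @export
read_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$studies) || length(man$studies) == 0) {
    abort(sprintf("Manifest '%s' lists no studies.", path))
  }
  base <- dirname(normalizePath(path))
  entries <- purrr::map_dfr(man$studies, function(e) {
    for (f in c("study_id", "matrix", "annotation")) {
      if (is.null(e[[f]])) {
        abort(sprintf("Manifest entry missing field '%s'.", f))
      }
    }
    tibble(
      study_id = as.character(e$study_id),
      matrix = file.path(base, e$matrix),
      annotation = file.path(base, e$annotation),
      cancer_type = as.character(e$cancer_type %||% "Unspecified"),
      cancer_subtype = as.character(e$cancer_subtype %||% "Unspecified"),
      scale_hint = as.character(e$scale_hint %||% "linear")
    )
  })
  if (anyDuplicated(entries$study_id)) {
    abort("Manifest study_ids must be unique.")
  }
  missing <- entries$matrix[!file.exists(entries$matrix)]
  missing <- c(missing, entries$annotation[!file.exists(entries$annotation)])
  if (length(missing) > 0) {
    abort(sprintf("Manifest references missing file(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  list(studies = entries, options = man$options %||% list())
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Load all studies referenced by a manifest
#'
#' @param manifest Result of [read_manifest()] or a manifest path.
#' @return Named list of [expression_study()] objects.
#' @export
load_studies <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  entries <- manifest$studies
  studies <- purrr::pmap(entries, function(study_id, matrix, annotation,
                                           cancer_type, cancer_subtype,
                                           scale_hint) {
    tryCatch(
      read_expression_study(matrix, annotation, study_id = study_id,
                            cancer_type = cancer_type,
                            cancer_subtype = cancer_subtype,
                            scale_hint = scale_hint),
      error = function(e) {
        abort(sprintf("Study '%s' failed validation: %s",
                      study_id, conditionMessage(e)))
      }
    )
  })
  setNames(studies, entries$study_id)
}

#' Write a simulated collection to disk
#'
#' Materialises a [simulate_studies()] collection as a directory of
#' per-study matrix and annotation TSVs, a `manifest.yaml`, and the planted
#' `truth.tsv` — a complete, reloadable input set for [run_pipeline()].
#' Output is deterministic: the same collection writes byte-identical files.
#'
#' @param collection A `study_collection`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "study_collection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- purrr::map(collection$studies, function(st) {
    mfile <- sprintf("%s_matrix.tsv", st$study_id)
    afile <- sprintf("%s_annotation.tsv", st$study_id)
    write_expression_study(st, file.path(dir, mfile), file.path(dir, afile))
    list(study_id = st$study_id, matrix = mfile, annotation = afile,
         cancer_type = st$cancer_type, cancer_subtype = st$cancer_subtype)
  })
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(studies = unname(entries)), manifest_path)
  readr::write_tsv(collection$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  invisible(manifest_path)
}

#' Curated KCNK above-threshold records from the Oncomine screen
#'
#' The above-threshold cancer-vs-normal analyses for the K2P channel gene
#' family (KCNK1-KCNK18), as compiled from the historical Oncomine microarray
#' compendium at the standard criteria (p < 0.05, |fold change| >= 2, gene
#' rank percentile <= 10): per analysis the gene, cancer type and subtype,
#' direction, two-sided p-value, signed linear fold change and gene rank
#' percentile. Useful as a real worked example for the aggregation and
#' summary stages; shipped in `inst/extdata/kcnk_oncomine_records.tsv`.
#'
#' @return A record tibble in [write_records_table()] column layout.
#' @examples
#' recs <- kcnk_records()
#' count_above_threshold(recs, gene = "KCNK1", cancer_subtype = "Glioblastoma",
#'                       direction = "under")
#' @export
kcnk_records <- function() {
  path <- system.file("extdata", "kcnk_oncomine_records.tsv",
                      package = "oncoscreen", mustWork = TRUE)
  read_records_table(path)
}
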