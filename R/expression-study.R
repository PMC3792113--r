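#' Construct a cancer-vs-normal expression study
#'
#' An expression study bundles one microarray (or pre-processed RNA-seq)
#' experiment: a genes-by-samples matrix of linear-scale intensities together
#' with a two-group sample annotation (`cancer` vs `normal`) and cancer
#' type/subtype metadata. All downstream statistics (`analyze_study()`) are
#' computed per study.
#'
#' Intensities are stored on the linear scale. Inputs declared
#' `scale_hint = "log2"` are exponentiated on construction so that fold
#' changes are always ratios of linear means.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene
#'   identifiers), samples in columns (colnames are sample identifiers).
#'   Missing entries may be `NA`.
#' @param groups Character vector of `"cancer"`/`"normal"` labels, one per
#'   column of `values`; may be named by sample id.
#' @param study_id Short study identifier.
#' @param cancer_type Tissue-of-origin grouping (e.g. `"Brain"`).
#' @param cancer_subtype Specific disease (e.g. `"Glioblastoma"`).
#' @param scale_hint Scale of the supplied `values`: `"linear"` (default) or
#'   `"log2"`.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `values` (linear matrix), `samples` (tibble of `sample_id`, `group`),
#'   `study_id`, `cancer_type`, `cancer_subtype`.
#'
#' @details Validation enforces the preconditions of the two-sample t-test
#'   and of fold-change estimation: at least two samples per group, unique
#'   gene identifiers, no gene with all values missing, and finite values
#'   where present. Gene identifiers are opaque case-sensitive strings; no
#'   mapping between identifier schemes is attempted.
#'
#' @examples
#' m <- matrix(2^rnorm(12, 8), 3, 4,
#'             dimnames = list(c("KCNK1", "KCNK2", "KCNK3"),
#'                             c("s1", "s2", "s3", "s4")))
#' st <- expression_study(m, c("cancer", "cancer", "normal", "normal"),
#'                        study_id = "toy", cancer_type = "Brain",
#'                        cancer_subtype = "Glioblastoma")
#' st
#' @export
expression_study <- function(values, groups, study_id,
                             cancer_type = "Unspecified",
                             cancer_subtype = "Unspecified",
                             scale_hint = c("linear", "log2")) {
  scale_hint <- match.arg(scale_hint)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values))) {
    abort("`values` must carry gene identifiers as rownames.")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  }
  if (length(groups) != ncol(values)) {
    abort(sprintf("`groups` has length %d but the matrix has %d samples.",
                  length(groups), ncol(values)))
  }
  groups <- as.character(unname(groups))
  bad <- setdiff(unique(groups), c("cancer", "normal"))
  if (length(bad) > 0) {
    abort(sprintf("Group labels must be 'cancer' or 'normal'; found: %s.",
                  paste(bad, collapse = ", ")))
  }
  tab <- table(factor(groups, levels = c("cancer", "normal")))
  if (any(tab < 2)) {
    abort(sprintf(
      "Each group needs >= 2 samples for a t-test; got %d cancer, %d normal.",
      tab[["cancer"]], tab[["normal"]]))
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate gene identifiers: %s.",
                  paste(unique(dup), collapse = ", ")))
  }
  if (any(is.infinite(values))) {
    abort("Expression values must be finite where present.")
  }
  all_na <- rowSums(!is.na(values)) == 0
  if (any(all_na)) {
    abort(sprintf("Genes with no measured value: %s.",
                  paste(head(rownames(values)[all_na], 5), collapse = ", ")))
  }
  if (scale_hint == "log2") {
    values <- 2^values
  }
  structure(
    list(
      values = values,
      samples = tibble(sample_id = colnames(values), group = groups),
      study_id = as.character(study_id),
      cancer_type = as.character(cancer_type),
      cancer_subtype = as.character(cancer_subtype)
    ),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  tab <- table(x$samples$group)
  cat(sprintf(
    "<expression_study> %s (%s / %s)\n  %d genes x %d samples (%d cancer, %d normal)\n",
    x$study_id, x$cancer_type, x$cancer_subtype,
    nrow(x$values), ncol(x$values),
    tab[["cancer"]], tab[["normal"]]))
  invisible(x)
}

#' Read an expression study from delimited text
#'
#' Reads a tab-separated genes-by-samples matrix (first column gene
#' identifiers, header row sample identifiers) plus a two-column sample
#' annotation (`sample_id`, `group`) and returns a validated
#' [expression_study()]. Empty fields and `NA` are treated as missing;
#' scientific notation (`1.72E-24`) is accepted; parsing is
#' locale-independent (decimal point only).
#'
#' @param matrix_path Path to the TSV expression matrix.
#' @param annotation_path Path to the TSV sample annotation mapping every
#'   sample to `cancer` or `normal`.
#' @inheritParams expression_study
#' @return An `expression_study`.
#' @details Samples present in the matrix but absent from the annotation are
#'   an error, as are duplicated gene rows, non-numeric cells (reported with
#'   row and column), or a group with fewer than two samples.
#' @seealso [write_expression_study()]
#' @export
read_expression_study <- function(matrix_path, annotation_path,
                                  study_id = basename(matrix_path),
                                  cancer_type = "Unspecified",
                                  cancer_subtype = "Unspecified",
                                  scale_hint = c("linear", "log2")) {
  scale_hint <- match.arg(scale_hint)
  raw <- readr::read_tsv(matrix_path, col_types = readr::cols(
    .default = readr::col_character()), na = c("", "NA"),
    progress = FALSE)
  if (ncol(raw) < 2) {
    abort(sprintf("Malformed matrix header in '%s': need a gene column plus >= 1 sample column.",
                  matrix_path))
  }
  gene_ids <- as.character(raw[[1]])
  sample_ids <- colnames(raw)[-1]
  num <- matrix(NA_real_, nrow(raw), length(sample_ids),
                dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1]]
    parsed <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(parsed))
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-numeric cell '%s' at gene '%s', sample '%s' in '%s'.",
        col[bad[1]], gene_ids[bad[1]], sample_ids[j], matrix_path))
    }
    num[, j] <- parsed
  }
  ann <- readr::read_tsv(annotation_path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(ann))) {
    abort(sprintf("Annotation '%s' must have columns sample_id and group.",
                  annotation_path))
  }
  missing_ann <- setdiff(sample_ids, ann$sample_id)
  if (length(missing_ann) > 0) {
    abort(sprintf("Samples in matrix but not annotated: %s.",
                  paste(missing_ann, collapse = ", ")))
  }
  groups <- ann$group[match(sample_ids, ann$sample_id)]
  expression_study(num, groups, study_id = study_id,
                   cancer_type = cancer_type,
                   cancer_subtype = cancer_subtype,
                   scale_hint = scale_hint)
}

#' Write an expression study to delimited text
#'
#' Inverse of [read_expression_study()]: writes the linear-scale matrix with
#' a `gene_id` first column and the two-column sample annotation. Missing
#' values are written as `NA`. `read(write(x))` reproduces `x`
#' field-for-field.
#'
#' @param study An `expression_study`.
#' @param matrix_path,annotation_path Output TSV paths.
#' @return Invisibly, `study`.
#' @export
write_expression_study <- function(study, matrix_path, annotation_path) {
  stopifnot(inherits(study, "expression_study"))
  tb <- as_tibble(study$values, rownames = "gene_id")
  readr::write_tsv(tb, matrix_path, na = "NA", progress = FALSE)
  readr::write_tsv(study$samples, annotation_path, na = "NA", progress = FALSE)
  invisible(study)
}
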