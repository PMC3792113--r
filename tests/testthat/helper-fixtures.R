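# Small in-code fixtures shared across the suite.

# A deterministic toy study: `shift_genes` get a log2 shift of `shift` in the
# cancer group on top of unit-ish noise.
make_toy_study <- function(n_genes = 10, n_per_group = 4, shift_genes = NULL,
                           shift = 0, seed = 101, study_id = "toy",
                           cancer_type = "Simulated",
                           cancer_subtype = "SubtypeA") {
  withr::with_seed(seed, {
    genes <- sprintf("G%03d", seq_len(n_genes))
    log2_vals <- matrix(rnorm(n_genes * 2 * n_per_group, mean = 8, sd = 0.4),
                        n_genes, 2 * n_per_group)
    if (!is.null(shift_genes)) {
      log2_vals[shift_genes, seq_len(n_per_group)] <-
        log2_vals[shift_genes, seq_len(n_per_group)] + shift
    }
    vals <- 2^log2_vals
    dimnames(vals) <- list(genes, c(sprintf("C%02d", seq_len(n_per_group)),
                                    sprintf("N%02d", seq_len(n_per_group))))
    expression_study(vals, rep(c("cancer", "normal"), each = n_per_group),
                     study_id = study_id, cancer_type = cancer_type,
                     cancer_subtype = cancer_subtype)
  })
}

# Minimal per-gene result rows for gate tests (rank/N/q filled consistently).
make_result_rows <- function(p, fc, pct, gene = sprintf("G%02d", seq_along(p)),
                             study = "S1", subtype = "SubtypeA",
                             type = "Simulated") {
  tibble::tibble(
    study_id = study, cancer_type = type, cancer_subtype = subtype,
    gene_id = gene, t_stat = NA_real_, p_value = p, fold_change = fc,
    direction = ifelse(fc > 0, "over", "under"),
    rank = rank(p, ties.method = "first"), n_genes = length(p),
    percentile = as.integer(pct),
    q_value = length(p) * p / rank(p, ties.method = "first")
  )
}
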