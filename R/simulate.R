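#' Configuration for the multi-study microarray simulator
#'
#' Describes a synthetic corpus of cancer-vs-normal microarray studies used
#' to exercise the screen end to end: several cancer subtypes, each measured
#' by several independent studies on platforms of roughly fourteen thousand
#' genes, with a small fraction of genes planted as truly over- or
#' under-expressed at a two-fold-or-greater linear effect.
#'
#' Intensities follow a log-normal model: on the log2 scale each value is
#' `mu_g + delta_g * [cancer] + eps`, with gene baselines `mu_g` uniform on
#' `baseline_log2_mean_range`, planted effects `delta_g` of magnitude
#' `planted_log2_effect` (so the true linear fold change is
#' `2^planted_log2_effect`, about 2.83 at the default 1.5) and Gaussian noise
#' `eps`. Planted genes share their direction across all studies of a
#' subtype; `effect_jitter_sd` adds optional per-study heterogeneity to the
#' planted effect (default 0: homogeneous effects). Each study independently
#' drops genes with probability `platform_dropout`, emulating per-platform
#' gene panel differences.
#'
#' @param n_subtypes Number of cancer subtypes.
#' @param studies_per_subtype Independent studies per subtype (default 7, so
#'   the n >= 5 meta-analysis rule is exercisable).
#' @param genes_per_platform Genes per platform (default 14000).
#' @param samples_per_group Samples in each of the cancer and normal groups
#'   (default 10).
#' @param baseline_log2_mean_range Range of per-gene baseline log2 means
#'   (default `c(4, 12)`).
#' @param within_group_log2_sd Within-group noise SD on the log2 scale
#'   (default 0.5).
#' @param planted_fraction Fraction of genes differentially expressed per
#'   subtype (default 0.01).
#' @param planted_log2_effect Magnitude of the planted log2 effect
#'   (default 1.5).
#' @param effect_sign_mix Probability a planted gene is over- rather than
#'   under-expressed (default 0.5).
#' @param effect_jitter_sd Per-study SD of the planted effect around its
#'   subtype value (default 0).
#' @param platform_dropout Per-study probability that a gene is absent from
#'   the platform (default 0.05).
#' @param seed Integer seed; identical seeds give bit-identical collections.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subtypes = 3,
                              studies_per_subtype = 7,
                              genes_per_platform = 14000,
                              samples_per_group = 10,
                              baseline_log2_mean_range = c(4, 12),
                              within_group_log2_sd = 0.5,
                              planted_fraction = 0.01,
                              planted_log2_effect = 1.5,
                              effect_sign_mix = 0.5,
                              effect_jitter_sd = 0,
                              platform_dropout = 0.05,
                              seed = 1L) {
  cfg <- list(
    n_subtypes = as.integer(n_subtypes),
    studies_per_subtype = as.integer(studies_per_subtype),
    genes_per_platform = as.integer(genes_per_platform),
    samples_per_group = as.integer(samples_per_group),
    baseline_log2_mean_range = as.numeric(baseline_log2_mean_range),
    within_group_log2_sd = as.numeric(within_group_log2_sd),
    planted_fraction = as.numeric(planted_fraction),
    planted_log2_effect = as.numeric(planted_log2_effect),
    effect_sign_mix = as.numeric(effect_sign_mix),
    effect_jitter_sd = as.numeric(effect_jitter_sd),
    platform_dropout = as.numeric(platform_dropout),
    seed = as.integer(seed)
  )
  counts <- c("n_subtypes", "studies_per_subtype", "genes_per_platform",
              "samples_per_group")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1) {
      abort(sprintf("`%s` must be a count >= 1.", f))
    }
  }
  if (cfg$samples_per_group < 2) {
    abort("`samples_per_group` must be >= 2 for a t-test.")
  }
  for (f in c("planted_fraction", "effect_sign_mix", "platform_dropout")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(sprintf("`%s` must lie in [0, 1].", f))
    }
  }
  if (cfg$within_group_log2_sd <= 0) {
    abort("`within_group_log2_sd` must be > 0.")
  }
  if (cfg$effect_jitter_sd < 0) {
    abort("`effect_jitter_sd` must be >= 0.")
  }
  if (length(cfg$baseline_log2_mean_range) != 2 ||
      diff(cfg$baseline_log2_mean_range) < 0) {
    abort("`baseline_log2_mean_range` must be an increasing interval.")
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    paste0("<simulation_config> %d subtypes x %d studies; %d genes, ",
           "%d+%d samples\n  planted %.1f%% at |log2 effect| %.2f ",
           "(fold %.2f), dropout %.2f, seed %d\n"),
    x$n_subtypes, x$studies_per_subtype, x$genes_per_platform,
    x$samples_per_group, x$samples_per_group,
    100 * x$planted_fraction, x$planted_log2_effect,
    2^x$planted_log2_effect, x$platform_dropout, x$seed))
  invisible(x)
}

# Deterministic per-purpose substreams: each study (and the truth draw) gets
# its own seed derived from (collection seed, counter), so generation does
# not depend on the order in which studies are realised.
substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) + 1000003 * as.double(counter)) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a collection of cancer-vs-normal expression studies
#'
#' Generates the synthetic corpus described by a [simulation_config()]:
#' for each subtype, `studies_per_subtype` independent studies whose linear
#' intensities follow the log-normal model `2^(mu_g + delta_g * [cancer] +
#' eps)`, plus the planted ground truth against which gate performance can be
#' scored with [truth_recovery_report()].
#'
#' @param config A [simulation_config()].
#' @return A list of class `study_collection` with elements `studies` (list
#'   of [expression_study()] objects, study ids `T<subtype>S<study>`) and
#'   `truth` (tibble: `cancer_subtype`, `gene_id`, `direction` in
#'   over/under/null, `true_fold` — linear, 1 for null genes).
#' @examples
#' sim <- simulate_studies(simulation_config(
#'   n_subtypes = 1, studies_per_subtype = 2, genes_per_platform = 50,
#'   samples_per_group = 4, seed = 42))
#' sim$studies[[1]]
#' @export
simulate_studies <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$genes_per_platform
  genes <- sprintf("G%05d", seq_len(g))
  subtypes <- sprintf("Subtype%02d", seq_len(config$n_subtypes))

  # planted truth: one draw per subtype, from its own substream
  truth <- purrr::map_dfr(seq_along(subtypes), function(si) {
    with_seed(substream_seed(config$seed, si), {
      direction <- rep("null", g)
      n_planted <- round(config$planted_fraction * g)
      if (n_planted > 0) {
        planted <- sample.int(g, n_planted)
        over <- runif(n_planted) < config$effect_sign_mix
        direction[planted] <- ifelse(over, "over", "under")
      }
      tibble(
        cancer_subtype = subtypes[si],
        gene_id = genes,
        direction = direction,
        true_fold = ifelse(direction == "null", 1,
                           ifelse(direction == "over",
                                  2^config$planted_log2_effect,
                                  -(2^config$planted_log2_effect)))
      )
    })
  })

  ns <- config$samples_per_group
  group <- rep(c("cancer", "normal"), each = ns)
  sample_ids <- c(sprintf("C%03d", seq_len(ns)), sprintf("N%03d", seq_len(ns)))
  counter <- length(subtypes)  # truth substreams used 1..n_subtypes
  studies <- list()
  for (si in seq_along(subtypes)) {
    tr <- truth[truth$cancer_subtype == subtypes[si], ]
    delta_base <- ifelse(tr$direction == "null", 0,
                         sign(tr$true_fold) * config$planted_log2_effect)
    for (k in seq_len(config$studies_per_subtype)) {
      counter <- counter + 1
      st <- with_seed(substream_seed(config$seed, counter), {
        mu <- runif(g, config$baseline_log2_mean_range[1],
                    config$baseline_log2_mean_range[2])
        delta <- delta_base
        if (config$effect_jitter_sd > 0) {
          jitter <- rnorm(g, 0, config$effect_jitter_sd)
          delta <- ifelse(delta_base == 0, 0, delta_base + jitter)
        }
        eps <- matrix(rnorm(g * 2 * ns, 0, config$within_group_log2_sd),
                      g, 2 * ns)
        log2_vals <- mu + outer(delta, as.numeric(group == "cancer")) + eps
        vals <- 2^log2_vals
        dimnames(vals) <- list(genes, sample_ids)
        if (config$platform_dropout > 0) {
          keep <- runif(g) >= config$platform_dropout
          if (!any(keep)) keep[1] <- TRUE
          vals <- vals[keep, , drop = FALSE]
        }
        expression_study(vals, group,
                         study_id = sprintf("T%02dS%02d", si, k),
                         cancer_type = "Simulated",
                         cancer_subtype = subtypes[si])
      })
      studies[[st$study_id]] <- st
    }
  }
  structure(list(studies = studies, truth = truth),
            class = "study_collection")
}

#' @export
print.study_collection <- function(x, ...) {
  n_planted <- sum(x$truth$direction != "null")
  cat(sprintf(
    "<study_collection> %d studies over %d subtypes; %d planted truth entries\n",
    length(x$studies), n_distinct(x$truth$cancer_subtype), n_planted))
  invisible(x)
}

#' Score gate output against the planted simulation truth
#'
#' Compares above-threshold records from a simulated collection with the
#' planted ground truth, per subtype and per planted direction. A gene
#' counts as gated in a subtype when at least one of its analyses there is
#' above threshold.
#'
#' @param truth Truth tibble from [simulate_studies()].
#' @param records Above-threshold records obtained from the same collection.
#' @return A tibble with one row per (subtype, direction in over/under):
#'   `n_planted`, `n_gated` (planted genes with >= 1 record), `sensitivity`,
#'   `sign_agreement` (fraction of gated planted genes whose recorded
#'   direction matches the planted one; `NA` when none gated), plus
#'   `n_null` and `fpr` (null genes with >= 1 record of that direction /
#'   null genes). Sensitivity is `NA` when no gene of that direction was
#'   planted.
#' @export
truth_recovery_report <- function(truth, records) {
  gated <- records %>%
    distinct(.data$cancer_subtype, .data$gene_id, .data$direction) %>%
    rename(gated_direction = "direction")
  purrr::map_dfr(unique(truth$cancer_subtype), function(st) {
    tr <- truth[truth$cancer_subtype == st, ]
    gt <- gated[gated$cancer_subtype == st, ]
    null_genes <- tr$gene_id[tr$direction == "null"]
    purrr::map_dfr(c("over", "under"), function(dir) {
      planted <- tr$gene_id[tr$direction == dir]
      hit <- planted[planted %in% gt$gene_id]
      agree <- gt$gene_id[gt$gated_direction == dir]
      n_fp <- sum(null_genes %in% agree)
      tibble(
        cancer_subtype = st,
        direction = dir,
        n_planted = length(planted),
        n_gated = length(hit),
        sensitivity = if (length(planted) == 0) NA_real_ else
          length(hit) / length(planted),
        sign_agreement = if (length(hit) == 0) NA_real_ else
          mean(hit %in% agree),
        n_null = length(null_genes),
        fpr = if (length(null_genes) == 0) NA_real_ else
          n_fp / length(null_genes)
      )
    })
  })
}
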