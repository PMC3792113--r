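test_that("a minimal well-formed matrix + annotation loads and validates", {
  dir <- withr::local_tempdir()
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "KCNK1\t10\t12\t5\t6",
               "KCNK2\t8\t9\t8.5\t9.5",
               "KCNK3\t1.5\t2.5\t1.72E-1\t2"),
             file.path(dir, "m.tsv"))
  writeLines(c("sample_id\tgroup", "s1\tcancer", "s2\tcancer",
               "s3\tnormal", "s4\tnormal"),
             file.path(dir, "a.tsv"))
  st <- read_expression_study(file.path(dir, "m.tsv"), file.path(dir, "a.tsv"),
                              study_id = "S1", cancer_type = "Brain",
                              cancer_subtype = "Glioblastoma")
  expect_s3_class(st, "expression_study")
  expect_equal(nrow(st$values), 3)
  expect_equal(st$samples$group, c("cancer", "cancer", "normal", "normal"))
  # scientific notation parsed, locale-independent
  expect_equal(st$values["KCNK3", "s3"], 0.172)
})

test_that("malformed inputs are rejected with informative errors", {
  dir <- withr::local_tempdir()
  ann <- file.path(dir, "a.tsv")
  writeLines(c("sample_id\tgroup", "s1\tcancer", "s2\tcancer",
               "s3\tnormal", "s4\tnormal"), ann)

  dup <- file.path(dir, "dup.tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "KCNK1\t1\t2\t3\t4", "KCNK1\t5\t6\t7\t8"), dup)
  expect_error(read_expression_study(dup, ann), "Duplicate gene")

  badnum <- file.path(dir, "badnum.tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "KCNK1\t1\t2\tabc\t4"), badnum)
  expect_error(read_expression_study(badnum, ann), "KCNK1.*s3")

  small <- file.path(dir, "small.tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4", "KCNK1\t1\t2\t3\t4"), small)
  ann_13 <- file.path(dir, "a13.tsv")
  writeLines(c("sample_id\tgroup", "s1\tcancer", "s2\tnormal",
               "s3\tnormal", "s4\tnormal"), ann_13)
  expect_error(read_expression_study(small, ann_13), ">= 2 samples")

  ann_missing <- file.path(dir, "amiss.tsv")
  writeLines(c("sample_id\tgroup", "s1\tcancer", "s2\tcancer",
               "s3\tnormal"), ann_missing)
  expect_error(read_expression_study(small, ann_missing), "not annotated")

  header_only <- file.path(dir, "h.tsv")
  writeLines("gene_id", header_only)
  expect_error(read_expression_study(header_only, ann), "header")
})

test_that("log2-scale inputs are exponentiated to linear on load", {
  m <- matrix(c(3, 3, 1, 1, 4, 4, 2, 2), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "n1", "n2")))
  st <- expression_study(m, c("cancer", "cancer", "normal", "normal"),
                         study_id = "L", scale_hint = "log2")
  expect_equal(st$values["g1", ], c(c1 = 8, c2 = 8, n1 = 2, n2 = 2))
  # linear fold math is then one code path: 2^(3-1) = 4
  expect_equal(fold_change(st$values["g1", 1:2], st$values["g1", 3:4]), 4)
})

test_that("expression studies round-trip through disk exactly", {
  st <- make_toy_study(n_genes = 8, n_per_group = 3, seed = 11)
  st$values[2, 3] <- NA  # missing entries survive the round trip
  dir <- withr::local_tempdir()
  write_expression_study(st, file.path(dir, "m.tsv"), file.path(dir, "a.tsv"))
  back <- read_expression_study(file.path(dir, "m.tsv"),
                                file.path(dir, "a.tsv"),
                                study_id = st$study_id,
                                cancer_type = st$cancer_type,
                                cancer_subtype = st$cancer_subtype)
  expect_equal(back$values, st$values)
  expect_equal(back$samples, st$samples)
  expect_equal(back[c("study_id", "cancer_type", "cancer_subtype")],
               st[c("study_id", "cancer_type", "cancer_subtype")])
})

test_that("record tables are written sorted and round-trip exactly", {
  recs <- tibble::tibble(
    gene_id = c("KCNK2", "KCNK1", "KCNK1"),
    cancer_type = c("Lung", "Brain", "Brain"),
    cancer_subtype = c("Squamous cell", "Glioblastoma", "Glioblastoma"),
    study_id = c("S3", "S2", "S1"),
    direction = c("over", "under", "under"),
    p_value = c(2.98e-4, 1.03e-5, 1.72e-24),
    fold_change = c(2.111, -13.309, -9.574),
    percentile = c(5L, 4L, 2L)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_records_table(recs, path)
  back <- read_records_table(path)
  # independent sort of the same rows
  expect_equal(back, dplyr::arrange(recs, gene_id, cancer_type,
                                    cancer_subtype, p_value))
  # empty set -> header-only file
  write_records_table(recs[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_records_table(path)), 0L)
})

test_that("per-study result tables round-trip exactly", {
  res <- analyze_study(make_toy_study(n_genes = 12, shift_genes = 1,
                                      shift = 2, seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(res, path)
  back <- read_results_table(path)
  expect_equal(as.data.frame(back), as.data.frame(res),
               ignore_attr = TRUE)
})

test_that("manifests load their studies and reject broken entries", {
  dir <- withr::local_tempdir()
  st1 <- make_toy_study(seed = 1, study_id = "S1")
  st2 <- make_toy_study(seed = 2, study_id = "S2")
  write_expression_study(st1, file.path(dir, "s1_m.tsv"),
                         file.path(dir, "s1_a.tsv"))
  write_expression_study(st2, file.path(dir, "s2_m.tsv"),
                         file.path(dir, "s2_a.tsv"))
  yaml::write_yaml(list(studies = list(
    list(study_id = "S1", matrix = "s1_m.tsv", annotation = "s1_a.tsv",
         cancer_type = "Brain", cancer_subtype = "Glioblastoma"),
    list(study_id = "S2", matrix = "s2_m.tsv", annotation = "s2_a.tsv",
         cancer_type = "Brain", cancer_subtype = "Glioblastoma")
  )), file.path(dir, "manifest.yaml"))
  studies <- load_studies(file.path(dir, "manifest.yaml"))
  expect_named(studies, c("S1", "S2"))
  expect_equal(studies$S1$cancer_subtype, "Glioblastoma")

  yaml::write_yaml(list(studies = list(
    list(study_id = "S1", matrix = "s1_m.tsv", annotation = "s1_a.tsv"),
    list(study_id = "S1", matrix = "s2_m.tsv", annotation = "s2_a.tsv")
  )), file.path(dir, "dup.yaml"))
  expect_error(read_manifest(file.path(dir, "dup.yaml")), "unique")

  yaml::write_yaml(list(studies = list(
    list(study_id = "S9", matrix = "nope.tsv", annotation = "s1_a.tsv")
  )), file.path(dir, "missing.yaml"))
  expect_error(read_manifest(file.path(dir, "missing.yaml")), "missing file")
})
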