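report_cfg <- function(out_dir, seed = 2L) {
  analysis_config(
    out_dir = out_dir,
    simulate = sim_config(
      n_tissues = 6L, samples_per_tissue = c(30L, 20L, 15L, 10L, 8L, 6L),
      n_subjects = 60L, n_stable = 30L, n_tissue_specific = 12L,
      n_tissue_variable = 20L, n_heterogeneous = 15L, n_sex_dimorphic = 6L,
      n_silent = 10L, n_noncoding = 40L, seed = seed
    )
  )
}

test_that("per-tissue summaries follow the registry and flag the heterogeneous tissue", {
  sim <- default_sim()
  tab <- summarize_per_tissue(sim$score_table$gini_tissue, sim$cohort,
                              threshold = 0.2, mode = "lt")
  expect_equal(tab$tissue, names(sim$cohort$tissues))
  expect_equal(tab$n_samples, unname(cohort_manifest(sim$cohort)$n_samples))
  het <- names(sim$cohort$tissues)[sim$config$heterogeneous_tissue]
  expect_equal(tab$tissue[which.min(tab$n_housekeeping)], het)
  expect_equal(tab$tissue[which.max(tab$mean_gini_tissue)], het)

  single <- subset_tissues(sim$cohort, names(sim$cohort$tissues)[1])
  grid1 <- score_gini_tissue(single, sim$expressed)
  expect_equal(nrow(summarize_per_tissue(grid1, single)), 1L)
})

test_that("expression-bin summaries partition the scored genes", {
  sim <- default_sim()
  bins <- summarize_expression_bins(sim$score_table)
  expect_equal(nrow(bins), 12L)
  expect_equal(sum(bins$n_genes), nrow(sim$score_table$scores))
  expect_equal(bins$n_genes[1], 0L)  # below the 0.05 TPM filter floor
  expect_true(all(is.na(bins$mean_gini_subject[bins$n_genes == 0])))
})

test_that("a full simulate-then-analyse run emits a complete, consistent bundle", {
  out <- file.path(tempfile(), "run1")
  res <- run_full_analysis(report_cfg(out))
  expect_true(all(file.exists(res$files)))
  s <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(s$n_protein_coding, 30 + 12 + 20 + 15 + 6 + 10)
  expect_equal(s$n_expressed, s$n_protein_coding - s$n_low_expression_removed)
  expect_equal(s$n_intersection, length(res$call$intersection))
  expect_true(s$n_intersection <= s$n_subject_axis)
  expect_lt(res$summaries$comparisons$p_value[
    res$summaries$comparisons$comparison == "gini_subject_coding_vs_noncoding"
  ], 0.05)
  # pooled inequality exceeds the average within-tissue inequality
  paired <- res$summaries$comparisons[
    res$summaries$comparisons$comparison ==
      "gini_tissue_mean_vs_gini_subject_paired", ]
  expect_lt(paired$mean_difference, 0)
  expect_equal(nrow(res$recovery$metrics), 3L)
  # provenance header on every table
  first <- readLines(res$files[["scores"]], n = 1L)
  expect_match(first, "^# hkgini ")
})

test_that("re-running an identical configuration is byte-identical", {
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  run_full_analysis(report_cfg(d1))
  run_full_analysis(report_cfg(d2))
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_setequal(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("an unknown tissue in the tissue set fails before computation", {
  cfg <- report_cfg(file.path(tempfile(), "x"))
  cfg$tissue_set <- c("sim_tissue_01", "andromeda")
  expect_error(run_full_analysis(cfg), "andromeda")
  expect_false(dir.exists(cfg$out_dir))
})

test_that("within-tissue Gini and CV agree strongly on the synthetic cohort", {
  out <- file.path(tempfile(), "cv")
  res <- run_full_analysis(report_cfg(out))
  big <- res$summaries$cv_correlation[
    res$summaries$cv_correlation$tissue == "sim_tissue_01", ]
  expect_gt(big$r_squared, 0.5)
})
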