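small_cfg <- function(seed = 1L) {
  sim_config(
    n_tissues = 4L, samples_per_tissue = c(10L, 8L, 6L, 4L),
    n_subjects = 20L, n_stable = 15L, n_tissue_specific = 8L,
    n_tissue_variable = 10L, n_heterogeneous = 6L, n_sex_dimorphic = 4L,
    n_silent = 5L, n_noncoding = 12L, seed = seed
  )
}

test_that("the same seed reproduces the cohort byte for byte", {
  s1 <- generate_cohort(small_cfg(seed = 7L))
  s2 <- generate_cohort(small_cfg(seed = 7L))
  expect_identical(s1$cohort$tissues[[1]]$tpm, s2$cohort$tissues[[1]]$tpm)
  p1 <- tempfile(fileext = ".gct"); p2 <- tempfile(fileext = ".gct")
  write_gct(s1$cohort$tissues[[2]], p1)
  write_gct(s2$cohort$tissues[[2]], p2)
  expect_identical(readLines(p1), readLines(p2))

  s3 <- generate_cohort(small_cfg(seed = 8L))
  expect_false(identical(s1$cohort$tissues[[1]]$tpm,
                         s3$cohort$tissues[[1]]$tpm))
})

test_that("invalid simulation configs fail before any generation", {
  expect_error(sim_config(n_stable = -1L), "counts")
  expect_error(sim_config(within_sd = -0.1), "log-sd")
  expect_error(sim_config(n_tissues = 3L, samples_per_tissue = c(5L, 5L)),
               "length")
  expect_error(sim_config(sex_tissue = 99L), "sex_tissue")
  expect_error(sim_config(n_subjects = 10L), "largest tissue")
  expect_error(sim_config(specific_dropout = 1.5), "specific_dropout")
})

test_that("with all dispersions zero every non-silent gene has Gini 0 on both axes", {
  cfg <- sim_config(
    n_tissues = 4L, samples_per_tissue = c(6L, 5L, 4L, 3L), n_subjects = 12L,
    n_stable = 10L, n_tissue_variable = 8L, n_silent = 4L,
    n_tissue_specific = 0L, n_heterogeneous = 0L, n_sex_dimorphic = 0L,
    n_noncoding = 0L,
    within_sd = 0, between_sd_stable = 0, between_sd_variable = 0,
    heterogeneous_sd_multiplier = 1, quiet_sd_multiplier = 1, seed = 3L
  )
  sim <- generate_cohort(cfg)
  live <- sim$truth$gene_id[sim$truth$class != "silent"]
  expect_equal(unname(score_gini_subject(sim$cohort, live)),
               rep(0, length(live)))
  grid <- score_gini_tissue(sim$cohort, live)
  expect_equal(unname(as.vector(grid)), rep(0, length(grid)))
})

test_that("silent genes are exactly the genes removed by the 0.05 TPM filter", {
  sim <- default_sim()
  removed <- setdiff(sim$split$protein_coding, sim$expressed)
  expect_setequal(removed, truth_genes(sim, "silent"))
  expect_equal(attr(sim$expressed, "n_removed"),
               length(truth_genes(sim, "silent")))
})

test_that("tissue-specific genes are unequal across tissues but tight within their tissue", {
  sim <- default_sim()
  ts <- intersect(truth_genes(sim, "tissue_specific"),
                  sim$score_table$scores$gene_id)
  sc <- sim$score_table$scores
  expect_true(all(sc$gini_tpm[sc$gene_id %in% ts] > 0.8))
  designated <- sim$truth$designated_tissue[match(ts, sim$truth$gene_id)]
  within <- sim$score_table$gini_tissue[cbind(ts, designated)]
  # small-n Gini estimates are noisy; assert tightness where the designated
  # tissue has a reasonable donor count, plus the class-wide median
  sizes <- vapply(sim$cohort$tissues, function(m) ncol(m$tpm), 0L)
  well_sampled <- sizes[designated] >= 20L
  expect_true(all(within[well_sampled] < 0.35))
  expect_lt(median(within), 0.3)
  expect_true(all(sc$tau[sc$gene_id %in% ts] > 0.9))
})

test_that("planted classes separate on the subject axis in the designed order", {
  sim <- default_sim()
  gs <- setNames(sim$score_table$scores$gini_subject,
                 sim$score_table$scores$gene_id)
  med <- function(class) median(gs[intersect(truth_genes(sim, class), names(gs))])
  expect_lt(med("stable_housekeeping"),
            med("within_tissue_stable_tissue_variable"))
  expect_lt(med("within_tissue_stable_tissue_variable"),
            med("tissue_specific"))
})

test_that("the designated heterogeneous tissue maximises mean Gini-tissue and the quiet one minimises it", {
  sim <- default_sim()
  grid <- score_gini_tissue(sim$cohort, sim$split$protein_coding)
  tm <- attr(grid, "tissue_mean")
  het <- sim$truth$designated_tissue[sim$truth$class == "heterogeneous_marker"][1]
  expect_equal(names(which.max(tm)), het)
  expect_equal(names(which.min(tm)),
               names(sim$cohort$tissues)[sim$config$quiet_tissue])
})

test_that("recovery evaluation scores called lists against the stable class", {
  sim <- default_sim()
  stable <- truth_genes(sim, "stable_housekeeping")
  perfect <- structure(list(subject_axis = stable, tissue_axis = stable,
                            intersection = stable, params = list()),
                       class = "housekeeping_call")
  m <- evaluate_recovery(perfect, sim$truth)$metrics
  expect_equal(m$precision, rep(1, 3))
  expect_equal(m$recall, rep(1, 3))

  empty <- structure(list(subject_axis = character(), tissue_axis = character(),
                          intersection = character(), params = list()),
                     class = "housekeeping_call")
  m0 <- evaluate_recovery(empty, sim$truth)$metrics
  expect_true(all(is.na(m0$precision)))
  expect_equal(m0$recall, rep(0, 3))

  ghost <- structure(list(subject_axis = "GHOST.1", tissue_axis = character(),
                          intersection = character(), params = list()),
                     class = "housekeeping_call")
  expect_error(evaluate_recovery(ghost, sim$truth), "GHOST.1")
})
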