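test_that("a GCT fixture reads back its exact values and subject mapping", {
  vals <- c(1.5, 0, 3.25, 10, 0.007, 2)
  path <- write_toy_gct(vals, c("G1.1", "G2.1", "G3.1"),
                        c("GTEX-AB12-0001-SM", "GTEX-CD34-0002-SM"),
                        symbols = c("S1", "S2", "S3"))
  em <- read_gct(path, tissue = "liver")
  expect_s3_class(em, "expression_matrix")
  expect_equal(dim(em$tpm), c(3L, 2L))
  expect_equal(as.numeric(em$tpm), vals)
  expect_equal(rownames(em$tpm), c("G1.1", "G2.1", "G3.1"))
  expect_equal(unname(em$symbols), c("S1", "S2", "S3"))
  expect_equal(unname(em$subjects), c("GTEX-AB12", "GTEX-CD34"))
})

test_that("GCT write -> read round trip is value-identical, also gzipped", {
  set.seed(7)
  m <- matrix(round(rlnorm(40, 2, 1.3), 9), 8, 5,
              dimnames = list(sprintf("G%d.1", 1:8),
                              sprintf("SYN-%04d-01-SM", 1:5)))
  m[2, ] <- 0
  em <- expression_matrix("lung", m)
  for (ext in c(".gct", ".gct.gz")) {
    p <- tempfile(fileext = ext)
    write_gct(em, p)
    back <- read_gct(p, tissue = "lung")
    expect_identical(back$tpm, em$tpm)
  }
})

test_that("GCT format violations are rejected with informative errors", {
  ok_args <- list(values = 1:6, gene_ids = c("G1", "G2", "G3"),
                  sample_ids = c("A-1", "B-1"))
  p <- do.call(write_toy_gct, ok_args)
  lines <- readLines(p)

  v <- p; writeLines(c("#1.3", lines[-1]), v)
  expect_error(read_gct(v, "t"), "version|1\\.2")

  d <- tempfile(); writeLines(c(lines[1], "4\t2", lines[-(1:2)]), d)
  expect_error(read_gct(d, "t"), "expected 4 data rows, found 3")

  d2 <- tempfile(); writeLines(c(lines[1], "3\t5", lines[-(1:2)]), d2)
  expect_error(read_gct(d2, "t"), "expected 5 sample columns, found 2")

  neg <- do.call(write_toy_gct, modifyList(ok_args, list(values = c(1:5, -2))))
  expect_error(read_gct(neg, "t"), "negative")

  blank <- tempfile()
  writeLines(sub("\t6$", "\t", readLines(do.call(write_toy_gct, ok_args))),
             blank)
  expect_error(read_gct(blank, "t"), "blank|non-finite")
})

test_that("subject phenotypes decode the 1/2 sex convention", {
  p <- tempfile()
  writeLines(c("SUBJID\tSEX\tAGE",
               "GTEX-AB\t1\t50-59",
               "GTEX-CD\t2\t60-69",
               "GTEX-EF\t99\t20-29"), p)
  tab <- read_subject_phenotypes(p)
  expect_equal(tab$sex, c("male", "female", "unknown"))
  expect_equal(tab$subject_id, c("GTEX-AB", "GTEX-CD", "GTEX-EF"))

  dup <- tempfile()
  writeLines(c("SUBJID\tSEX\tAGE", "X-1\t1\t50-59", "X-1\t2\t50-59"), dup)
  expect_error(read_subject_phenotypes(dup), "duplicate")

  miss <- tempfile()
  writeLines(c("SUBJID\tAGE", "X-1\t50-59"), miss)
  expect_error(read_subject_phenotypes(miss), "SEX")
})

test_that("cohorts are assembled with exclusions, harmonised gene order and orphan reporting", {
  genes <- sprintf("G%02d.1", 1:10)
  m1 <- toy_matrix(rlnorm(30), genes, sprintf("SYN-%03d", 1:3), "01")
  perm <- sample(genes)
  m2raw <- toy_matrix(rlnorm(20), genes, sprintf("SYN-%03d", 4:5), "02")[perm, ]
  em1 <- expression_matrix("liver", m1)
  em2 <- expression_matrix("lung", m2raw)
  emx <- expression_matrix("cells_cultured_fibroblasts", m1)
  subjects <- data.frame(subject_id = sprintf("SYN-%03d", 1:5),
                         sex = "unknown", age = "50-59")
  co <- assemble_cohort(list(em1, em2, emx), subjects)
  expect_named(co$tissues, c("liver", "lung"))
  expect_equal(rownames(co$tissues$lung$tpm), genes)
  expect_equal(co$tissues$lung$tpm["G03.1", ], m2raw["G03.1", ])
  expect_equal(n_samples(co), 5L)
  expect_equal(cohort_manifest(co)$n_samples, c(3L, 2L))

  em3 <- expression_matrix("spleen",
                           toy_matrix(rlnorm(20), c(genes[-1], "OTHER.1"),
                                      sprintf("SYN-%03d", 6:7), "03"))
  expect_error(
    assemble_cohort(list(em1, em3), subjects, exclude_tissues = character()),
    "G01.1|OTHER.1"
  )

  expect_warning(
    assemble_cohort(list(em1), subjects[1:2, ], exclude_tissues = character()),
    "SYN-003"
  )
})

test_that("tissue presets match the documented registries", {
  m27 <- tissue_preset("major27")
  expect_length(m27, 27L)
  expect_true(all(c("testis", "liver") %in% m27))
  expect_false(any(c("whole_blood", "kidney_medulla") %in% m27))

  g52 <- tissue_preset("gtex52")
  expect_length(g52, 52L)
  expect_length(intersect(g52, cell_line_tissues()), 0L)
  expect_true(all(m27 %in% g52))
  expect_error(tissue_preset("major28"), "unknown")
})

test_that("tissue subsetting never changes stored values and validates names", {
  genes <- sprintf("G%d.1", 1:4)
  co <- toy_cohort(list(
    a = toy_matrix(rlnorm(12), genes, sprintf("S-%d", 1:3), "01"),
    b = toy_matrix(rlnorm(8), genes, sprintf("S-%d", 4:5), "02")
  ))
  sub <- subset_tissues(co, "b")
  expect_identical(sub$tissues$b$tpm, co$tissues$b$tpm)
  expect_equal(n_samples(sub), 2L)
  expect_error(subset_tissues(co, c("a", "zz")), "zz")
})

test_that("a cohort written to disk loads back value-identical", {
  genes <- sprintf("G%d.1", 1:5)
  sexes <- c("S-1" = "male", "S-2" = "female", "S-3" = "male")
  co <- toy_cohort(list(
    liver = toy_matrix(rlnorm(10), genes, c("S-1", "S-2"), "01"),
    lung = toy_matrix(rlnorm(5), genes, "S-3", "02")
  ), sexes)
  dir <- tempfile()
  write_cohort(co, dir)
  back <- load_cohort(dir)
  expect_identical(back$tissues$liver$tpm, co$tissues$liver$tpm)
  expect_identical(back$tissues$lung$tpm, co$tissues$lung$tpm)
  expect_equal(back$subjects$sex[match(names(sexes), back$subjects$subject_id)],
               unname(sexes))
})
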