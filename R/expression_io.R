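DEFAULT_SUBJECT_PATTERN <- "^[^-]+-[^-]+"

#' Construct a per-tissue expression matrix
#'
#' Wraps a gene x sample TPM matrix for one tissue together with the
#' sample-to-subject mapping. Values must be finite and non-negative.
#'
#' @param tissue tissue name (lower-snake-case by convention).
#' @param tpm numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param symbols optional character vector of gene symbols (the GCT
#'   `Description` column); defaults to the gene ids.
#' @param subjects optional named character vector mapping sample id to
#'   subject id; derived from `subject_pattern` when `NULL`.
#' @param subject_pattern regex whose match on a sample id yields the
#'   subject id (default: the first two dash-delimited fields, the GTEx
#'   convention `GTEX-ABCD`).
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(tissue, tpm, symbols = NULL, subjects = NULL,
                              subject_pattern = DEFAULT_SUBJECT_PATTERN) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)), !is.null(colnames(tpm)))
  if (anyNA(tpm) || any(!is.finite(tpm))) {
    stop("TPM matrix for '", tissue, "' contains non-finite or blank cells",
         call. = FALSE)
  }
  if (any(tpm < 0)) {
    stop("TPM matrix for '", tissue, "' contains negative values", call. = FALSE)
  }
  if (is.null(subjects)) {
    subjects <- subject_from_sample(colnames(tpm), subject_pattern)
  }
  stopifnot(length(subjects) == ncol(tpm))
  names(subjects) <- colnames(tpm)
  structure(
    list(
      tissue = tissue,
      tpm = tpm,
      symbols = setNames(symbols %||% rownames(tpm), rownames(tpm)),
      subjects = subjects
    ),
    class = "expression_matrix"
  )
}

subject_from_sample <- function(sample_ids, pattern = DEFAULT_SUBJECT_PATTERN) {
  m <- regexpr(pattern, sample_ids)
  if (any(m < 0)) {
    stop("sample id '", sample_ids[which(m < 0)[1L]],
         "' does not match the subject pattern '", pattern, "'", call. = FALSE)
  }
  regmatches(sample_ids, m)
}

#' Read a GCT v1.2 expression matrix
#'
#' GCT v1.2 is tab-delimited: line 1 is the version tag `#1.2`, line 2 the
#' `rows<TAB>columns` dimensions, line 3 the header (`Name`, `Description`,
#' then sample ids), followed by one row per gene. Gzipped files are read
#' transparently. Cells must be numeric: absence of expression is an
#' explicit `0`, a blank cell is an error, as is any negative value or a
#' dimension disagreement with line 2.
#'
#' @param path path to a `.gct` or `.gct.gz` file.
#' @param tissue tissue name; defaults to the file name stripped of the
#'   GTEx `gene_tpm_<date>_v8_` prefix and `.gct(.gz)` suffix.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()].
#' @export
read_gct <- function(path, tissue = NULL,
                     subject_pattern = DEFAULT_SUBJECT_PATTERN) {
  tissue <- tissue %||% gct_tissue_name(path)
  head2 <- read_text_lines(path, n = 2L)
  if (length(head2) < 2L || trimws(head2[1L]) != "#1.2") {
    stop("not a GCT v1.2 file (version line is '",
         if (length(head2)) head2[1L] else "", "', expected '#1.2')",
         call. = FALSE)
  }
  dims <- suppressWarnings(as.integer(strsplit(head2[2L], "\t", fixed = TRUE)[[1L]]))
  if (length(dims) < 2L || anyNA(dims[1:2])) {
    stop("GCT dimensions line is malformed: '", head2[2L], "'", call. = FALSE)
  }
  dt <- if (grepl("\\.gz$", path)) {
    # fread cannot open gz streams without extra packages; decompress here
    fread(text = read_text_lines(path)[-(1:2)], header = TRUE, sep = "\t",
          check.names = FALSE)
  } else {
    fread(path, skip = 2L, header = TRUE, sep = "\t", check.names = FALSE)
  }
  if (nrow(dt) != dims[1L]) {
    stop(sprintf("GCT dimension mismatch: expected %d data rows, found %d",
                 dims[1L], nrow(dt)), call. = FALSE)
  }
  if (ncol(dt) - 2L != dims[2L]) {
    stop(sprintf("GCT dimension mismatch: expected %d sample columns, found %d",
                 dims[2L], ncol(dt) - 2L), call. = FALSE)
  }
  vals <- as.matrix(dt[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(dt[[1L]])
  expression_matrix(tissue, vals, symbols = as.character(dt[[2L]]),
                    subject_pattern = subject_pattern)
}

gct_tissue_name <- function(path) {
  x <- sub("\\.gct(\\.gz)?$", "", basename(path))
  sub("^gene_tpm_[0-9-]+_v[0-9]+_", "", x)
}

#' Write an expression matrix as GCT v1.2
#'
#' Values are written at full double precision so that a read/write/read
#' round trip is value-identical. A `.gz` suffix gzips the output.
#'
#' @param em an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  # %.17g guarantees the doubles survive a write -> read round trip
  txt <- matrix(sprintf("%.17g", em$tpm), nrow = nrow(em$tpm))
  rows <- paste(
    rownames(em$tpm),
    unname(em$symbols[rownames(em$tpm)]),
    apply(txt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  write_text_lines(
    c(
      "#1.2",
      paste(nrow(em$tpm), ncol(em$tpm), sep = "\t"),
      paste(c("Name", "Description", colnames(em$tpm)), collapse = "\t"),
      rows
    ),
    path
  )
  invisible(path)
}

#' Read a subject phenotype table
#'
#' TSV with columns `SUBJID`, `SEX` and `AGE` (the GTEx
#' SubjectPhenotypes layout). Sex is decoded from the file's integer
#' convention: 1 = male, 2 = female, anything else = unknown. Duplicate
#' subject ids and missing columns are errors.
#'
#' @param path path to the phenotype TSV.
#' @return data frame with columns `subject_id`, `sex`
#'   (`male`/`female`/`unknown`) and `age`.
#' @export
read_subject_phenotypes <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, check.names = FALSE)
  for (col in c("SUBJID", "SEX", "AGE")) {
    if (!col %in% names(dt)) {
      stop("phenotype table is missing column '", col, "'", call. = FALSE)
    }
  }
  if (anyDuplicated(dt$SUBJID)) {
    stop("duplicate subject id '", dt$SUBJID[duplicated(dt$SUBJID)][1L],
         "' in phenotype table", call. = FALSE)
  }
  sex_code <- suppressWarnings(as.integer(dt$SEX))
  sex <- rep("unknown", nrow(dt))
  sex[!is.na(sex_code) & sex_code == 1L] <- "male"
  sex[!is.na(sex_code) & sex_code == 2L] <- "female"
  data.frame(
    subject_id = as.character(dt$SUBJID),
    sex = sex,
    age = as.character(dt$AGE),
    stringsAsFactors = FALSE
  )
}

#' Tissues excluded as cell lines
#'
#' The two GTEx "Gene TPMs by tissue" files that are cultured cell lines
#' rather than tissues; [assemble_cohort()] drops them by default.
#'
#' @return character vector of tissue names.
#' @export
cell_line_tissues <- function() {
  c("cells_cultured_fibroblasts", "cells_ebv-transformed_lymphocytes")
}

#' Assemble per-tissue matrices into a cohort
#'
#' A cohort bundles the per-tissue expression matrices (an ordered tissue
#' registry), the subject phenotype table and the shared gene universe. All
#' matrices must carry the same gene set; rows are harmonised to the first
#' matrix's order. Samples whose subject id is absent from the phenotype
#' table are reported with a warning and listed in the `orphan_samples`
#' element.
#'
#' @param matrices list of [expression_matrix()] objects.
#' @param subjects subject phenotype data frame
#'   (see [read_subject_phenotypes()]).
#' @param exclude_tissues tissue names dropped before assembly (default:
#'   the two cell-line files).
#' @return an `expr_cohort` object: list with elements `tissues` (named
#'   list), `subjects`, `genes`, `orphan_samples`.
#' @export
assemble_cohort <- function(matrices, subjects,
                            exclude_tissues = cell_line_tissues()) {
  stopifnot(length(matrices) >= 1L)
  nm <- vapply(matrices, function(m) m$tissue, "")
  if (anyDuplicated(nm)) {
    stop("duplicate tissue name '", nm[duplicated(nm)][1L], "'", call. = FALSE)
  }
  names(matrices) <- nm
  matrices <- matrices[!nm %in% exclude_tissues]
  if (!length(matrices)) {
    stop("no tissues left after exclusion", call. = FALSE)
  }
  genes <- rownames(matrices[[1L]]$tpm)
  for (m in matrices) {
    g <- rownames(m$tpm)
    if (!setequal(g, genes)) {
      diff1 <- c(setdiff(genes, g), setdiff(g, genes))[1L]
      stop("gene universes differ: tissue '", m$tissue,
           "' disagrees at gene '", diff1, "'", call. = FALSE)
    }
  }
  matrices <- lapply(matrices, function(m) {
    m$tpm <- m$tpm[genes, , drop = FALSE]
    m
  })
  all_subj <- unique(unlist(lapply(matrices, function(m) unname(m$subjects))))
  orphans <- character()
  missing_subj <- setdiff(all_subj, subjects$subject_id)
  if (length(missing_subj)) {
    orphans <- unlist(lapply(matrices, function(m) {
      names(m$subjects)[m$subjects %in% missing_subj]
    }), use.names = FALSE)
    warning(length(orphans), " sample(s) reference subjects absent from the ",
            "phenotype table (first: '", orphans[1L], "')", call. = FALSE)
  }
  structure(
    list(
      tissues = matrices,
      subjects = subjects,
      genes = genes,
      orphan_samples = orphans
    ),
    class = "expr_cohort"
  )
}

#' Built-in tissue presets
#'
#' `"gtex52"` is the 52 GTEx V8 bulk tissue subtypes retained after
#' excluding the two cell-line files; `"major27"` is the 27 representative
#' major-organ subtypes used for the consensus housekeeping lists.
#'
#' @param name `"gtex52"` or `"major27"`.
#' @return ordered character vector of tissue names.
#' @export
tissue_preset <- function(name) {
  major27 <- c(
    "adipose_subcutaneous", "adrenal_gland", "artery_aorta", "bladder",
    "brain_cerebellum", "brain_cortex", "breast_mammary_tissue",
    "colon_transverse", "esophagus_mucosa", "heart_atrial_appendage",
    "liver", "lung", "minor_salivary_gland", "muscle_skeletal",
    "nerve_tibial", "ovary", "pancreas", "pituitary", "prostate",
    "skin_sun_exposed_lower_leg", "small_intestine_terminal_ileum",
    "spleen", "stomach", "testis", "thyroid", "uterus", "vagina"
  )
  gtex52 <- c(
    "adipose_subcutaneous", "adipose_visceral_omentum", "adrenal_gland",
    "artery_aorta", "artery_coronary", "artery_tibial", "bladder",
    "brain_amygdala", "brain_anterior_cingulate_cortex_ba24",
    "brain_caudate_basal_ganglia", "brain_cerebellar_hemisphere",
    "brain_cerebellum", "brain_cortex", "brain_frontal_cortex_ba9",
    "brain_hippocampus", "brain_hypothalamus",
    "brain_nucleus_accumbens_basal_ganglia", "brain_putamen_basal_ganglia",
    "brain_spinal_cord_cervical_c-1", "brain_substantia_nigra",
    "breast_mammary_tissue", "cervix_ectocervix", "cervix_endocervix",
    "colon_sigmoid", "colon_transverse",
    "esophagus_gastroesophageal_junction", "esophagus_mucosa",
    "esophagus_muscularis", "fallopian_tube", "heart_atrial_appendage",
    "heart_left_ventricle", "kidney_cortex", "kidney_medulla", "liver",
    "lung", "minor_salivary_gland", "muscle_skeletal", "nerve_tibial",
    "ovary", "pancreas", "pituitary", "prostate",
    "skin_not_sun_exposed_suprapubic", "skin_sun_exposed_lower_leg",
    "small_intestine_terminal_ileum", "spleen", "stomach", "testis",
    "thyroid", "uterus", "vagina", "whole_blood"
  )
  switch(name,
    major27 = major27,
    gtex52 = gtex52,
    stop("unknown tissue preset '", name, "'", call. = FALSE)
  )
}

#' Restrict a cohort to a tissue subset
#'
#' Keeps the named tissues (in the given order) without touching any stored
#' value. Unknown tissue names are an error.
#'
#' @param cohort an [assemble_cohort()] result.
#' @param tissues character vector of tissue names, or a preset name
#'   accepted by [tissue_preset()].
#' @return the restricted cohort.
#' @export
subset_tissues <- function(cohort, tissues) {
  stopifnot(inherits(cohort, "expr_cohort"))
  if (length(tissues) == 1L && tissues %in% c("gtex52", "major27")) {
    tissues <- tissue_preset(tissues)
  }
  unknown <- setdiff(tissues, names(cohort$tissues))
  if (length(unknown)) {
    stop("unknown tissue '", unknown[1L], "' in tissue set", call. = FALSE)
  }
  cohort$tissues <- cohort$tissues[tissues]
  cohort
}

#' Per-tissue sample and gene counts
#'
#' @param cohort an `expr_cohort`.
#' @return data frame with columns `tissue`, `n_samples`, `n_genes`.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "expr_cohort"))
  data.frame(
    tissue = names(cohort$tissues),
    n_samples = vapply(cohort$tissues, function(m) ncol(m$tpm), 0L),
    n_genes = vapply(cohort$tissues, function(m) nrow(m$tpm), 0L),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Total number of samples in a cohort
#' @param cohort an `expr_cohort`.
#' @return integer sample count summed over tissues.
#' @export
n_samples <- function(cohort) {
  sum(vapply(cohort$tissues, function(m) ncol(m$tpm), 0L))
}

#' @export
print.expr_cohort <- function(x, ...) {
  cat(sprintf("expr_cohort: %d tissues, %d genes, %d samples, %d subjects\n",
              length(x$tissues), length(x$genes), n_samples(x),
              nrow(x$subjects)))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix '%s': %d genes x %d samples\n",
              x$tissue, nrow(x$tpm), ncol(x$tpm)))
  invisible(x)
}

#' Write a cohort to a directory / load it back
#'
#' `write_cohort()` emits one GCT v1.2 file per tissue
#' (`<tissue>.gct`), the phenotype TSV (`phenotypes.tsv`, GTEx column
#' conventions) and a manifest (`manifest.tsv`). `load_cohort()` reads such
#' a directory back into an `expr_cohort`.
#'
#' @param cohort an `expr_cohort`.
#' @param dir directory path.
#' @return `write_cohort()` the directory path invisibly; `load_cohort()`
#'   an `expr_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "expr_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in cohort$tissues) {
    write_gct(m, file.path(dir, paste0(m$tissue, ".gct")))
  }
  sex_code <- match(cohort$subjects$sex, c("male", "female"))
  sex_code[is.na(sex_code)] <- 99L
  fwrite(
    data.table(SUBJID = cohort$subjects$subject_id, SEX = sex_code,
               AGE = cohort$subjects$age),
    file.path(dir, "phenotypes.tsv"), sep = "\t", quote = FALSE
  )
  fwrite(as.data.table(cohort_manifest(cohort)),
         file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
load_cohort <- function(dir) {
  manifest <- fread(file.path(dir, "manifest.tsv"), sep = "\t", header = TRUE)
  mats <- lapply(manifest$tissue, function(t) {
    read_gct(file.path(dir, paste0(t, ".gct")), tissue = t)
  })
  subjects <- read_subject_phenotypes(file.path(dir, "phenotypes.tsv"))
  assemble_cohort(mats, subjects, exclude_tissues = character())
}
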