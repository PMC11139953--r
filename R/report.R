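#' Per-tissue summary of donor variability and housekeeping counts
#'
#' One row per tissue in the cohort's registry order: sample count, mean
#' Gini-tissue over the scored genes, and the number of genes whose
#' Gini-tissue passes the threshold in that tissue.
#'
#' @param grid genes x tissues matrix from [score_gini_tissue()].
#' @param cohort the cohort the grid was computed on.
#' @param threshold Gini-tissue threshold (default 0.2).
#' @param mode `"lt"` (default, genes called below the threshold) or
#'   `"le"`.
#' @return data frame: `tissue`, `n_samples`, `mean_gini_tissue`,
#'   `n_housekeeping`.
#' @export
summarize_per_tissue <- function(grid, cohort, threshold = 0.2, mode = "lt") {
  stopifnot(is.matrix(grid), inherits(cohort, "expr_cohort"))
  tissues <- intersect(names(cohort$tissues), colnames(grid))
  cmp <- cmp_fun(mode)
  data.frame(
    tissue = tissues,
    n_samples = vapply(cohort$tissues[tissues], function(m) ncol(m$tpm), 0L),
    mean_gini_tissue = colMeans(grid[, tissues, drop = FALSE], na.rm = TRUE),
    n_housekeeping = as.integer(colSums(cmp(grid[, tissues, drop = FALSE],
                                            threshold), na.rm = TRUE)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Gini-subject distribution by expression group
#'
#' Groups the scored genes into expression bins (see
#' [bin_by_expression()]) and summarises the Gini-subject distribution per
#' group; empty groups are kept with zero counts.
#'
#' @param score_table a [build_score_table()] result.
#' @param edges bin boundaries (default [expression_bin_edges()]).
#' @return data frame: `bin`, `tpm_range`, `n_genes`,
#'   `mean_gini_subject`, `median_gini_subject`.
#' @export
summarize_expression_bins <- function(score_table,
                                      edges = expression_bin_edges()) {
  stopifnot(inherits(score_table, "score_table"))
  sc <- score_table$scores
  bins <- bin_by_expression(sc$mean_tpm, edges)
  k <- length(edges) + 1L
  data.frame(
    bin = seq_len(k),
    tpm_range = expression_bin_labels(edges),
    n_genes = vapply(seq_len(k), function(b) sum(bins == b), 0L),
    mean_gini_subject = vapply(seq_len(k), function(b) {
      if (any(bins == b)) mean(sc$gini_subject[bins == b]) else NA_real_
    }, 0),
    median_gini_subject = vapply(seq_len(k), function(b) {
      if (any(bins == b)) median(sc$gini_subject[bins == b]) else NA_real_
    }, 0),
    stringsAsFactors = FALSE
  )
}

#' Configuration for a full analysis run
#'
#' A single flat configuration object for [run_full_analysis()]. Inputs
#' come either from a cohort directory written by [write_cohort()] (with a
#' catalog TSV) or from the synthetic generator (`simulate`). Defaults
#' mirror the pipeline's standard parameters: 0.05 TPM expression floor,
#' 0.2 Gini threshold, strict `<` for calling and `<=` for tissue-pass
#' counting.
#'
#' @param out_dir output directory (created if needed).
#' @param simulate a [sim_config()] for simulate-then-analyse mode.
#' @param cohort_dir directory holding GCTs + phenotypes (see
#'   [load_cohort()]); ignored when `simulate` is given.
#' @param catalog_file gene-catalog TSV (see [read_gene_catalog()]);
#'   required with `cohort_dir`.
#' @param tissue_set optional tissue subset: preset name (`"gtex52"`,
#'   `"major27"`) or explicit tissue names.
#' @param tpm_cutoff expression filter (TPM).
#' @param gini_threshold housekeeping Gini threshold.
#' @param call_mode,pass_mode comparison modes for calling and pass
#'   counting.
#' @param bin_edges expression-bin boundaries.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(out_dir,
                            simulate = NULL,
                            cohort_dir = NULL,
                            catalog_file = NULL,
                            tissue_set = NULL,
                            tpm_cutoff = 0.05,
                            gini_threshold = 0.2,
                            call_mode = "lt",
                            pass_mode = "le",
                            bin_edges = expression_bin_edges()) {
  if (is.null(simulate) && is.null(cohort_dir)) {
    stop("either 'simulate' or 'cohort_dir' must be given", call. = FALSE)
  }
  if (!is.null(cohort_dir) && is.null(simulate) && is.null(catalog_file)) {
    stop("'catalog_file' is required with 'cohort_dir'", call. = FALSE)
  }
  structure(as.list(environment()), class = "analysis_config")
}

prov_header <- function(params) {
  c(
    paste0("# hkgini ", as.character(packageVersion("hkgini"))),
    vapply(names(params), function(k) {
      paste0("# ", k, "=", paste(format(params[[k]], trim = TRUE),
                                 collapse = ","))
    }, "")
  )
}

write_tsv_report <- function(df, path, params) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  fwrite(as.data.table(df), tmp, sep = "\t", quote = FALSE, na = "NA")
  write_text_lines(c(prov_header(params), readLines(tmp)), path)
  invisible(path)
}

write_gene_list <- function(genes, path, params) {
  write_text_lines(c(prov_header(params), genes), path)
  invisible(path)
}

#' Run the full housekeeping-gene analysis
#'
#' Orchestrates every stage end to end: input (simulate or load), PAR-Y
#' deduplication, biotype split, coding-vs-non-coding contrast, expression
#' filtering, the three Gini variants plus Tau and CV, housekeeping calls
#' on both axes, per-tissue and expression-bin summaries, the paired
#' subject-vs-tissue-axis comparison, the per-tissue Gini-tissue/CV
#' correlation, and (with truth labels) planted-class recovery. All result
#' tables are written to `out_dir` with a provenance header holding the
#' resolved parameters, and a `summary.json` records the cardinality chain.
#' Re-running with an identical configuration reproduces the outputs
#' byte for byte.
#'
#' @param config an [analysis_config()].
#' @return the result bundle, invisibly: list with `cohort`, `catalog`,
#'   `score_table`, `call`, `summaries`, `recovery`, `files`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- generate_cohort(config$simulate)
    cohort <- sim$cohort
    catalog <- sim$catalog
    truth <- sim$truth
  } else {
    cohort <- load_cohort(config$cohort_dir)
    catalog <- read_gene_catalog(config$catalog_file)
  }
  if (!is.null(config$tissue_set)) {
    cohort <- subset_tissues(cohort, config$tissue_set)  # errors pre-compute
  }

  catalog <- drop_par_y(catalog)
  n_par_removed <- attr(catalog, "n_removed")
  split <- split_by_biotype(catalog)
  coding <- intersect(split$protein_coding, cohort$genes)
  noncoding <- intersect(split$non_coding, cohort$genes)
  if (!length(coding)) {
    stop("no protein-coding genes shared between catalog and cohort",
         call. = FALSE)
  }

  # coding vs non-coding contrast (expression level and pooled Gini)
  gini_subj_all <- score_gini_subject(cohort, c(coding, noncoding))
  mean_tpm_all <- rowMeans(tissue_mean_matrix(cohort, c(coding, noncoding)))
  contrast <- NULL
  if (length(noncoding) >= 2L && length(coding) >= 2L) {
    contrast <- rbind(
      cbind(comparison = "gini_subject_coding_vs_noncoding",
            compare_groups(gini_subj_all[coding], gini_subj_all[noncoding])),
      cbind(comparison = "mean_tpm_coding_vs_noncoding",
            compare_groups(mean_tpm_all[coding], mean_tpm_all[noncoding]))
    )
  }

  expressed <- filter_expressed(cohort, coding, config$tpm_cutoff)
  st <- build_score_table(cohort, expressed,
                          tissue_pass_threshold = config$gini_threshold,
                          tissue_pass_mode = config$pass_mode,
                          tpm_cutoff = config$tpm_cutoff)
  call <- call_housekeeping(st, config$gini_threshold, config$call_mode)

  per_tissue <- summarize_per_tissue(st$gini_tissue, cohort,
                                     config$gini_threshold, config$call_mode)
  bins <- summarize_expression_bins(st, config$bin_edges)
  paired <- cbind(
    comparison = "gini_tissue_mean_vs_gini_subject_paired",
    compare_groups(st$scores$gini_tissue_mean, st$scores$gini_subject,
                   paired = TRUE)
  )
  if (!is.null(contrast)) {
    contrast <- rbind(contrast, paired)
  } else {
    contrast <- paired
  }

  # within-tissue agreement of Gini-tissue with CV, per tissue
  cv_cor <- do.call(rbind, lapply(names(cohort$tissues), function(t) {
    m <- cohort$tissues[[t]]
    if (ncol(m$tpm) < 3L) {
      return(data.frame(tissue = t, r = NA_real_, r_squared = NA_real_))
    }
    g <- st$gini_tissue[, t]
    cv <- apply(m$tpm[expressed, , drop = FALSE], 1L, coef_variation)
    ok <- !is.na(g) & !is.na(cv)
    if (sum(ok) < 3L) {
      return(data.frame(tissue = t, r = NA_real_, r_squared = NA_real_))
    }
    cc <- correlate_scores(g[ok], cv[ok])
    data.frame(tissue = t, r = cc$r, r_squared = cc$r_squared)
  }))

  recovery <- if (!is.null(truth)) evaluate_recovery(call, truth)

  params <- list(
    tissue_set = names(cohort$tissues),
    tpm_cutoff = config$tpm_cutoff,
    gini_threshold = config$gini_threshold,
    call_mode = config$call_mode,
    pass_mode = config$pass_mode,
    n_par_y_removed = n_par_removed,
    n_protein_coding = length(coding),
    n_non_coding = length(noncoding),
    n_expressed = length(expressed),
    n_low_expression_removed = attr(expressed, "n_removed")
  )
  if (!is.null(config$simulate)) {
    params$seed <- config$simulate$seed
  }

  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "calls"), showWarnings = FALSE)
  grid_df <- data.frame(gene_id = rownames(st$gini_tissue),
                        as.data.frame(st$gini_tissue),
                        check.names = FALSE)
  files <- c(
    scores = write_tsv_report(st$scores, file.path(out, "scores.tsv"), params),
    gini_tissue = write_tsv_report(grid_df, file.path(out, "gini_tissue.tsv"),
                                   params),
    per_tissue = write_tsv_report(per_tissue,
                                  file.path(out, "per_tissue_summary.tsv"),
                                  params),
    bins = write_tsv_report(bins, file.path(out, "expression_bins.tsv"),
                            params),
    comparisons = write_tsv_report(contrast,
                                   file.path(out, "group_comparisons.tsv"),
                                   params),
    cv_cor = write_tsv_report(cv_cor, file.path(out, "cv_correlation.tsv"),
                              params),
    subject_axis = write_gene_list(call$subject_axis,
                                   file.path(out, "calls", "subject_axis.txt"),
                                   params),
    tissue_axis = write_gene_list(call$tissue_axis,
                                  file.path(out, "calls", "tissue_axis.txt"),
                                  params),
    intersection = write_gene_list(call$intersection,
                                   file.path(out, "calls", "intersection.txt"),
                                   params)
  )
  if (!is.null(recovery)) {
    files["recovery"] <- write_tsv_report(recovery$metrics,
                                          file.path(out, "recovery.tsv"),
                                          params)
  }
  summary <- c(params, list(
    n_subject_axis = length(call$subject_axis),
    n_tissue_axis = length(call$tissue_axis),
    n_intersection = length(call$intersection),
    n_samples = n_samples(cohort)
  ))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["summary"] <- file.path(out, "summary.json")

  invisible(list(
    cohort = cohort, catalog = catalog, score_table = st, call = call,
    summaries = list(per_tissue = per_tissue, expression_bins = bins,
                     comparisons = contrast, cv_correlation = cv_cor),
    recovery = recovery, files = files
  ))
}
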