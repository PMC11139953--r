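# gene x (all pooled samples) matrix for the requested genes
pooled_matrix <- function(cohort, genes) {
  check_cohort_genes(cohort, genes)
  do.call(cbind, lapply(cohort$tissues, function(m) {
    m$tpm[genes, , drop = FALSE]
  }))
}

check_cohort_genes <- function(cohort, genes) {
  stopifnot(inherits(cohort, "expr_cohort"))
  if (length(genes) == 0L) {
    stop("empty gene set", call. = FALSE)
  }
  missing <- setdiff(genes, cohort$genes)
  if (length(missing)) {
    stop("gene '", missing[1L], "' is absent from the cohort", call. = FALSE)
  }
  invisible(TRUE)
}

# per-gene x per-tissue matrix of mean TPMs
tissue_mean_matrix <- function(cohort, genes) {
  check_cohort_genes(cohort, genes)
  vapply(cohort$tissues, function(m) {
    rowMeans(m$tpm[genes, , drop = FALSE])
  }, numeric(length(genes)))
}

#' Filter genes by minimum average expression
#'
#' Retains genes whose unweighted mean of per-tissue mean TPMs is strictly
#' above `tpm_cutoff` (default 0.05 TPM, the housekeeping-gene expression
#' floor). The average is over tissues, not samples, so small tissues weigh
#' as much as large ones; the number of removed genes is attached as the
#' `n_removed` attribute and the per-gene averages as `mean_tpm`.
#'
#' @param cohort an `expr_cohort`.
#' @param genes gene ids to filter (default: the whole cohort universe).
#' @param tpm_cutoff non-negative expression floor in TPM.
#' @return character vector of retained gene ids, with attributes
#'   `n_removed` and `mean_tpm` (named, for the retained genes).
#' @export
filter_expressed <- function(cohort, genes = cohort$genes, tpm_cutoff = 0.05) {
  stopifnot(tpm_cutoff >= 0)
  tm <- tissue_mean_matrix(cohort, genes)
  overall <- rowMeans(tm)
  keep <- overall > tpm_cutoff
  out <- genes[keep]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "mean_tpm") <- setNames(overall[keep], out)
  out
}

#' Gini-subject: inequality over all pooled samples
#'
#' For each gene, the Gini index of its TPM values over the concatenation
#' of every sample of every tissue in the cohort's active tissue set. Each
#' sample counts as one individual; subject metadata plays no role here.
#' By construction the score depends only on the pooled vector, so it is
#' invariant to how samples are partitioned into tissues.
#'
#' @inheritParams filter_expressed
#' @return named numeric vector of Gini-subject scores in `[0, 1)`.
#' @export
score_gini_subject <- function(cohort, genes = cohort$genes) {
  pooled <- pooled_matrix(cohort, genes)
  setNames(apply(pooled, 1L, gini), genes)
}

#' Gini-tissue: inequality across donors within each tissue
#'
#' For each gene and each tissue, the Gini index over that tissue's samples
#' alone. Tissues with fewer than two samples yield `NA` (undefined) and
#' never enter pass counts. The per-gene mean over tissues and the
#' per-tissue mean over genes (both `NA`-aware) are attached as attributes
#' `gene_mean` and `tissue_mean`.
#'
#' @inheritParams filter_expressed
#' @return numeric matrix, genes x tissues, with attributes `gene_mean` and
#'   `tissue_mean`.
#' @export
score_gini_tissue <- function(cohort, genes = cohort$genes) {
  check_cohort_genes(cohort, genes)
  grid <- vapply(cohort$tissues, function(m) {
    if (ncol(m$tpm) < 2L) {
      return(rep(NA_real_, length(genes)))
    }
    apply(m$tpm[genes, , drop = FALSE], 1L, gini)
  }, numeric(length(genes)))
  if (is.null(dim(grid))) {
    grid <- matrix(grid, nrow = length(genes),
                   dimnames = list(genes, names(cohort$tissues)))
  } else {
    rownames(grid) <- genes
  }
  attr(grid, "gene_mean") <- rowMeans(grid, na.rm = TRUE)
  attr(grid, "tissue_mean") <- colMeans(grid, na.rm = TRUE)
  grid
}

#' Gini-TPM: inequality over per-tissue mean expression
#'
#' The conventional tissue-level Gini: for each gene, the Gini index of the
#' vector of per-tissue mean TPMs (one entry per tissue). Captures
#' between-tissue inequality only and ignores donor variation.
#'
#' @inheritParams filter_expressed
#' @return named numeric vector of scores.
#' @export
score_gini_tpm <- function(cohort, genes = cohort$genes) {
  tm <- tissue_mean_matrix(cohort, genes)
  if (ncol(tm) < 2L) {
    stop("Gini-TPM requires at least 2 tissues", call. = FALSE)
  }
  setNames(apply(tm, 1L, gini), genes)
}

#' Count tissues passing a Gini-tissue criterion
#'
#' Per gene, the number of tissues whose Gini-tissue score satisfies the
#' comparison with `threshold`. `NA` cells (tissues where the score is
#' undefined) never count. Default mode `"le"` mirrors the tissue-pass
#' column convention (score at most the threshold).
#'
#' @param grid genes x tissues score matrix from [score_gini_tissue()].
#' @param threshold Gini threshold in (0, 1), default 0.2.
#' @param mode `"le"` (score <= threshold) or `"lt"` (strict <).
#' @return named integer vector of pass counts.
#' @export
count_tissue_passes <- function(grid, threshold = 0.2, mode = "le") {
  stopifnot(is.matrix(grid), threshold > 0, threshold < 1)
  cmp <- cmp_fun(mode)
  pass <- cmp(grid, threshold)
  setNames(as.integer(rowSums(pass, na.rm = TRUE)), rownames(grid))
}

#' Call housekeeping genes on the subject and tissue axes
#'
#' Applies the Gini threshold (default 0.2) to a score table:
#' * `subject_axis` - genes whose pooled Gini-subject passes;
#' * `tissue_axis` - genes whose Gini-tissue passes in *every* tissue of
#'   `tissue_set` that has a defined score (and at least one defined score);
#' * `intersection` - genes on both axes.
#'
#' Default comparison is strict `"lt"` (score below the threshold). All
#' parameters that produced the call are stored alongside the lists.
#'
#' @param score_table a [build_score_table()] result.
#' @param gini_threshold threshold in (0, 1).
#' @param mode `"lt"` or `"le"`.
#' @param tissue_set tissues required on the tissue axis (default: every
#'   tissue in the score table).
#' @return a `housekeeping_call`: list with `subject_axis`, `tissue_axis`,
#'   `intersection` (character vectors) and `params`.
#' @export
call_housekeeping <- function(score_table, gini_threshold = 0.2, mode = "lt",
                              tissue_set = NULL) {
  stopifnot(inherits(score_table, "score_table"))
  if (!is.numeric(gini_threshold) || gini_threshold <= 0 || gini_threshold >= 1) {
    stop("gini_threshold must lie in (0, 1)", call. = FALSE)
  }
  cmp <- cmp_fun(mode)
  tissue_set <- tissue_set %||% colnames(score_table$gini_tissue)
  unknown <- setdiff(tissue_set, colnames(score_table$gini_tissue))
  if (length(unknown)) {
    stop("tissue '", unknown[1L], "' was not scored", call. = FALSE)
  }
  sc <- score_table$scores
  subject_axis <- sc$gene_id[cmp(sc$gini_subject, gini_threshold)]
  sub_grid <- score_table$gini_tissue[, tissue_set, drop = FALSE]
  pass <- cmp(sub_grid, gini_threshold)
  defined <- !is.na(sub_grid)
  all_pass <- rowSums(pass & defined) == rowSums(defined) & rowSums(defined) > 0
  tissue_axis <- rownames(sub_grid)[all_pass]
  structure(
    list(
      subject_axis = subject_axis,
      tissue_axis = tissue_axis,
      intersection = intersect(subject_axis, tissue_axis),
      params = list(
        gini_threshold = gini_threshold,
        mode = mode,
        tissue_set = tissue_set,
        tpm_cutoff = score_table$params$tpm_cutoff
      )
    ),
    class = "housekeeping_call"
  )
}

#' @export
print.housekeeping_call <- function(x, ...) {
  cat(sprintf(
    "housekeeping_call (threshold %g, mode %s, %d tissues):\n  subject_axis %d | tissue_axis %d | intersection %d genes\n",
    x$params$gini_threshold, x$params$mode, length(x$params$tissue_set),
    length(x$subject_axis), length(x$tissue_axis), length(x$intersection)
  ))
  invisible(x)
}

#' Exact intersection of gene lists
#'
#' @param ... character vectors of gene ids (or a single list of them).
#' @return character vector of genes present in every list; its length is
#'   attached as the `n` attribute.
#' @export
intersect_gene_lists <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1L]])) {
    lists <- lists[[1L]]
  }
  out <- Reduce(intersect, lists)
  attr(out, "n") <- length(out)
  out
}

#' Sex-stratified Gini-tissue for one gene
#'
#' Restricts one tissue's samples to male and to female donors (via the
#' cohort's subject phenotypes) and computes the Gini index in each group.
#' A group with fewer than two samples yields `NA`.
#'
#' @param cohort an `expr_cohort`.
#' @param tissue tissue name.
#' @param gene gene id.
#' @return named numeric vector `c(male = ..., female = ...)`.
#' @export
stratify_by_sex <- function(cohort, tissue, gene) {
  stopifnot(inherits(cohort, "expr_cohort"))
  if (!tissue %in% names(cohort$tissues)) {
    stop("unknown tissue '", tissue, "'", call. = FALSE)
  }
  m <- cohort$tissues[[tissue]]
  if (!gene %in% rownames(m$tpm)) {
    stop("unknown gene '", gene, "'", call. = FALSE)
  }
  sex <- cohort$subjects$sex[match(unname(m$subjects), cohort$subjects$subject_id)]
  v <- m$tpm[gene, ]
  one <- function(s) {
    vs <- v[!is.na(sex) & sex == s]
    if (length(vs) < 2L) NA_real_ else gini(vs)
  }
  c(male = one("male"), female = one("female"))
}

#' Two-group comparison of score vectors
#'
#' Two-sided t-test: Welch's for unpaired comparisons, the paired t-test
#' when `paired = TRUE` (requiring equal length and aligned gene order).
#' Degenerate inputs with zero variance are resolved analytically instead
#' of erroring: a zero mean difference gives statistic 0 and p = 1, a
#' constant non-zero difference gives an infinite statistic and p = 0.
#'
#' @param a,b numeric score vectors.
#' @param paired logical.
#' @return one-row data frame: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`, `mean_difference`.
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (paired && length(a) != length(b)) {
    stop("paired comparison requires equal-length, aligned vectors",
         call. = FALSE)
  }
  mean_diff <- if (paired) mean(a - b) else mean(a) - mean(b)
  # mirror t.test()'s "essentially constant" guard instead of erroring
  stderr <- if (paired) {
    sd(a - b) / sqrt(length(a))
  } else {
    sqrt(sd(a)^2 / length(a) + sd(b)^2 / length(b))
  }
  degenerate <- is.na(stderr) || stderr == 0 ||
    stderr < 10 * .Machine$double.eps * abs(mean_diff)
  if (degenerate) {
    stat <- if (mean_diff == 0) 0 else sign(mean_diff) * Inf
    p <- if (mean_diff == 0) 1 else 0
    return(data.frame(
      statistic = stat, df = NA_real_, p_value = p,
      mean_a = mean(a), mean_b = mean(b), mean_difference = mean_diff
    ))
  }
  tt <- t.test(a, b, paired = paired, var.equal = FALSE)
  data.frame(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(a),
    mean_b = mean(b),
    mean_difference = mean_diff
  )
}

#' Pearson correlation between two score vectors
#'
#' @param x,y equal-length numeric vectors without undefined entries.
#' @return list with `r` and `r_squared` (`NA` for zero-variance input).
#' @export
correlate_scores <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) {
    stop("correlation requires at least 3 paired values", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("undefined entries in score vectors", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, r_squared = NA_real_))
  }
  r <- cor(x, y)
  list(r = r, r_squared = r^2)
}

#' Build the per-gene score table
#'
#' Computes, for each gene: the unweighted mean of per-tissue mean TPMs
#' (`mean_tpm`, the reported "average TPM"), Gini-subject over pooled
#' samples, the per-tissue Gini-tissue grid with its per-gene mean,
#' Gini-TPM over tissue means, Tau over tissue means, the coefficient of
#' variation over pooled samples, and the tissue-pass count at
#' `tissue_pass_threshold` (default 0.2, mode `"le"`).
#'
#' @inheritParams filter_expressed
#' @param tissue_pass_threshold threshold for the pass-count column.
#' @param tissue_pass_mode `"le"` (default) or `"lt"`.
#' @param tpm_cutoff recorded provenance: the expression filter the gene
#'   set was built with (not re-applied here).
#' @return a `score_table`: list with `scores` (data frame), `gini_tissue`
#'   (matrix), `tissues`, `params`.
#' @export
build_score_table <- function(cohort, genes = cohort$genes,
                              tissue_pass_threshold = 0.2,
                              tissue_pass_mode = "le",
                              tpm_cutoff = NA_real_) {
  check_cohort_genes(cohort, genes)
  genes <- as.character(genes)
  tm <- tissue_mean_matrix(cohort, genes)
  pooled <- pooled_matrix(cohort, genes)
  grid <- score_gini_tissue(cohort, genes)
  scores <- data.frame(
    gene_id = genes,
    mean_tpm = rowMeans(tm),
    gini_subject = apply(pooled, 1L, gini),
    gini_tissue_mean = attr(grid, "gene_mean"),
    gini_tpm = if (ncol(tm) >= 2L) apply(tm, 1L, gini) else NA_real_,
    tau = apply(tm, 1L, function(v) {
      if (max(v) == 0 || length(v) == 1L) NA_real_ else tau_index(v)
    }),
    cv = apply(pooled, 1L, coef_variation),
    tissue_pass_count = count_tissue_passes(grid, tissue_pass_threshold,
                                            tissue_pass_mode),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      scores = scores,
      gini_tissue = grid,
      tissues = names(cohort$tissues),
      params = list(
        tissue_pass_threshold = tissue_pass_threshold,
        tissue_pass_mode = tissue_pass_mode,
        tpm_cutoff = tpm_cutoff,
        n_tissues = length(cohort$tissues),
        n_samples = n_samples(cohort)
      )
    ),
    class = "score_table"
  )
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d genes x %d tissues (%d samples)\n",
              nrow(x$scores), x$params$n_tissues, x$params$n_samples))
  invisible(x)
}
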