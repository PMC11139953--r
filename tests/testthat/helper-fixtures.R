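# Independent brute-force Gini oracle: literal double sum over ordered
# pairs, written without reference to the package implementation.
oracle_gini <- function(v) {
  n <- length(v)
  if (mean(v) == 0) {
    return(0)
  }
  total <- 0
  for (i in seq_len(n)) {
    total <- total + sum(abs(v[i] - v))
  }
  total / (2 * n^2 * mean(v))
}

gff3_line <- function(chrom, type, attrs, start = 1L, end = 1000L) {
  paste(chrom, "HAVANA", type, start, end, ".", "+", ".", attrs, sep = "\t")
}

gene_gff3_line <- function(chrom, gene_id, gene_type, gene_name) {
  gff3_line(chrom, "gene", sprintf("ID=%s;gene_id=%s;gene_type=%s;gene_name=%s",
                                   gene_id, gene_id, gene_type, gene_name))
}

write_toy_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

# GCT v1.2 text for an explicit value matrix
write_toy_gct <- function(values, gene_ids, sample_ids,
                          symbols = gene_ids,
                          path = tempfile(fileext = ".gct"),
                          dims = NULL) {
  values <- matrix(values, nrow = length(gene_ids))
  body <- apply(values, 1L, function(r) paste(r, collapse = "\t"))
  writeLines(c(
    "#1.2",
    paste(dims[1L] %||% nrow(values), dims[2L] %||% ncol(values), sep = "\t"),
    paste(c("Name", "Description", sample_ids), collapse = "\t"),
    paste(gene_ids, symbols, body, sep = "\t")
  ), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small in-memory cohort: tissue_values is a named list of gene x sample
# matrices sharing rownames; sample ids encode the subject in the first two
# dash fields; sexes is a named character vector subject -> sex
toy_cohort <- function(tissue_values, sexes = NULL) {
  mats <- lapply(names(tissue_values), function(t) {
    m <- tissue_values[[t]]
    expression_matrix(t, m)
  })
  subj <- unique(unlist(lapply(mats, function(m) unname(m$subjects))))
  subjects <- data.frame(
    subject_id = subj,
    sex = if (is.null(sexes)) rep("unknown", length(subj)) else
      unname(sexes[subj]),
    age = rep("50-59", length(subj)),
    stringsAsFactors = FALSE
  )
  assemble_cohort(mats, subjects, exclude_tissues = character())
}

# gene x sample matrix with GTEx-like sample ids SUBJ-<k>-<tissue>
toy_matrix <- function(values, genes, subj_ids, tag = "01") {
  m <- matrix(values, nrow = length(genes), byrow = TRUE)
  dimnames(m) <- list(genes, paste0(subj_ids, "-", tag, "-SM"))
  m
}
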