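#' Construct a gene catalog
#'
#' A gene catalog is a data frame with one row per gene and columns
#' `gene_id`, `symbol`, `biotype`, `chromosome`, `par_y`. It is the product
#' of annotation parsing and the input to PAR-Y deduplication and the
#' biotype split.
#'
#' @param gene_id character, versioned gene identifiers (non-empty).
#' @param symbol character gene symbols.
#' @param biotype character biotype labels (e.g. `"protein_coding"`).
#' @param chromosome character chromosome names.
#' @param par_y logical, `TRUE` for the chrY pseudoautosomal copy of an
#'   X-located twin.
#' @return a `gene_catalog` data frame.
#' @export
gene_catalog <- function(gene_id, symbol, biotype, chromosome,
                         par_y = logical(length(gene_id))) {
  if (length(gene_id) && (anyNA(gene_id) || any(!nzchar(gene_id)))) {
    stop("gene_id entries must be non-empty", call. = FALSE)
  }
  out <- data.frame(
    gene_id = as.character(gene_id),
    symbol = as.character(symbol),
    biotype = as.character(biotype),
    chromosome = as.character(chromosome),
    par_y = as.logical(par_y),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' Parse gene records from a GFF3 annotation file
#'
#' Reads a (possibly gzipped) GFF3 stream and extracts one record per
#' `gene` feature line, keeping the `gene_id`, `gene_type` and `gene_name`
#' attributes verbatim. Pseudoautosomal chrY duplicates are flagged when the
#' gene identifier carries the `_PAR_Y` suffix (the convention of the GTEx
#' gene universe) or, as a fallback for generic GFF3, when a chrY record has
#' an identically identified twin on chrX.
#'
#' @param path path to a GFF3 file, plain or `.gz`.
#' @return a [gene_catalog()] with the genes in file order.
#' @export
read_gff3_genes <- function(path) {
  lines <- read_text_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) {
    stop(sprintf(
      "malformed GFF3 line %d: expected 9 tab-separated fields, found %d",
      idx[bad[1L]], lengths(fields)[bad[1L]]
    ), call. = FALSE)
  }
  type <- vapply(fields, `[[`, "", 3L)
  gi <- which(type == "gene")
  if (!length(gi)) {
    return(gene_catalog(character(), character(), character(), character()))
  }
  parse_attrs <- function(f, line_no) {
    pairs <- strsplit(strsplit(f[[9L]], ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
    vals <- vapply(pairs, function(p) if (length(p) >= 2L) p[[2L]] else NA_character_, "")
    names(vals) <- vapply(pairs, `[[`, "", 1L)
    for (a in c("gene_id", "gene_type", "gene_name")) {
      if (!a %in% names(vals) || is.na(vals[[a]])) {
        stop(sprintf("GFF3 line %d: missing mandatory attribute '%s'", line_no, a),
             call. = FALSE)
      }
    }
    vals
  }
  attrs <- mapply(parse_attrs, fields[gi], idx[gi], SIMPLIFY = FALSE)
  cat <- gene_catalog(
    gene_id = vapply(attrs, `[[`, "", "gene_id"),
    symbol = vapply(attrs, `[[`, "", "gene_name"),
    biotype = vapply(attrs, `[[`, "", "gene_type"),
    chromosome = vapply(fields[gi], `[[`, "", 1L)
  )
  flag_par_y(cat)
}

# PAR-Y flagging rule: explicit `_PAR_Y` id suffix, else a chrY record whose
# identifier also occurs on chrX
flag_par_y <- function(catalog) {
  suffix <- grepl("_PAR_Y$", catalog$gene_id)
  base <- sub("_PAR_Y$", "", catalog$gene_id)
  on_y <- catalog$chromosome %in% c("chrY", "Y")
  on_x <- catalog$chromosome %in% c("chrX", "X")
  twin <- on_y & base %in% base[on_x]
  catalog$par_y <- suffix | twin
  catalog
}

#' Remove pseudoautosomal chrY duplicate records
#'
#' Drops every record flagged `par_y`, keeping the X-located copies and the
#' original gene order. The number of removed records is attached as the
#' `n_removed` attribute. Idempotent.
#'
#' @param catalog a [gene_catalog()].
#' @return the deduplicated catalog with attribute `n_removed`.
#' @export
drop_par_y <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  removed <- sum(catalog$par_y)
  out <- catalog[!catalog$par_y, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(catalog)
  attr(out, "n_removed") <- removed
  out
}

#' Split a catalog into protein-coding and non-coding gene sets
#'
#' Membership is decided solely by exact equality of the biotype string with
#' `"protein_coding"`; the partition is exhaustive and disjoint.
#'
#' @param catalog a deduplicated [gene_catalog()].
#' @return list with character vectors `protein_coding` and `non_coding`.
#' @export
split_by_biotype <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  coding <- catalog$biotype == "protein_coding"
  list(
    protein_coding = catalog$gene_id[coding],
    non_coding = catalog$gene_id[!coding]
  )
}

#' Write / read a gene catalog as TSV
#'
#' Plain five-column TSV (`gene_id`, `symbol`, `biotype`, `chromosome`,
#' `par_y`); reading back reproduces the records exactly.
#'
#' @param catalog a [gene_catalog()].
#' @param path output (or input) file path.
#' @return `write_gene_catalog()` returns `path` invisibly;
#'   `read_gene_catalog()` returns a [gene_catalog()].
#' @export
write_gene_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  fwrite(as.data.table(unclass(catalog)), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_gene_catalog
#' @export
read_gene_catalog <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("gene_id", "symbol", "biotype", "chromosome"),
    logical = "par_y"
  ))
  gene_catalog(dt$gene_id, dt$symbol, dt$biotype, dt$chromosome, dt$par_y)
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf(
    "gene_catalog: %d genes (%d protein_coding, %d PAR-Y flagged)\n",
    nrow(x), sum(x$biotype == "protein_coding"), sum(x$par_y)
  ))
  invisible(x)
}
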