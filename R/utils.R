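`%||%` <- function(a, b) if (is.null(a)) b else a

# shared validation for metric inputs: finite, non-negative, non-empty
check_value_vector <- function(x, what = "values") {
  if (!is.numeric(x)) {
    stop(what, " must be a numeric vector", call. = FALSE)
  }
  if (length(x) == 0L) {
    stop(what, " must contain at least one entry", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(what, " contain non-finite entries", call. = FALSE)
  }
  if (any(x < 0)) {
    stop(what, " contain negative entries", call. = FALSE)
  }
  invisible(x)
}

# "lt" -> strict <, "le" -> <=; every thresholding step routes through this
cmp_fun <- function(mode) {
  mode <- match.arg(mode, c("lt", "le"))
  if (mode == "lt") `<` else `<=`
}

# gzip-transparent line reader (gzfile() also reads plain text)
read_text_lines <- function(path, n = -1L) {
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  readLines(con, n = n)
}

write_text_lines <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con)
}
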