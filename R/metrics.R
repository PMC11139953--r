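#' Gini index of a non-negative value vector
#'
#' The Gini index is the mean absolute difference between every pair of
#' observations, normalised by twice the mean:
#' \deqn{G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \mu}.}
#' It is 0 when all values are equal and bounded above by \eqn{(n-1)/n},
#' attained when a single observation holds all the mass. `gini()` evaluates
#' the equivalent sorted form
#' \deqn{G = \frac{2 \sum_i i\, x_{(i)}}{n \sum_i x_i} - \frac{n+1}{n}}
#' (1-based ranks over the ascending sort), which is O(n log n) and therefore
#' usable on vectors of tens of thousands of pooled samples.
#' [gini_pairwise()] evaluates the O(n^2) pairwise definition directly.
#'
#' All-equal vectors, including all-zero vectors, score 0 by convention:
#' perfect equality is the minimum of the index and TPM data contain exact
#' zeros, so no epsilon shift is applied.
#'
#' @param x numeric vector of finite, non-negative values (e.g. TPMs).
#' @param unbiased if `TRUE`, apply the small-sample correction `n / (n - 1)`
#'   (the default population form uses the `n^2` denominator).
#' @return a single number in `[0, (n-1)/n]`.
#' @examples
#' gini(c(5, 5, 5, 5))   # 0
#' gini(c(0, 0, 0, 7))   # 0.75 = (n-1)/n
#' gini(c(1, 2, 3, 4))   # 0.25
#' @seealso [gini_pairwise()], [tau_index()], [coef_variation()]
#' @export
gini <- function(x, unbiased = FALSE) {
  check_value_vector(x)
  n <- length(x)
  if (n == 1L) {
    return(0)
  }
  s <- sum(x)
  if (s == 0) {
    return(0)
  }
  xs <- sort.int(x, method = "quick")
  if (xs[1L] == xs[n]) {
    return(0)
  }
  g <- 2 * sum(seq_len(n) * xs) / (n * s) - (n + 1) / n
  if (unbiased) {
    g <- g * n / (n - 1)
  }
  g
}

#' Gini index by the direct pairwise definition
#'
#' Computes \eqn{\sum_i \sum_j |x_i - x_j| / (2 n^2 \mu)} literally, in
#' O(n^2) time and memory. Agrees with [gini()] to floating-point precision;
#' intended for small vectors and as a readable statement of the definition.
#'
#' @inheritParams gini
#' @return a single number in `[0, (n-1)/n]`.
#' @export
gini_pairwise <- function(x, unbiased = FALSE) {
  check_value_vector(x)
  n <- length(x)
  if (n == 1L) {
    return(0)
  }
  m <- mean(x)
  if (m == 0) {
    return(0)
  }
  g <- sum(abs(outer(x, x, `-`))) / (2 * n^2 * m)
  if (unbiased) {
    g <- g * n / (n - 1)
  }
  g
}

#' Coefficient of variation (population form)
#'
#' Population standard deviation divided by the mean. Returns the ratio;
#' multiply by 100 for the percentage convention used in reports. A
#' zero-mean vector (e.g. an unexpressed gene) yields `NA_real_` rather than
#' an error, because the pipeline filters unexpressed genes before scoring.
#'
#' @inheritParams gini
#' @return non-negative ratio, or `NA_real_` when the mean is zero.
#' @export
coef_variation <- function(x) {
  check_value_vector(x)
  m <- mean(x)
  if (m == 0) {
    return(NA_real_)
  }
  sqrt(mean((x - m)^2)) / m
}

#' Tissue specificity index Tau
#'
#' \deqn{\tau = \frac{\sum_i (1 - x_i / \max x)}{n - 1}}
#' computed on raw values (no log transform). Tau is 0 for a constant
#' positive profile and exactly 1 when a single context carries all
#' expression. Undefined (`NA_real_`) for all-zero vectors and for `n = 1`.
#'
#' In this package Tau is a reported diagnostic computed on the vector of
#' per-tissue mean TPMs; it does not gate any housekeeping call.
#'
#' @inheritParams gini
#' @return a number in `[0, 1]`, or `NA_real_` when undefined.
#' @examples
#' tau_index(c(3, 3, 3, 3))  # 0
#' tau_index(c(0, 0, 9))     # 1
#' tau_index(c(2, 4, 8))     # 0.625
#' @export
tau_index <- function(x) {
  check_value_vector(x)
  n <- length(x)
  mx <- max(x)
  if (n == 1L || mx == 0) {
    return(NA_real_)
  }
  sum(1 - x / mx) / (n - 1)
}

#' Default expression-bin boundaries
#'
#' Interior boundaries (in TPM) used to group genes by mean expression for
#' the Gini-by-expression summary. The 11 default boundaries partition
#' `[0, Inf)` into 12 half-open groups; the lowest, `[0, 0.05)`, is empty
#' once the 0.05 TPM expression filter has run, and the top group collects
#' genes with mean TPM of 100 or more.
#'
#' @return strictly ascending numeric vector of bin boundaries.
#' @export
expression_bin_edges <- function() {
  c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 20, 50, 100)
}

#' Assign mean expression values to expression groups
#'
#' Half-open binning: a value equal to a boundary belongs to the higher
#' group; values at or above the last boundary go to the top group; values
#' below the first boundary go to group 1.
#'
#' @param mean_tpm non-negative numeric vector of mean TPMs.
#' @param edges strictly ascending boundaries (default
#'   [expression_bin_edges()]).
#' @return integer group indices in `1 .. length(edges) + 1`.
#' @export
bin_by_expression <- function(mean_tpm, edges = expression_bin_edges()) {
  check_value_vector(mean_tpm, "mean_tpm")
  if (!is.numeric(edges) || length(edges) < 1L || is.unsorted(edges, strictly = TRUE)) {
    stop("edges must be strictly ascending", call. = FALSE)
  }
  findInterval(mean_tpm, edges) + 1L
}

# human-readable labels for the groups delimited by `edges`
expression_bin_labels <- function(edges = expression_bin_edges()) {
  k <- length(edges)
  c(
    sprintf("[0,%g)", edges[1L]),
    sprintf("[%g,%g)", edges[-k], edges[-1L]),
    sprintf(">=%g", edges[k])
  )
}
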