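#' Rank-based comparison of methods across datasets
#'
#' Given an AUC table (methods in rows, datasets in columns), computes the
#' within-dataset ranks (1 = best AUC; ties get average ranks), each
#' method's average rank over datasets, and an exact two-sided Wilcoxon
#' signed-rank p-value on the paired per-dataset ranks of two designated
#' methods — the protocol used to compare the best and second-best method
#' of a benchmark.
#'
#' The signed-rank null distribution is computed exactly (by dynamic
#' programming over all `2^n` sign assignments, ties handled by midranks)
#' for up to 25 datasets, and by normal approximation beyond; benchmark
#' comparisons over ~10 datasets demand the exact test.
#'
#' @param auc_table Numeric matrix, methods x datasets, with method
#'   rownames.
#' @param method_a,method_b Rownames (or indices) of the two methods to
#'   test.
#' @return List of class `"method_comparison"`: `ranks` (methods x
#'   datasets), `avg_rank` (named vector), `signed_rank_p` (scalar, `NA`
#'   with a warning for a single dataset), `pair`.
#' @export
compare_methods <- function(auc_table, method_a, method_b) {
  m <- as.matrix(auc_table)
  if (is.null(rownames(m))) {
    rownames(m) <- paste0("method", seq_len(nrow(m)))
  }
  if (nrow(m) < 2L || ncol(m) < 1L) {
    stop("invalid input: need >= 2 methods and >= 1 dataset", call. = FALSE)
  }
  if (anyNA(m)) stop("invalid input: AUC table contains NA", call. = FALSE)
  ranks <- apply(m, 2, function(col) rank(-col, ties.method = "average"))
  ranks <- matrix(ranks, nrow = nrow(m), dimnames = dimnames(m))
  avg_rank <- rowMeans(ranks)
  ra <- ranks[method_a, ]
  rb <- ranks[method_b, ]
  if (ncol(m) < 2L) {
    warning("single dataset: signed-rank p-value undefined")
    p <- NA_real_
  } else {
    p <- exact_signed_rank_test(ra - rb)
  }
  structure(
    list(ranks = ranks, avg_rank = avg_rank, signed_rank_p = p,
         pair = c(method_a, method_b)),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\naverage ranks:\n")
  print(round(sort(x$avg_rank), 3))
  cat(sprintf("signed-rank p (%s vs %s): %s\n", x$pair[1], x$pair[2],
              format(x$signed_rank_p, digits = 4)))
  invisible(x)
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Paired test on differences `d`: zeros are dropped, absolute values are
#' midranked, and the two-sided p-value is computed from the exact
#' permutation distribution of the positive-rank sum `W+` under random
#' sign flips (each of the `2^n` sign patterns equally likely). Midranks
#' are doubled to keep the convolution integral-valued. For `n > 25`
#' differences the normal approximation with tie correction is used.
#'
#' @param d Numeric vector of paired differences.
#' @return Two-sided p-value (1 when all differences are zero).
#' @export
exact_signed_rank_test <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  if (n <= 25L) {
    r2 <- as.integer(round(2 * r))      # midranks are multiples of 1/2
    total <- sum(r2)
    # coef[s + 1] = number of sign patterns with doubled rank sum s
    coef <- numeric(total + 1)
    coef[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), coef[seq_len(total + 1 - ri)])
      coef <- coef + shifted
    }
    probs <- coef / 2^n
    w2 <- round(2 * w_plus)
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    # variance with tie correction over midranks
    sigma2 <- sum(r^2) / 4
    z <- (w_plus - mu) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}
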