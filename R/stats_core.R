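# Shared statistical procedures. Each wrapper returns a uniform result object
# so downstream modules and reports never depend on the shape of htest.

new_test_result <- function(statistic, p_value, n, method) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(statistic = unname(statistic), p_value = unname(p_value),
         n = n, method = method),
    class = "pislice_test"
  )
}

#' @export
print.pislice_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format(x$p_value), " n =", paste(x$n, collapse = ", "), "\n")
  invisible(x)
}

#' Two-sample Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-tailed. Uses exact enumeration when both samples have eight or fewer
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param x,y numeric vectors.
#' @return A `pislice_test` with the Mann-Whitney U statistic (number of
#'   (x, y) pairs with x > y).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) <= 8L && length(y) <= 8L
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact)
  )
  new_test_result(ht$statistic, ht$p.value, c(length(x), length(y)),
                  if (exact) "Mann-Whitney (exact)" else
                    "Mann-Whitney (normal approximation)")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-tailed, statistic D = sup |ECDF_x - ECDF_y|.
#'
#' @param x,y numeric vectors.
#' @return A `pislice_test`.
#' @export
ks_2samp <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  ht <- suppressWarnings(ks.test(x, y, alternative = "two.sided"))
  new_test_result(ht$statistic, ht$p.value, c(length(x), length(y)),
                  "two-sample Kolmogorov-Smirnov")
}

#' Kruskal-Wallis test (one-way ANOVA on ranks)
#'
#' @param groups a list of numeric vectors, one per group.
#' @return A `pislice_test`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("'groups' must be a list of at least two numeric vectors")
  if (any(lengths(groups) < 1L)) stop("empty group")
  ht <- kruskal.test(groups)
  new_test_result(ht$statistic, ht$p.value, lengths(groups),
                  "Kruskal-Wallis rank sum")
}

#' Welch-corrected two-sample t test
#'
#' @param x,y numeric vectors with at least two observations each.
#' @return A `pislice_test`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("variance-based tests need >= 2 observations per group")
  ht <- t.test(x, y, var.equal = FALSE)
  new_test_result(ht$statistic, ht$p.value, c(length(x), length(y)),
                  "Welch two-sample t")
}

#' One-sample two-tailed t test
#'
#' @param x numeric vector with at least two observations.
#' @param mu null-hypothesis mean.
#' @return A `pislice_test`.
#' @export
one_sample_t <- function(x, mu = 0) {
  if (length(x) < 2L)
    stop("variance-based tests need >= 2 observations")
  ht <- t.test(x, mu = mu)
  new_test_result(ht$statistic, ht$p.value, length(x), "one-sample t")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: q_i = min over j >= i of p_(j) * m / j.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
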