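#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR adjustment (with the usual monotonicity enforcement) over
#' one family of p-values; the caller defines the family.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param q Rejection threshold on the adjusted values (default 0.05).
#' @param method "BH" (Benjamini-Hochberg, default) or "BY"
#'   (Benjamini-Yekutieli).
#' @return List with `q` (adjusted p-values) and `reject` (logical).
#' @export
fdr_bh <- function(p, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("fdr_bh: empty input")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("fdr_bh: p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = method)
  list(q = adj, reject = adj <= q)
}

# shared zero-variance guard: infinite statistic reported as p -> 0
t_degenerate <- function(mean_diff, df) {
  list(statistic = sign(mean_diff) * Inf, df = df,
       p = if (mean_diff == 0) 1 else 0,
       degenerate = TRUE)
}

#' One-sample t-test
#'
#' Two-sided one-sample t-test of `values` against `mu`. Zero variance
#' with a non-zero mean difference yields an infinite statistic with
#' p = 0 and a `degenerate` flag instead of an error.
#'
#' @param values Numeric vector (n >= 2).
#' @param mu Null mean.
#' @return List with statistic, df, p (and `degenerate` when variance
#'   was zero).
#' @export
one_sample_t <- function(values, mu = 0) {
  if (length(values) < 2L || any(!is.finite(values)))
    stop("one_sample_t: need >= 2 finite values")
  if (stats::sd(values) == 0) {
    d <- mean(values) - mu
    if (d == 0)
      return(list(statistic = 0, df = length(values) - 1L, p = 1,
                  degenerate = TRUE))
    return(t_degenerate(d, length(values) - 1L))
  }
  tt <- stats::t.test(values, mu = mu)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Paired t-test
#'
#' @param a,b Numeric vectors of equal length (n >= 2).
#' @return List with statistic, df, p; see [one_sample_t()] for the
#'   zero-variance convention.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired_t: unequal lengths")
  one_sample_t(a - b, mu = 0)
}

#' One-way analysis of variance
#'
#' Fixed-effects one-way ANOVA assuming equal variances (the textbook
#' F = MS_between / MS_within with k - 1 and N - k degrees of freedom).
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2), or a
#'   data.frame with columns `value` and `group`.
#' @return List with statistic (F), df1, df2, p.
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  if (length(groups) < 2L) stop("one_way_anova: need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("one_way_anova: each group needs n >= 2")
  vals <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(vals))) stop("one_way_anova: non-finite values")
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (stats::var(vals) == 0)
    return(list(statistic = 0,
                df1 = length(groups) - 1L,
                df2 = length(vals) - length(groups), p = 1))
  ft <- stats::oneway.test(vals ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic),
       df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]),
       p = ft$p.value)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values Numeric vector (n >= 2).
#' @param n_iter Bootstrap iterations (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return Length-2 numeric vector (lower, upper).
#' @export
bootstrap_ci_mean <- function(values, n_iter = 1000, level = 0.95,
                              seed = NULL) {
  if (length(values) < 2L)
    stop("bootstrap_ci_mean: need >= 2 values")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  means <- vapply(seq_len(n_iter),
                  function(i) mean(values[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  a <- (1 - level) / 2
  unname(stats::quantile(means, c(a, 1 - a)))
}
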