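# Nonparametric group comparisons and DeLong AUC machinery. Midranks are
# used throughout, with tie-corrected variance terms; the Mann-Whitney
# normal approximation carries a continuity correction.

pcg_test_result <- function(statistic, p_value, method, n) {
  structure(list(statistic = statistic, p_value = p_value, method = method, n = n),
            class = "pcg_test")
}

#' @export
print.pcg_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Thin wrapper around the vetted [stats::shapiro.test()], used to justify
#' the nonparametric tests downstream. Requires `3 <= n <= 5000`; a constant
#' sample is rejected with an explicit error.
#'
#' @param values numeric sample.
#' @return a `pcg_test` result.
#' @export
shapiro_gate <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (length(unique(values)) == 1L) stop("constant sample: normality undefined")
  st <- stats::shapiro.test(values)
  pcg_test_result(unname(st$statistic), st$p.value, "Shapiro-Wilk", n)
}

#' Mann-Whitney U test
#'
#' Midrank U statistic for `x` against `y`. For at most 8 observations per
#' side and no ties the two-sided p-value is exact (complete enumeration of
#' the permutation distribution); otherwise the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @return a `pcg_test` result; `statistic` is U for `x`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L

  if (n1 <= 8L && n2 <= 8L && !has_ties) {
    # exact: U depends only on which ranks go to x
    combs <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(seq_len(n1 + n2)[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(u_all <= u), mean(u_all >= u))
    p <- min(p, 1)
    return(pcg_test_result(u, p, "Mann-Whitney U (exact)", c(n1, n2)))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(c(x, y))
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(pcg_test_result(u, 1, "Mann-Whitney U (normal approx)", c(n1, n2)))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(v)   # continuity correction
  p <- 2 * stats::pnorm(-abs(z))
  pcg_test_result(u, min(p, 1), "Mann-Whitney U (normal approx)", c(n1, n2))
}

#' Kruskal-Wallis H test
#'
#' Rank-based k-group comparison with tie correction; p-value from the
#' chi-square approximation with k - 1 degrees of freedom.
#'
#' @param groups list of at least two non-empty numeric vectors.
#' @return a `pcg_test` result.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) == 0L)) stop("empty group")
  all_v <- unlist(groups)
  n <- length(all_v)
  r <- rank(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) * sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  tie_tab <- table(all_v)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  h <- if (corr > 0) h / corr else 0
  p <- stats::pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
  pcg_test_result(h, p, "Kruskal-Wallis H", lengths(groups))
}

#' Rank-based AUC (Mann-Whitney identity)
#'
#' @param scores numeric classifier scores.
#' @param labels logical (or 0/1) vector, `TRUE` = positive class.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (!n1 || !n0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components via the fast midrank formulation.
# Returns list(auc, v10 (length n1), v01 (length n0)).
delong_components <- function(scores, labels) {
  labels <- as.logical(labels)
  xs <- scores[labels]; ys <- scores[!labels]
  n1 <- length(xs); n0 <- length(ys)
  r_all <- rank(c(xs, ys))
  v10 <- (r_all[seq_len(n1)] - rank(xs)) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - rank(ys)) / n1
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

#' DeLong comparison of two correlated AUCs
#'
#' Paired comparison of the AUCs of two score vectors evaluated on the same
#' labels, using the structural-components covariance estimate. Identical
#' score vectors are reported as exact equality (z = 0, p = 1).
#'
#' @param scores_a,scores_b classifier scores on the same cases.
#' @param labels logical (or 0/1) class labels.
#' @return a `pcg_test` result with extra fields `auc_a`, `auc_b`.
#' @export
delong_auc_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(labels) || length(scores_b) != length(labels))
    stop("scores and labels must have the same length")
  if (!any(labels) || all(labels)) stop("both classes must be present in labels")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  n1 <- length(ca$v10); n0 <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  res <- pcg_test_result(z, p, "DeLong AUC comparison", c(n1, n0))
  res$auc_a <- ca$auc
  res$auc_b <- cb$auc
  res
}

#' DeLong confidence interval for one AUC
#'
#' @param scores classifier scores.
#' @param labels logical (or 0/1) class labels.
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `lower`, `upper`, `se`.
#' @export
delong_auc_ci <- function(scores, labels, conf = 0.95) {
  comp <- delong_components(scores, as.logical(labels))
  se <- sqrt(stats::var(comp$v10) / length(comp$v10) +
             stats::var(comp$v01) / length(comp$v01))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc = comp$auc,
       lower = max(0, comp$auc - zq * se),
       upper = min(1, comp$auc + zq * se),
       se = se)
}
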