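#' Element-wise two-sample t-test map over network edges
#'
#' Runs an equal-variance Student's t-test at every unordered edge (i < j)
#' between two diagnostic groups of a (typically confound-adjusted) cohort,
#' mirrors t and p symmetrically into p x p maps, and marks edges passing the
#' Bonferroni threshold `0.05 / (p (p-1) / 2)`. Edges with zero pooled
#' variance get t = 0, p = 1 (with one warning).
#'
#' @param cohort A `cohort_tensor` (usually from [adjust_cohort()]).
#' @param group_a,group_b Labels of the two groups to compare.
#' @param alpha Family-wise level before correction (default 0.05).
#' @return List with `t_map`, `p_map`, `mask` (p x p), `threshold`, and
#'   `n_tests`.
#' @export
elementwise_ttest_map <- function(cohort, group_a, group_b, alpha = 0.05) {
  lab <- cohort$phenotypes$label
  ia <- which(lab == group_a); ib <- which(lab == group_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("need at least 2 subjects per group")
  }
  d <- dim(cohort$data)
  n <- d[1]; p <- d[2]
  flat <- matrix(cohort$data, nrow = n)
  cols <- t(matrix(seq_len(p * p), p, p))[lower.tri(matrix(0, p, p))]
  xa <- flat[ia, cols, drop = FALSE]
  xb <- flat[ib, cols, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2, stats::var); vb <- apply(xb, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  degen <- se == 0
  if (any(degen)) {
    warning(sum(degen), " edge(s) with zero pooled variance; p set to 1")
  }
  tval <- ifelse(degen, 0, (ma - mb) / ifelse(degen, 1, se))
  pval <- ifelse(degen, 1, 2 * stats::pt(-abs(tval), df = na + nb - 2))
  n_tests <- p * (p - 1) / 2
  threshold <- alpha / n_tests
  list(t_map = symmetric_from_vector(tval, p),
       p_map = symmetric_from_vector(pval, p) + diag(1, p),
       mask = symmetric_from_vector(pval < threshold, p) > 0,
       threshold = threshold, n_tests = n_tests)
}

#' Group comparison of global network measures
#'
#' Equal-variance Student's t-tests per measure (columns of the adjusted
#' metric table) between two groups, Bonferroni-corrected across the 5
#' measures (threshold 0.05/5 = 0.01); also returns -log10(p) for plotting
#' against the threshold line at 2.
#'
#' @param adjusted_metrics n x 5 matrix of (confound-adjusted) measures.
#' @param labels Label per subject (rows of `adjusted_metrics`).
#' @param group_a,group_b Labels to compare.
#' @param alpha Family-wise level (default 0.05).
#' @return List with `p_values`, `t_values`, `neg_log10_p`, `threshold`,
#'   `significant` (logical per measure).
#' @export
metric_group_tests <- function(adjusted_metrics, labels, group_a, group_b,
                               alpha = 0.05) {
  m <- as.matrix(adjusted_metrics)
  ia <- which(labels == group_a); ib <- which(labels == group_b)
  if (length(ia) < 2 || length(ib) < 2) stop("need >= 2 subjects per group")
  res <- apply(m, 2, function(col) {
    if (stats::sd(col[ia]) == 0 && stats::sd(col[ib]) == 0) {
      return(c(t = 0, p = 1))
    }
    tt <- stats::t.test(col[ia], col[ib], var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  threshold <- alpha / ncol(m)
  list(p_values = res["p", ], t_values = res["t", ],
       neg_log10_p = -log10(res["p", ]), threshold = threshold,
       significant = res["p", ] < threshold)
}

#' One-sided paired t-test comparing two methods' per-repeat performance
#'
#' Tests whether method A outperforms method B across paired evaluation
#' repeats (alternative A > B). Zero-variance differences use a declared
#' convention: p = 0 if the mean difference is positive, 1 if negative, 0.5 if
#' every difference is exactly zero (identical performance).
#'
#' @param perf_a,perf_b Equal-length numeric vectors (one entry per repeat).
#' @return One-sided p-value.
#' @export
compare_methods_ttest <- function(perf_a, perf_b) {
  if (length(perf_a) != length(perf_b)) stop("vectors must have equal length")
  if (length(perf_a) < 2) stop("need at least 2 repeats")
  d <- perf_a - perf_b
  if (stats::sd(d) == 0) {
    return(if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5)
  }
  stats::t.test(perf_a, perf_b, paired = TRUE,
                alternative = "greater")$p.value
}

#' McNemar's test on two classifiers' paired predictions
#'
#' Builds the discordance counts b (A correct, B wrong) and c (A wrong, B
#' correct); uses the exact two-sided binomial test when b + c < 25, otherwise
#' the chi-square test with continuity correction. b + c = 0 gives p = 1.
#'
#' @param preds_a,preds_b Predicted labels from the two classifiers.
#' @param truth True labels, aligned with both prediction vectors.
#' @return List with `p_value`, `b`, `c`, `method`.
#' @export
mcnemar_test <- function(preds_a, preds_b, truth) {
  if (length(preds_a) != length(truth) || length(preds_b) != length(truth)) {
    stop("prediction vectors must align with truth")
  }
  ok_a <- preds_a == truth
  ok_b <- preds_b == truth
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  n <- b + cc
  if (n == 0) {
    return(list(p_value = 1, b = b, c = cc, method = "none discordant"))
  }
  if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
    method <- "exact binomial"
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square with continuity correction"
  }
  list(p_value = p, b = b, c = cc, method = method)
}
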