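#' @title Diagnostic statistics for LSN cohorts
#' @name diagstats
#' @description Nonparametric group comparison (Kruskal-Wallis,
#'   Mann-Whitney, Wilcoxon signed-rank), measurement variability (CV),
#'   interobserver agreement (ICC(2,1)) and ROC-based diagnostic accuracy
#'   (AUC with DeLong interval, Youden cutoff, confusion-table metrics).
NULL

#' Kruskal-Wallis H test
#'
#' Rank-based H statistic with tie correction; p from the chi-square
#' approximation with k - 1 degrees of freedom. All-identical data yield
#' H = 0, p = 1 rather than an error.
#'
#' @param groups list of >= 3 numeric vectors, each of length >= 2.
#' @return list `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 3) stop_param("kruskal_wallis needs >= 3 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop_param("each group needs >= 2 values")
  }
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  if (length(unique(x)) == 1L) {
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L))
  }
  r <- rank(x)
  Rj <- tapply(r, g, sum)
  nj <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  df <- length(groups) - 1L
  list(statistic = H, p_value = stats::pchisq(H, df, lower.tail = FALSE), df = df)
}

#' Mann-Whitney U test (two-sided)
#'
#' `U` counts pairs where a value of `a` exceeds a value of `b` (ties count
#' one half). The p-value is exact (null permutation distribution) when
#' `length(a) + length(b) <= 12` and there are no ties, and otherwise uses
#' the normal approximation with tie and continuity corrections.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list `statistic` (U), `p_value`, `exact`.
#' @export
mann_whitney <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop_param("each sample needs >= 2 values")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(c(a, b)))
  exact <- (na + nb) <= 12 && !ties
  if (exact) {
    p <- min(1, 2 * min(stats::pwilcox(U, na, nb),
                        stats::pwilcox(U - 1, na, nb, lower.tail = FALSE)))
  } else {
    N <- na + nb
    tt <- table(c(a, b))
    mu <- na * nb / 2
    sigma2 <- na * nb / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(statistic = U, p_value = 1, exact = FALSE))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = U, p_value = p, exact = exact)
}

#' Wilcoxon signed-rank test (two-sided, paired)
#'
#' Zero differences are dropped. The reported statistic `W` is
#' `min(W+, W-)` (the smaller of the positive- and negative-rank sums).
#' Exact null distribution for n <= 15 without ties in |differences|;
#' normal approximation with tie and continuity corrections otherwise.
#' All-zero differences give p = 1.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return list `statistic` (W), `p_value`, `n_used`, `exact`.
#' @export
wilcoxon_signed <- function(a, b) {
  if (length(a) != length(b)) stop_param("a and b must be paired (equal length)")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1, n_used = 0L, exact = TRUE))
  if (n < 3) stop_param("need >= 3 non-zero paired differences")
  r <- rank(abs(d))
  Wplus <- sum(r[d > 0])
  Wminus <- sum(r[d < 0])
  W <- min(Wplus, Wminus)
  ties <- any(duplicated(abs(d)))
  exact <- n <= 15 && !ties
  if (exact) {
    p <- min(1, 2 * stats::psignrank(W, n))
  } else {
    tt <- table(abs(d))
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
    if (sigma2 <= 0) return(list(statistic = W, p_value = 1, n_used = n, exact = FALSE))
    z <- (W - mu + 0.5) / sqrt(sigma2) # W = min side, always below the mean
    p <- min(1, 2 * stats::pnorm(z))
  }
  list(statistic = W, p_value = p, n_used = as.integer(n), exact = exact)
}

#' Coefficient of variation
#'
#' `CV = sample SD / mean x 100` (percent).
#'
#' @param values numeric vector (length >= 2, non-zero mean).
#' @return percent CV.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop_param("CV needs >= 2 values")
  m <- mean(values)
  if (m == 0) stop_domain("CV undefined for zero mean")
  stats::sd(values) / m * 100
}

#' Reliability label for an ICC value
#'
#' Bands: poor (< 0.4), moderate (0.4 to < 0.6), good (0.6 to < 0.8),
#' excellent (0.8 to 1.0).
#'
#' @param icc numeric ICC.
#' @return character label.
#' @export
icc_label <- function(icc) {
  if (icc < 0.4) "poor" else if (icc < 0.6) "moderate" else if (icc < 0.8) "good" else "excellent"
}

#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single measure
#'
#' From the two-way ANOVA mean squares (rows = subjects, columns = raters):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with the
#' McGraw-Wong F-based 95% confidence interval and the F test of ICC = 0
#' (`F = MSR/MSE` on (n-1, (n-1)(k-1)) df).
#'
#' @param ratings numeric matrix, subjects x raters (>= 5 subjects, >= 2
#'   raters).
#' @param conf confidence level (default 0.95).
#' @return an `icc_result`: `icc`, `ci95`, `p_value`, `label`, mean squares.
#' @export
icc_agreement <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5) stop_param("ICC needs >= 5 subjects")
  if (k < 2) stop_param("ICC needs >= 2 raters")
  if (any(!is.finite(ratings))) stop_domain("ratings must be finite")
  grand <- mean(ratings)
  Si <- rowMeans(ratings); Mj <- colMeans(ratings)
  SSR <- k * sum((Si - grand)^2)
  SSC <- n * sum((Mj - grand)^2)
  SST <- sum((ratings - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR <= 0) stop_domain("ICC undefined: no between-subject variance")
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  alpha <- 1 - conf
  if (MSE <= 0) {
    # perfect agreement: the F-based interval degenerates
    lower <- upper <- icc
    p <- 0
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    p <- stats::pf(MSR / MSE, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  structure(list(icc = icc, ci95 = c(lower = lower, upper = upper),
                 p_value = p, label = icc_label(icc),
                 mean_squares = c(MSR = MSR, MSC = MSC, MSE = MSE),
                 n = n, k = k), class = "icc_result")
}

# DeLong standard error of the empirical AUC.
delong_se <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  V10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  V01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  s10 <- if (n1 > 1) stats::var(V10) else 0
  s01 <- if (n0 > 1) stats::var(V01) else 0
  sqrt(s10 / n1 + s01 / n0)
}

#' ROC analysis with DeLong interval and Youden cutoff
#'
#' Empirical ROC over all score thresholds (classification rule: positive if
#' `score > t`). The AUC is the trapezoidal area, identical to the normalized
#' Mann-Whitney statistic `U / (n1 n0)`. The 95% CI and the p-value against
#' AUC = 0.5 use the DeLong variance estimate. The reported cutoff is the
#' threshold maximizing Youden's J (ties broken toward the smallest
#' threshold), phrased as "positive when score greater than cutoff";
#' sensitivity/specificity/PPV/NPV at the cutoff are percentages.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1, logical, or two-level factor) with both
#'   classes present.
#' @return a `roc_result`: `auc`, `ci95`, `p_vs_half`, `cutoff`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `counts`, `curve`.
#' @export
roc_analysis <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop_param("scores and labels differ in length")
  if (length(unique(labels)) < 2) stop_domain("both classes must be present")
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  curve <- data.frame(threshold = c(-Inf, thr), sensitivity = c(1, sens),
                      specificity = c(0, spec))
  j <- sens + spec - 1
  best <- which.max(j) # which.max takes the first (smallest threshold) on ties
  cutoff <- thr[best]
  tp <- sum(pos > cutoff); fn <- n1 - tp
  tn <- sum(neg <= cutoff); fp <- n0 - tn
  cs <- confusion_stats(tp, fp, tn, fn)
  se <- delong_se(scores, labels)
  ci <- if (se > 0) c(auc - stats::qnorm(0.975) * se, auc + stats::qnorm(0.975) * se)
        else c(auc, auc)
  ci <- pmin(pmax(ci, 0), 1)
  p <- if (se > 0) 2 * stats::pnorm(-abs(auc - 0.5) / se) else as.numeric(auc == 0.5)
  structure(list(auc = auc, ci95 = c(lower = ci[1], upper = ci[2]),
                 p_vs_half = min(1, p), cutoff = cutoff,
                 sensitivity = cs$sensitivity, specificity = cs$specificity,
                 ppv = cs$ppv, npv = cs$npv,
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 curve = curve), class = "roc_result")
}

#' Confusion-table metrics in percent
#'
#' `sens = tp/(tp+fn)`, `spec = tn/(tn+fp)`, `ppv = tp/(tp+fp)`,
#' `npv = tn/(tn+fn)`, each x 100. A zero PPV/NPV denominator yields `NA`
#' (reported as missing, not an error).
#'
#' @param tp,fp,tn,fn non-negative integer counts; `tp+fn >= 1` and
#'   `tn+fp >= 1`.
#' @return list of the four percentages.
#' @export
confusion_stats <- function(tp, fp, tn, fn) {
  cnt <- c(tp, fp, tn, fn)
  if (any(cnt < 0) || any(cnt != round(cnt))) {
    stop_param("counts must be non-negative integers")
  }
  if (tp + fn < 1 || tn + fp < 1) stop_param("need tp+fn >= 1 and tn+fp >= 1")
  pct <- function(num, den) if (den >= 1) num / den * 100 else NA_real_
  list(sensitivity = pct(tp, tp + fn), specificity = pct(tn, tn + fp),
       ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn))
}

#' Aggregate histology component scores into a NAFLD activity score
#'
#' The NAS is the sum of the steatosis (0-3), lobular inflammation (0-3) and
#' ballooning (0-2) scores; the same rule applies to group means of the
#' components.
#'
#' @param steatosis,inflammation,ballooning component scores (or means).
#' @return summed NAS.
#' @export
nas_score <- function(steatosis, inflammation, ballooning) {
  steatosis + inflammation + ballooning
}
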