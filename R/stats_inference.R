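# Evaluation statistics: midrank ROC/AUC with DeLong variance and paired
# DeLong comparison (authored here; the remaining tests wrap the standard
# implementations in stats and survival behind a uniform surface).

as_binary_label <- function(label) {
  if (is.logical(label)) return(label)
  if (is.factor(label)) label <- as.character(label)
  if (is.numeric(label)) {
    if (!all(label %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(label == 1)
  }
  u <- sort(unique(label))
  if (length(u) > 2L) stop("labels must be binary")
  label == u[length(u)]  # alphabetically last level is the positive class
}

# DeLong structural components: V10 (one per positive), V01 (one per
# negative); mean of either is the midrank AUC.
delong_components <- function(score, pos) {
  x <- score[pos]; y <- score[!pos]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' ROC curve and midrank AUC
#'
#' The AUC is the Mann-Whitney midrank estimator: the fraction of
#' (positive, negative) pairs in which the positive sample scores higher,
#' counting ties as one half. The DeLong variance of the AUC is returned
#' alongside the ROC curve points, whose trapezoidal area equals the AUC.
#'
#' @param score numeric vector.
#' @param label binary labels (logical, 0/1, or two-level factor; the
#'   alphabetically last level is the positive class).
#' @return object of class `roc_result`: `auc`, `variance`, `n_pos`,
#'   `n_neg`, and `curve` (data.frame with `fpr`, `tpr`).
#' @export
roc_auc <- function(score, label) {
  pos <- as_binary_label(label)
  if (length(score) != length(pos)) stop("score and label lengths differ")
  if (anyNA(score) || anyNA(pos)) stop("missing values in score or label")
  if (!any(pos) || all(pos)) stop("both classes must be present")
  cmp <- delong_components(score, pos)
  v <- stats::var(cmp$v10) / cmp$m + stats::var(cmp$v01) / cmp$n
  # curve: one operating point per unique threshold, descending
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(score[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(score[!pos] >= t), 0)
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(auc = cmp$auc, variance = v, n_pos = cmp$m, n_neg = cmp$n,
                 curve = curve), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (DeLong SE %.4f), %d positives / %d negatives\n",
              x$auc, sqrt(x$variance), x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same samples using
#' DeLong's structural-components covariance and a two-sided normal
#' reference. Identical scores give z = 0, p = 1.
#'
#' @param score_a,score_b numeric vectors on the same samples.
#' @param label binary labels.
#' @return list: `auc_a`, `auc_b`, `z`, `p_value`, `var_diff`.
#' @export
delong_test <- function(score_a, score_b, label) {
  pos <- as_binary_label(label)
  if (length(score_a) != length(score_b) || length(score_a) != length(pos))
    stop("scores and labels must be paired (equal length)")
  if (sum(pos) < 2L || sum(!pos) < 2L)
    stop("DeLong test needs >= 2 samples in each class")
  ca <- delong_components(score_a, pos)
  cb <- delong_components(score_b, pos)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  s <- s10 / ca$m + s01 / ca$n
  var_diff <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  d <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, z = z, p_value = p,
       var_diff = var_diff)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass method: the sum of
#' hypergeometric probabilities of all tables (given the margins) no more
#' likely than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list: `odds_ratio` (conditional MLE), `p_value`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  ft <- stats::fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Rank tests for group comparisons of a continuous variable
#'
#' Two groups: Wilcoxon rank-sum with midrank tie correction and normal
#' approximation (no continuity correction). More than two groups:
#' Kruskal-Wallis by ranks with chi-square approximation.
#'
#' @param values numeric vector.
#' @param group grouping vector (>= 2 non-empty groups).
#' @return list: `test` ("wilcoxon" or "kruskal-wallis"), `statistic`,
#'   `p_value`.
#' @export
rank_tests <- function(values, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (length(values) != length(group)) stop("values and group lengths differ")
  if (nlevels(group) < 2L) stop("need >= 2 non-empty groups")
  if (nlevels(group) == 2L) {
    sp <- split(values, group)
    wt <- stats::wilcox.test(sp[[1]], sp[[2]], exact = FALSE, correct = FALSE)
    list(test = "wilcoxon", statistic = unname(wt$statistic),
         p_value = wt$p.value)
  } else {
    kt <- stats::kruskal.test(values, group)
    list(test = "kruskal-wallis", statistic = unname(kt$statistic),
         p_value = kt$p.value)
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, capped at 1.
#'
#' @param pvals numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Logistic regression by IRLS
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares,
#' convergence when the deviance change is below 1e-8) with Wald standard
#' errors and p-values. Complete or quasi-separation is reported through the
#' `separation` flag and a warning of class `tsescore_separation`.
#'
#' @param x design matrix (numeric; no intercept column needed).
#' @param y binary outcome.
#' @param add_intercept prepend an intercept column; default TRUE.
#' @return list: `coefficients` (data.frame: term, estimate, se, z, p_value),
#'   `converged`, `separation`, `loglik`.
#' @export
logistic_fit <- function(x, y, add_intercept = TRUE) {
  y <- as.numeric(as_binary_label(y))
  x <- as.matrix(x)
  if (ncol(x) > 0L && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (add_intercept) x <- cbind(`(Intercept)` = 1, x)
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank-deficient")
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100)))
  eta <- fit$linear.predictors
  sep <- !fit$converged || max(abs(eta)) > 20
  if (sep)
    warning(structure(class = c("tsescore_separation", "warning",
                                "condition"),
                      list(message = "possible complete/quasi-separation in logistic fit",
                           call = sys.call())))
  w <- fit$weights
  xtwx <- crossprod(x * sqrt(w))
  se <- sqrt(diag(solve(xtwx)))
  est <- fit$coefficients
  z <- est / se
  list(coefficients = data.frame(term = colnames(x), estimate = unname(est),
                                 se = unname(se), z = unname(z),
                                 p_value = unname(2 * stats::pnorm(-abs(z))),
                                 stringsAsFactors = FALSE),
       converged = fit$converged, separation = sep,
       loglik = -fit$deviance / 2)
}

# ---- survival ---------------------------------------------------------------

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return data.frame of class `km_fit`: `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_fit <- function(time, event) {
  check_surv(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, surv = sf$surv)
  class(out) <- c("km_fit", "data.frame")
  out
}

#' Log-rank test
#'
#' Observed-versus-expected comparison of survival curves across groups.
#'
#' @param time,event as in [km_fit()].
#' @param group grouping vector with >= 2 levels.
#' @return list: `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need >= 2 groups for the log-rank test")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with the Efron tie correction; Wald confidence
#' intervals and p-values per coefficient.
#'
#' @param time,event as in [km_fit()].
#' @param covariates data.frame (or numeric vector) of covariates.
#' @param conf_level confidence level for the hazard-ratio CI; default 0.95.
#' @return data.frame: `term`, `coef`, `hr`, `se`, `hr_lower`, `hr_upper`,
#'   `p_value`.
#' @export
cox_fit <- function(time, event, covariates, conf_level = 0.95) {
  check_surv(time, event)
  covariates <- as.data.frame(covariates)
  fit <- survival::coxph(survival::Surv(time, event) ~ .,
                         data = covariates, ties = "efron")
  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = names(est), coef = unname(est), hr = unname(exp(est)),
             se = unname(se),
             hr_lower = unname(exp(est - zq * se)),
             hr_upper = unname(exp(est + zq * se)),
             p_value = unname(2 * stats::pnorm(-abs(est / se))),
             stringsAsFactors = FALSE, row.names = NULL)
}

check_surv <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(time <= 0)) stop("survival times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) < 1) stop("need at least one event")
  invisible(NULL)
}
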