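# Heterogeneity, pleiotropy and robustness diagnostics for an MR fit.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j * (ratio_j - theta)^2)` over the per-SNP Wald ratios with
#' first-order inverse-variance weights. Against the IVW estimate the degrees
#' of freedom are `nsnp - 1`; against the Egger fit (`df = "egger"`) the
#' residuals are taken about the oriented Egger line and `df = nsnp - 2`
#' (Rucker's Q').
#'
#' @param instruments harmonized data.frame.
#' @param theta pooled causal estimate the deviations are measured against
#'   (defaults to the fixed-effect IVW estimate). Ignored when
#'   `df = "egger"`.
#' @param df `"ivw"` or `"egger"`.
#' @return list with `Q`, `df`, `p`.
#' @export
cochran_q <- function(instruments, theta = NULL, df = c("ivw", "egger")) {
  df <- match.arg(df)
  n <- nrow(instruments)
  if (df == "ivw") {
    if (n < 2L) stop(mr_error("degenerate", "Q requires at least 2 instruments"))
    if (is.null(theta)) theta <- mr_ivw(instruments)$beta
    r <- ratio_estimates(instruments)
    Q <- sum(r$w * (r$ratio - theta)^2)
    k <- n - 1L
  } else {
    if (n < 3L) stop(mr_error("degenerate", "Egger Q requires at least 3 instruments"))
    f <- .egger_fit(instruments)
    flip <- sign(instruments$beta_exp); flip[flip == 0] <- 1
    bx <- instruments$beta_exp * flip
    by <- instruments$beta_out * flip
    w <- 1 / instruments$se_out^2
    Q <- sum(w * (by - f$intercept - f$slope * bx)^2)
    k <- n - 2L
  }
  list(Q = Q, df = k, p = stats::pchisq(Q, k, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept row of the Egger regression: a nonzero intercept indicates
#' average directional pleiotropy across instruments. Two-sided t test with
#' `nsnp - 2` degrees of freedom.
#'
#' @param instruments harmonized data.frame with at least 3 rows.
#' @return list with `intercept`, `se`, `p`.
#' @export
egger_intercept_test <- function(instruments) {
  f <- .egger_fit(instruments)
  list(intercept = f$intercept, se = f$se_intercept, p = min(1, f$p_intercept))
}

#' Leave-one-out analysis
#'
#' Refits the chosen estimator after dropping each instrument in turn; each
#' row is flagged when the reduced estimate changes sign or crosses nominal
#' significance (`alpha`) relative to the full fit. A drop that leaves the
#' method inestimable is recorded as a failed row, not an error.
#'
#' @param instruments harmonized data.frame with at least 3 rows.
#' @param method estimator name, default `"ivw"`.
#' @param alpha nominal level for the significance-change flag, default 0.05.
#' @param ... passed to the estimator.
#' @return data.frame with one row per dropped SNP: `dropped`, `beta`, `se`,
#'   `pval`, `nsnp`, `sign_change`, `significance_change`, `failed`.
#' @export
leave_one_out <- function(instruments, method = "ivw", alpha = 0.05, ...) {
  n <- nrow(instruments)
  if (n < 3L)
    stop(mr_error("degenerate", "leave-one-out requires at least 3 instruments"))
  fit_one <- function(d) {
    est <- mr_estimate_all(d, methods = method, ...)
    if (length(est) == 0L) NULL else est[[1L]]
  }
  full <- fit_one(instruments)
  if (is.null(full))
    stop(mr_error("degenerate", sprintf("method %s not estimable on full set", method)))
  rows <- lapply(seq_len(n), function(i) {
    e <- fit_one(instruments[-i, , drop = FALSE])
    if (is.null(e))
      return(data.frame(dropped = instruments$snp[i], beta = NA_real_,
                        se = NA_real_, pval = NA_real_, nsnp = n - 1L,
                        sign_change = NA, significance_change = NA,
                        failed = TRUE, stringsAsFactors = FALSE))
    data.frame(dropped = instruments$snp[i], beta = e$beta, se = e$se,
               pval = e$pval, nsnp = e$nsnp,
               sign_change = sign(e$beta) != sign(full$beta),
               significance_change = (e$pval < alpha) != (full$pval < alpha),
               failed = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- full
  out
}

#' Funnel-plot coordinates and asymmetry check
#'
#' Per SNP, the Wald ratio (x) and its inverse delta-method standard error
#' (y, a measure of instrument strength). Funnel asymmetry is summarized as
#' the weighted Pearson correlation between ratio and precision (weights
#' `1/var`); a value near 0 indicates symmetry. With a single SNP the
#' asymmetry is reported as `NA` (not applicable).
#'
#' @param instruments harmonized data.frame with at least 1 row.
#' @return list with `data` (per-SNP `snp`, `ratio`, `precision`) and
#'   `asymmetry` (weighted correlation, `NA` if undefined).
#' @export
funnel_data <- function(instruments) {
  if (nrow(instruments) < 1L)
    stop(mr_error("degenerate", "funnel requires at least 1 instrument"))
  r <- ratio_estimates(instruments)
  d <- data.frame(snp = r$snp, ratio = r$ratio, precision = 1 / sqrt(r$var),
                  stringsAsFactors = FALSE)
  asym <- if (nrow(d) < 2L || stats::sd(d$ratio) == 0 ||
              stats::sd(d$precision) == 0) NA_real_
  else {
    w <- r$w / sum(r$w)
    mx <- sum(w * d$ratio); my <- sum(w * d$precision)
    sxy <- sum(w * (d$ratio - mx) * (d$precision - my))
    sxy / sqrt(sum(w * (d$ratio - mx)^2) * sum(w * (d$precision - my)^2))
  }
  list(data = d, asymmetry = asym)
}

#' Bonferroni-corrected per-test threshold
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests, `>= 1`.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 5) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Full sensitivity report for an instrument set
#'
#' Bundles Cochran's Q (IVW and Egger forms), the Egger intercept test,
#' leave-one-out, funnel coordinates and per-SNP F-statistics.
#'
#' @param instruments harmonized data.frame.
#' @param loo_method estimator used for leave-one-out, default `"ivw"`.
#' @param bonferroni_m number of methods for the corrected threshold.
#' @param alpha family-wise level.
#' @return list of class `sensitivity_report`.
#' @export
sensitivity_report <- function(instruments, loo_method = "ivw",
                               bonferroni_m = 5, alpha = 0.05) {
  n <- nrow(instruments)
  q_ivw <- if (n >= 2) cochran_q(instruments) else NULL
  q_egger <- if (n >= 3) cochran_q(instruments, df = "egger") else NULL
  intercept <- if (n >= 3) egger_intercept_test(instruments) else NULL
  loo <- if (n >= 3) leave_one_out(instruments, method = loo_method) else NULL
  structure(list(
    q_ivw = q_ivw, q_egger = q_egger, egger_intercept = intercept,
    loo = loo, funnel = funnel_data(instruments),
    f_stats = stats::setNames(
      f_statistic(instruments$beta_exp, instruments$se_exp), instruments$snp),
    bonferroni_alpha = bonferroni_threshold(alpha, bonferroni_m)),
    class = "sensitivity_report")
}
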