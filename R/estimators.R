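# The five causal-effect estimators, all operating on harmonized instruments
# (columns beta_exp, se_exp, beta_out, se_out).

.z975 <- stats::qnorm(0.975)

.mr_estimate <- function(method, beta, se, pval, nsnp, extra = list()) {
  structure(list(method = method, beta = beta, se = se, pval = pval,
                 or_value = exp(beta),
                 ci_low = beta - .z975 * se, ci_high = beta + .z975 * se,
                 nsnp = nsnp, extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (se %.4f), OR = %.3f [%.3f, %.3f], p = %.3g, nsnp = %d\n",
              x$method, x$beta, x$se, x$or_value, exp(x$ci_low),
              exp(x$ci_high), x$pval, x$nsnp))
  invisible(x)
}

#' Odds ratio from a log-odds effect
#' @param beta finite log-odds estimate.
#' @return `exp(beta)`.
#' @export
or_from_beta <- function(beta) {
  stopifnot(all(is.finite(beta)))
  exp(beta)
}

#' Per-SNP Wald ratio estimates
#'
#' `ratio = beta_out / beta_exp` with first-order delta-method variance
#' `se_out^2 / beta_exp^2` (ignoring exposure uncertainty) and
#' inverse-variance weight; the shared ingredient of the median and mode
#' estimators and of the diagnostics. `second_order = TRUE` adds the
#' `beta_out^2 se_exp^2 / beta_exp^4` term.
#'
#' @param instruments harmonized data.frame.
#' @param second_order include the exposure-uncertainty variance term.
#' @return data.frame with `snp`, `ratio`, `var`, `w`.
#' @export
ratio_estimates <- function(instruments, second_order = FALSE) {
  bx <- instruments$beta_exp; by <- instruments$beta_out
  sx <- instruments$se_exp;   sy <- instruments$se_out
  if (any(bx == 0)) {
    bad <- instruments$snp[bx == 0][1]
    stop(mr_error("degenerate", sprintf(
      "degenerate instrument %s: exposure beta is 0", bad)))
  }
  ratio <- by / bx
  var1 <- sy^2 / bx^2
  var <- if (second_order) var1 + by^2 * sx^2 / bx^4 else var1
  data.frame(snp = instruments$snp, ratio = ratio, var = var, w = 1 / var,
             stringsAsFactors = FALSE)
}

#' Wald ratio estimate from a single instrument
#'
#' @param instruments one-row harmonized data.frame.
#' @return an `mr_estimate` with `method = "wald_ratio"`.
#' @export
wald_ratio <- function(instruments) {
  stopifnot(nrow(instruments) == 1L)
  r <- ratio_estimates(instruments)
  se <- sqrt(r$var)
  .mr_estimate("wald_ratio", r$ratio, se,
               2 * stats::pnorm(-abs(r$ratio / se)), 1L)
}

#' Inverse-variance weighted estimate
#'
#' Fixed-effect pooled estimate
#' `theta = sum(by*bx/se_out^2) / sum(bx^2/se_out^2)` with
#' `se = (sum(bx^2/se_out^2))^(-1/2)`; equivalently weighted least squares of
#' the outcome effects on the exposure effects through the origin with
#' weights `1/se_out^2`. With `variant = "multiplicative"` the standard error
#' is inflated by the residual standard deviation, floored at 1
#' (multiplicative random effects), as popular MR toolkits default to.
#'
#' @param instruments harmonized data.frame with at least 2 rows (a single
#'   row delegates to [wald_ratio()]).
#' @param variant `"fixed"` (default) or `"multiplicative"`.
#' @return an `mr_estimate` with `method = "ivw"`.
#' @export
mr_ivw <- function(instruments, variant = c("fixed", "multiplicative")) {
  variant <- match.arg(variant)
  n <- nrow(instruments)
  if (n < 1L) stop(mr_error("degenerate", "ivw requires at least 1 instrument"))
  if (n == 1L) return(wald_ratio(instruments))
  bx <- instruments$beta_exp; by <- instruments$beta_out
  w <- 1 / instruments$se_out^2
  if (any(bx == 0 & w > 0)) {
    bad <- instruments$snp[bx == 0][1]
    stop(mr_error("degenerate", sprintf(
      "degenerate instrument %s: exposure beta is 0", bad)))
  }
  denom <- sum(bx^2 * w)
  theta <- sum(by * bx * w) / denom
  se <- sqrt(1 / denom)
  if (variant == "multiplicative") {
    sigma <- sqrt(sum(w * (by - theta * bx)^2) / (n - 1))
    se <- se * max(1, sigma)
  }
  z <- theta / se
  .mr_estimate("ivw", theta, se, 2 * stats::pnorm(-abs(z)), n,
               extra = list(variant = variant))
}

# Shared Egger fit: orient each SNP so beta_exp >= 0, weighted least squares
# with free intercept, multiplicative over-dispersion floor, t(n-2) p-values.
.egger_fit <- function(instruments) {
  n <- nrow(instruments)
  if (n < 3L)
    stop(mr_error("degenerate", "egger requires at least 3 instruments"))
  flip <- sign(instruments$beta_exp)
  flip[flip == 0] <- 1
  bx <- instruments$beta_exp * flip
  by <- instruments$beta_out * flip
  w <- 1 / instruments$se_out^2
  if (stats::var(bx) == 0 || all(bx == bx[1]))
    stop(mr_error("degenerate", "egger collinearity: no spread in exposure effects"))
  sw <- sum(w); mx <- sum(w * bx) / sw; my <- sum(w * by) / sw
  sxx <- sum(w * (bx - mx)^2)
  if (sxx <= 0)
    stop(mr_error("degenerate", "egger collinearity: no spread in exposure effects"))
  slope <- sum(w * (bx - mx) * (by - my)) / sxx
  intercept <- my - slope * mx
  resid <- by - intercept - slope * bx
  sigma <- sqrt(sum(w * resid^2) / (n - 2))
  infl <- max(1, sigma)
  se_slope <- infl / sqrt(sxx)
  se_int <- infl * sqrt(1 / sw + mx^2 / sxx)
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = n - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = n - 2)
  list(slope = slope, se_slope = se_slope, p_slope = p_slope,
       intercept = intercept, se_intercept = se_int, p_intercept = p_int,
       sigma = sigma, n = n)
}

#' MR-Egger regression estimate
#'
#' Weighted regression of (sign-oriented) outcome effects on exposure effects
#' with a free intercept: the slope is the causal estimate, the intercept the
#' average directional pleiotropy. Standard errors carry a multiplicative
#' over-dispersion floor (residual sd, not below 1); p-values use a t
#' distribution on `nsnp - 2` degrees of freedom.
#'
#' @param instruments harmonized data.frame with at least 3 rows.
#' @return an `mr_estimate` with `method = "egger"`; the intercept estimate,
#'   its se and p-value are in `$extra`.
#' @export
mr_egger <- function(instruments) {
  f <- .egger_fit(instruments)
  .mr_estimate("egger", f$slope, f$se_slope, f$p_slope, f$n,
               extra = list(intercept = f$intercept,
                            se_intercept = f$se_intercept,
                            p_intercept = f$p_intercept,
                            sigma = f$sigma))
}

# Weighted-median point estimate of ratios given weights (cumulative-weight
# interpolation at probability 0.5).
.weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- w[ord]
  if (sum(w) <= 0) stop(mr_error("degenerate", "total weight is zero"))
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap se: resample the per-SNP betas from normal(beta, se)
# and recompute the point statistic.
.bootstrap_se <- function(instruments, stat_fun, n_boot, seed) {
  n <- nrow(instruments)
  reps <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(n, instruments$beta_exp, instruments$se_exp)
      by <- stats::rnorm(n, instruments$beta_out, instruments$se_out)
      sim <- instruments
      sim$beta_exp <- bx; sim$beta_out <- by
      stat_fun(sim)
    }, numeric(1))
  })
  stats::sd(reps)
}

# Run an expression under a local RNG seed without disturbing the caller's
# RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Weighted-median estimate
#'
#' Ratios are sorted ascending; with cumulative standardized weight
#' `p_j = (S_j - w_j/2) / sum(w)` the estimate is the linear interpolation of
#' the ratio at `p = 0.5`. The standard error comes from a parametric
#' bootstrap (resampling per-SNP betas from their reported normal sampling
#' distributions).
#'
#' @param instruments harmonized data.frame with at least 2 rows.
#' @param n_boot bootstrap replicates for the se, default 1000.
#' @param seed integer seed for the bootstrap.
#' @return an `mr_estimate` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = 1) {
  if (nrow(instruments) < 2L)
    stop(mr_error("degenerate", "weighted median requires at least 2 instruments"))
  stopifnot(n_boot >= 1)
  r <- ratio_estimates(instruments)
  est <- .weighted_median_point(r$ratio, r$w)
  se <- .bootstrap_se(instruments, function(sim) {
    rr <- ratio_estimates(sim)
    .weighted_median_point(rr$ratio, rr$w)
  }, n_boot, seed)
  .mr_estimate("weighted_median", est, se,
               2 * stats::pnorm(-abs(est / se)), nrow(instruments))
}

# Mode point estimate: argmax over the ratio values of the weighted
# normal-kernel density with normal-reference bandwidth scaled by phi.
.mode_point <- function(ratio, w, phi) {
  s <- stats::sd(ratio)
  iqr <- stats::IQR(ratio) / 1.349
  spread <- min(s, iqr)
  if (!is.finite(spread) || spread == 0) {
    # all (or almost all) ratios identical: the mode is that common value
    return(ratio[which.max(w)])
  }
  h <- phi * 0.9 * spread * length(ratio)^(-1 / 5)
  dens <- vapply(ratio, function(x)
    sum(w * stats::dnorm((x - ratio) / h)), numeric(1))
  ratio[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' Clusters the per-SNP Wald ratios with a weighted normal-kernel density
#' (normal-reference bandwidth `phi * 0.9 * min(sd, IQR/1.349) * n^(-1/5)`)
#' and returns the ratio maximizing the density. `weighted = TRUE` weights
#' each SNP by the inverse variance of its ratio; otherwise weights are
#' equal. Standard error by parametric bootstrap.
#'
#' @param instruments harmonized data.frame with at least 3 rows.
#' @param weighted use inverse-variance weights (weighted mode) or equal
#'   weights (simple mode).
#' @param phi bandwidth multiplier, default 1.
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed integer seed.
#' @return an `mr_estimate` with `method = "weighted_mode"` or
#'   `"simple_mode"`.
#' @export
mr_mode <- function(instruments, weighted = TRUE, phi = 1, n_boot = 1000,
                    seed = 1) {
  if (nrow(instruments) < 3L)
    stop(mr_error("degenerate", "mode estimators require at least 3 instruments"))
  stopifnot(phi > 0, n_boot >= 1)
  r <- ratio_estimates(instruments)
  wts <- function(rr) if (weighted) rr$w else rep(1, nrow(rr))
  est <- .mode_point(r$ratio, wts(r), phi)
  se <- .bootstrap_se(instruments, function(sim) {
    rr <- ratio_estimates(sim)
    .mode_point(rr$ratio, wts(rr), phi)
  }, n_boot, seed)
  .mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
               est, se, 2 * stats::pnorm(-abs(est / se)),
               nrow(instruments), extra = list(phi = phi))
}

#' Run a set of MR estimators
#'
#' @param instruments harmonized data.frame.
#' @param methods subset of `c("ivw", "egger", "weighted_median",
#'   "simple_mode", "weighted_mode")`.
#' @param n_boot,seed bootstrap settings for median/mode standard errors.
#' @param ivw_variant `"fixed"` or `"multiplicative"`.
#' @return named list of `mr_estimate` objects; methods whose instrument
#'   minimum is not met are reported as condition messages in the
#'   `"failures"` attribute rather than aborting the others.
#' @export
mr_estimate_all <- function(instruments,
                            methods = c("ivw", "egger", "weighted_median",
                                        "simple_mode", "weighted_mode"),
                            n_boot = 1000, seed = 1,
                            ivw_variant = "fixed") {
  runners <- list(
    ivw = function() mr_ivw(instruments, variant = ivw_variant),
    egger = function() mr_egger(instruments),
    weighted_median = function() mr_weighted_median(instruments, n_boot, seed),
    simple_mode = function() mr_mode(instruments, FALSE, 1, n_boot, seed),
    weighted_mode = function() mr_mode(instruments, TRUE, 1, n_boot, seed))
  bad <- setdiff(methods, names(runners))
  if (length(bad))
    stop(mr_error("config", paste("unknown method(s):",
                                  paste(bad, collapse = ", "))))
  out <- list(); fails <- character(0)
  for (m in methods) {
    res <- tryCatch(runners[[m]](), mr_degenerate_error = function(e) e)
    if (inherits(res, "condition")) fails[m] <- conditionMessage(res)
    else out[[m]] <- res
  }
  attr(out, "failures") <- fails
  out
}

#' Estimates as a long-format table
#' @param estimates list of `mr_estimate` objects (e.g. from
#'   [mr_estimate_all()]).
#' @param exposure,outcome trait labels for the table.
#' @return data.frame with one row per method.
#' @export
estimates_table <- function(estimates, exposure = "exposure",
                            outcome = "outcome") {
  do.call(rbind, lapply(estimates, function(e)
    data.frame(exposure = exposure, outcome = outcome, method = e$method,
               nsnp = e$nsnp, beta = e$beta, se = e$se, pval = e$pval,
               or = e$or_value, ci_low = e$ci_low, ci_high = e$ci_high,
               stringsAsFactors = FALSE)))
}
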