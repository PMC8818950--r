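test_that("ivw matches the WLS-through-origin oracle on random instances", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(2:30, 1)
    inst <- make_inst(rnorm(n, 0, 0.2) + 0.01, rnorm(n, 0, 0.1),
                      runif(n, 0.01, 0.3))
    est <- mr_ivw(inst)
    fit <- lm(beta_out ~ 0 + beta_exp, data = inst,
              weights = 1 / inst$se_out^2)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
  }
})

test_that("ivw closed forms: single SNP, identical pair, variants", {
  one <- make_inst(0.1, 0.2, 0.05)
  est <- mr_ivw(one)
  expect_equal(est$method, "wald_ratio")
  expect_equal(est$beta, 2.0)
  expect_equal(est$se, 0.5)

  two <- make_inst(c(1, 1), c(0.5, 0.5), c(1, 1))
  est2 <- mr_ivw(two)
  expect_equal(est2$beta, 0.5)
  expect_equal(est2$se, 1 / sqrt(2))

  # multiplicative variant never shrinks the se; equals fixed when sigma <= 1
  expect_gte(mr_ivw(two, "multiplicative")$se, est2$se)

  expect_error(mr_ivw(make_inst(c(0, 1), c(1, 1), c(1, 1))),
               class = "mr_degenerate_error")
  expect_equal(mr_ivw(two)$or_value, exp(mr_ivw(two)$beta))
})

test_that("egger recovers an exact affine relation with zero residual", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  inst <- make_inst(bx, 0.3 + 0.8 * bx, c(0.05, 0.04, 0.06, 0.05))
  est <- mr_egger(inst)
  expect_equal(est$beta, 0.8, tolerance = 1e-10)
  expect_equal(est$extra$intercept, 0.3, tolerance = 1e-10)
  expect_equal(est$extra$sigma, 0, tolerance = 1e-8)

  # matches lm on oriented data
  set.seed(5)
  inst2 <- make_inst(rnorm(8, 0.2, 0.1), rnorm(8), runif(8, 0.02, 0.1))
  flip <- sign(inst2$beta_exp)
  fit <- lm(I(beta_out * flip) ~ I(beta_exp * flip), data = inst2,
            weights = 1 / inst2$se_out^2)
  expect_equal(mr_egger(inst2)$beta, unname(coef(fit)[2]), tolerance = 1e-10)

  expect_error(mr_egger(inst[1:2, ]), class = "mr_degenerate_error")
  expect_error(mr_egger(make_inst(rep(0.2, 4), rnorm(4), rep(0.1, 4))),
               class = "mr_degenerate_error")
})

test_that("egger separates directional pleiotropy from the causal slope", {
  # beta_y = theta*beta_x + alpha + noise, theta = 0, alpha = 0.1, InSIDE
  set.seed(77)
  n <- 50; reps <- 200
  res <- t(replicate(reps, {
    bx <- abs(rnorm(n, 0.3, 0.1)) + 0.05
    sy <- rep(0.05, n)
    by <- 0.1 + rnorm(n, 0, sy)
    inst <- make_inst(bx, by, sy)
    e <- mr_egger(inst)
    c(slope = e$beta, int = e$extra$intercept, ivw = mr_ivw(inst)$beta)
  }))
  expect_equal(mean(res[, "int"]), 0.1, tolerance = 0.02)
  expect_equal(mean(res[, "slope"]), 0, tolerance = 0.05)
  # IVW drifts under directional pleiotropy while egger does not
  expect_gt(abs(mean(res[, "ivw"])), 5 * abs(mean(res[, "slope"])))
})

test_that("weighted median matches the cumulative-weight oracle", {
  inst <- make_inst(c(1, 1, 1), c(1, 2, 10), c(1, 1, 1))
  est <- mr_weighted_median(inst, n_boot = 50, seed = 1)
  expect_equal(est$beta, 2)  # p2 = 0.5 exactly

  # all ratios equal -> that constant, any weights
  instc <- make_inst(c(1, 2, 4), c(3, 6, 12), c(0.5, 1, 2))
  expect_equal(mr_weighted_median(instc, n_boot = 50, seed = 1)$beta, 3)

  set.seed(202)
  for (i in 1:20) {
    n <- sample(2:15, 1)
    inst <- make_inst(runif(n, 0.1, 1), rnorm(n), runif(n, 0.1, 1))
    r <- ratio_estimates(inst)
    est <- mr_weighted_median(inst, n_boot = 2, seed = 1)
    expect_equal(est$beta, oracle_weighted_median(r$ratio, r$w),
                 tolerance = 1e-12)
    expect_gte(est$beta, min(r$ratio))
    expect_lte(est$beta, max(r$ratio))
  }
  # equal weights, odd n: sample median
  inst <- make_inst(rep(1, 5), c(5, 1, 3, 2, 4), rep(1, 5))
  expect_equal(mr_weighted_median(inst, n_boot = 2, seed = 1)$beta, 3)
})

test_that("mode estimators agree with the dense-grid density oracle", {
  inst <- make_inst(rep(1, 4), c(1.00, 1.02, 0.98, 3.0), rep(1, 4))
  est <- mr_mode(inst, weighted = FALSE, n_boot = 20, seed = 1)
  r <- ratio_estimates(inst)
  o <- oracle_mode(r$ratio, rep(1, 4))
  expect_lt(abs(est$beta - o), 0.05)
  expect_lt(abs(est$beta - 1), 0.1)   # majority cluster

  # weights pull the weighted mode into the heavy cluster
  inst2 <- make_inst(c(1, 1, 1), c(1.0, 1.05, 3.0),
                     sqrt(1 / c(10, 10, 0.1)))
  w_est <- mr_mode(inst2, weighted = TRUE, n_boot = 20, seed = 1)
  expect_gte(w_est$beta, 1.0)
  expect_lte(w_est$beta, 1.05)
  r2 <- ratio_estimates(inst2)
  expect_lt(abs(w_est$beta - oracle_mode(r2$ratio, r2$w)), 0.05)

  # all ratios identical: the common value, not an error
  inst3 <- make_inst(c(1, 2, 3), c(2, 4, 6), rep(1, 3))
  expect_equal(mr_mode(inst3, n_boot = 20, seed = 1)$beta, 2)
  expect_error(mr_mode(inst3[1:2, ]), class = "mr_degenerate_error")
})

test_that("every estimator is invariant under per-SNP joint sign flips", {
  set.seed(301)
  n <- 12
  inst <- make_inst(runif(n, 0.1, 0.5), rnorm(n, 0.2, 0.1),
                    runif(n, 0.05, 0.2))
  flip <- sample(c(-1, 1), n, replace = TRUE)
  inst2 <- inst
  inst2$beta_exp <- inst$beta_exp * flip
  inst2$beta_out <- inst$beta_out * flip
  for (f in list(function(d) mr_ivw(d)$beta,
                 function(d) mr_egger(d)$beta,
                 function(d) mr_weighted_median(d, n_boot = 2, seed = 1)$beta,
                 function(d) mr_mode(d, TRUE, n_boot = 2, seed = 1)$beta,
                 function(d) mr_mode(d, FALSE, n_boot = 2, seed = 1)$beta))
    expect_equal(f(inst), f(inst2), tolerance = 1e-10)
})

test_that("or_from_beta and the estimate container are consistent", {
  expect_equal(or_from_beta(0), 1)
  expect_equal(round(or_from_beta(1.074), 2), 2.93)
  expect_equal(round(or_from_beta(-0.053), 3), 0.948)
  est <- mr_ivw(make_inst(c(1, 1), c(0.5, 0.6), c(1, 1)))
  expect_lte(est$ci_low, est$beta)
  expect_gte(est$ci_high, est$beta)
})

test_that("mr_estimate_all isolates per-method failures", {
  inst <- make_inst(c(1, 1), c(0.5, 0.6), c(1, 1))  # too few for egger/modes
  res <- mr_estimate_all(inst, n_boot = 10, seed = 1)
  expect_setequal(names(res), c("ivw", "weighted_median"))
  expect_true("egger" %in% names(attr(res, "failures")))
  tab <- estimates_table(res)
  expect_equal(nrow(tab), 2)
})
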