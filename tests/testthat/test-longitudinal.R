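test_that("BH adjustment matches its definition on worked examples", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.5)), c(0.03, 0.03, 0.5))
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("BH adjustment agrees with the brute-force step-up oracle", {
  set.seed(11)
  for (r in 1:50) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_bruteforce(p))
  }
  # order invariance
  p <- runif(25)
  ord <- sample(25)
  expect_equal(bh_adjust(p)[ord], bh_adjust(p[ord]))
})

test_that("random-intercept fits reduce to OLS when subjects do not vary", {
  set.seed(21)
  n_sub <- 60
  sid <- rep(seq_len(n_sub), each = 3)
  X <- cbind(intercept = 1, time = rep(0:2, n_sub),
             age = rep(rnorm(n_sub, 40, 10), each = 3))
  y <- drop(X %*% c(2, 0.5, 0.01)) + rnorm(length(sid))  # sigma_u = 0
  fit <- fit_random_intercept(y, X, sid)
  ols <- coef(lm(y ~ 0 + X))
  expect_lt(max(abs(fit$estimates$estimate - ols)), 1e-4)
  expect_true(all(fit$varcomp >= 0))
})

test_that("random-intercept fits recover a planted slope with both variance components", {
  set.seed(22)
  ok <- 0
  for (r in 1:5) {
    n_sub <- 200
    sid <- rep(seq_len(n_sub), each = 3)
    u <- rep(rnorm(n_sub), each = 3)
    t <- rep(0:2, n_sub)
    y <- 1 + 0.5 * t + u + rnorm(length(sid))
    fit <- fit_random_intercept(y, cbind(intercept = 1, time = t), sid)
    est <- fit$estimates$estimate[fit$estimates$term == "time"]
    ok <- ok + (abs(est - 0.5) < 0.1)
    expect_gt(fit$varcomp["between_subject"], 0.3)
  }
  expect_gte(ok, 4)
})

test_that("degenerate and ill-posed mixed-model inputs are handled explicitly", {
  sid <- rep(1:10, each = 2)
  X <- cbind(intercept = 1, x = rnorm(20))
  fit <- fit_random_intercept(rep(0, 20), X, sid)
  expect_true(all(fit$estimates$estimate == 0))
  expect_equal(unname(fit$varcomp), c(0, 0))

  X_sing <- cbind(a = 1, b = 2)  # b = 2a
  X_sing <- X_sing[rep(1, 20), ]
  expect_error(fit_random_intercept(rnorm(20), X_sing, sid), "collinear")
})

test_that("REML criterion is locally optimal at the fitted variance ratio", {
  set.seed(23)
  sid <- rep(1:80, each = 3)
  y <- rep(rnorm(80), each = 3) + rnorm(240)
  fit <- fit_random_intercept(y, matrix(1, 240, 1,
                                        dimnames = list(NULL, "intercept")), sid)
  dev_fun <- lme4::lmer(y ~ 1 + (1 | sid),
                        data = data.frame(y = y, sid = factor(sid)),
                        REML = TRUE, devFunOnly = TRUE)
  theta_hat <- sqrt(fit$varcomp[["between_subject"]] / fit$varcomp[["residual"]])
  for (f in c(0.9, 1.1)) {
    expect_gte(dev_fun(theta_hat * f), dev_fun(theta_hat) - 1e-8)
  }
})

test_that("exposure scan recovers a planted week-8 depletion as the top hit", {
  gt <- make_precision_matrix(p = 10, seed = 31)
  gt$exposure_effects[3, "week8"] <- -1  # serotonin-like post-treatment drop
  co <- simulate_cohort(200, gt, seed = 32)
  pp <- preprocess_cohort(co)
  tab <- exposure_scan(pp$processed, co$clinical, week = 8, ratios = NULL)
  top <- tab$feature_id[which.min(tab$q_value)]
  expect_equal(top, co$metabolite_ids[3])
  expect_lt(tab$q_value[tab$feature_id == top], 0.10)
  expect_lt(tab$effect[tab$feature_id == top], 0)
  expect_error(exposure_scan(pp$processed, co$clinical, week = 6), "week")
})

test_that("exposure scan is invariant to a consistent subject permutation", {
  gt <- make_precision_matrix(p = 6, seed = 33)
  co <- simulate_cohort(80, gt, seed = 34)
  pp <- preprocess_cohort(co)
  tab1 <- exposure_scan(pp$processed, co$clinical, week = 4, ratios = NULL)
  perm <- sample(80)
  proc_perm <- lapply(pp$processed, function(pm) {
    pm$values <- pm$values[perm, ]; pm$log2_values <- pm$log2_values[perm, ]; pm
  })
  tab2 <- exposure_scan(proc_perm, co$clinical[perm, ], week = 4, ratios = NULL)
  expect_equal(tab1$p_value, tab2$p_value, tolerance = 1e-8)
})

test_that("ratio features join the scan with the serotonin turnover pairs", {
  gt <- make_precision_matrix(p = 31, seed = 35)
  co <- simulate_cohort(120, gt, seed = 36)
  pp <- preprocess_cohort(co)
  tab <- exposure_scan(pp$processed, co$clinical, week = 8)
  expect_true(all(default_ratios()$ratio_id %in% tab$feature_id))
  expect_equal(nrow(tab), 31 + nrow(default_ratios()))
})

test_that("symptom scan detects a generated HRSD coupling and flags degenerate input", {
  gt <- make_precision_matrix(p = 8, seed = 41)
  co <- simulate_cohort(200, gt,
                        symptom_coupling = list(metabolite = 2, coef = 0.5),
                        seed = 42)
  pp <- preprocess_cohort(co)
  tab <- symptom_association_scan(pp$processed, co$clinical, ratios = NULL)
  row <- tab[tab$feature_id == co$metabolite_ids[2], ]
  expect_gt(row$effect, 0)
  expect_lt(row$q_value, 0.10)

  cl_const <- co$clinical
  cl_const$hrsd_t0 <- cl_const$hrsd_t4 <- cl_const$hrsd_t8 <- 17L
  expect_warning(tab2 <- symptom_association_scan(pp$processed, cl_const,
                                                  ratios = NULL), "constant")
  expect_true(all(is.na(tab2$effect)))
})

test_that("two-step time-course flags a responder-only trajectory divergence", {
  set.seed(51)
  gt <- make_precision_matrix(p = 8, seed = 51)
  co <- simulate_cohort(160, gt, response_rate = 0.5, seed = 52)
  # responder-only week-8 rise of 1 sd on metabolite 5
  resp <- co$clinical$responder
  co$abundances$t8[resp, 5] <- co$abundances$t8[resp, 5] * 2  # +1 on log2
  pp <- preprocess_cohort(co)
  res <- timecourse_two_step(pp$processed, resp)
  tab <- res$table
  expect_true(tab$selected[5])
  terms5 <- res$group_difference_terms[[co$metabolite_ids[5]]]
  expect_true(any(grepl("group_time", terms5$term) & terms5$p_value < 0.05))
  expect_error(timecourse_two_step(pp$processed, resp, degree = 3), "degree")
})

test_that("time-course selection stays quiet on constant input", {
  gt <- make_precision_matrix(p = 4, seed = 53)
  co <- simulate_cohort(40, gt, response_rate = 0.5, seed = 54)
  pp <- preprocess_cohort(co)
  for (tp in names(pp$processed)) pp$processed[[tp]]$values[, 2] <- 0
  res <- timecourse_two_step(pp$processed, co$clinical$responder)
  expect_true(is.na(res$table$global_fit_p[2]))
  expect_false(res$table$selected[2])
})
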