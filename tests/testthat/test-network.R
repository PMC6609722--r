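test_that("sample correlations match the textbook formula", {
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  x <- cbind(x, d = x[, 1])          # duplicate column: r = 1
  S <- sample_correlation(x)
  expect_equal(S["a", "d"], 1)
  # orthogonal contrasts on 3 samples
  y <- cbind(u = c(1, -1, 0), v = c(1, 1, -2))
  expect_equal(sample_correlation(y)["u", "v"], 0)
  # direct-formula oracle
  manual <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_lt(abs(S["a", "b"] - manual(x[, "a"], x[, "b"])), 1e-12)
  x_const <- x; x_const[, 2] <- 5
  expect_error(sample_correlation(x_const), "b")
})

test_that("graphical lasso hits its boundary solutions", {
  set.seed(2)
  z <- matrix(rnorm(400 * 6), 400, 6)
  x <- z %*% diag(6) + 0.3 * z[, c(2:6, 1)]
  S <- cor(x)
  # full shrinkage: diagonal precision
  lam_max <- max(abs(S[upper.tri(S)]))
  f_big <- graphical_lasso(S, lam_max)
  expect_true(all(f_big$theta[!diag(6)] == 0))
  expect_equal(diag(f_big$theta), 1 / diag(S))
  # no shrinkage: matrix inverse
  f0 <- graphical_lasso(S, 0, tol = 1e-9, max_iter = 500)
  expect_lt(max(abs(f0$theta - solve(S))), 1e-6)
})

test_that("graphical lasso solutions satisfy the KKT conditions", {
  set.seed(3)
  for (r in 1:10) {
    p <- sample(4:15, 1)
    x <- matrix(rnorm(300 * p), 300, p)
    x <- x + x[, sample(p)] * 0.5
    S <- cor(x)
    lam <- runif(1, 0.02, 0.3)
    f <- graphical_lasso(S, lam, tol = 1e-9, max_iter = 500)
    G <- solve(f$theta) - S
    off <- !diag(p)
    nz <- abs(f$theta) > 1e-8 & off
    if (any(nz)) {
      expect_lt(max(abs(G[nz] - lam * sign(f$theta[nz]))), 1e-5)
    }
    if (any(off & !nz)) {
      expect_lte(max(abs(G[off & !nz])), lam + 1e-5)
    }
    expect_lt(max(abs(diag(G))), 1e-6)  # unpenalised diagonal
    expect_gt(min(eigen(f$theta, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("partial correlations derive correctly from the precision matrix", {
  expect_equal(precision_to_partial_correlations(diag(3)), matrix(0, 3, 3))
  theta <- matrix(c(2, -1, -1, 2), 2, 2)
  w <- precision_to_partial_correlations(theta)
  expect_equal(w[1, 2], 0.5)
  # two-variable case: partial equals marginal correlation
  expect_equal(w[1, 2], cov2cor(solve(theta))[1, 2])
  set.seed(4)
  a <- crossprod(matrix(rnorm(49), 7)) + diag(7)
  w2 <- precision_to_partial_correlations(a)
  expect_true(all(abs(w2[upper.tri(w2)]) < 1))
  expect_error(precision_to_partial_correlations(-diag(2)), "positive")
})

test_that("EBIC selection is sparse under independence and respects its knobs", {
  set.seed(5)
  spurious <- sapply(1:5, function(r) {
    x <- matrix(rnorm(500 * 10), 500, 10)
    net <- ebic_select(x)
    sum(net$weights[upper.tri(net$weights)] != 0)
  })
  expect_gte(mean(spurious <= 2), 0.8)

  gt <- make_precision_matrix(p = 10, within_density = 0.4,
                              edge_strength = 0.3, seed = 6)
  co <- simulate_cohort(400, gt, seed = 6)
  x <- preprocess_cohort(co)$processed$t0$values
  # gamma = 0 (plain BIC) is never sparser than gamma = 0.5
  e0 <- sum(ebic_select(x, gamma = 0)$weights != 0)
  e5 <- sum(ebic_select(x, gamma = 0.5)$weights != 0)
  expect_gte(e0, e5)
  # a single-lambda grid returns that lambda
  net1 <- ebic_select(x, lambda_grid = 0.17)
  expect_equal(net1$lambda, 0.17)
  # edge count is non-increasing in lambda along the path
  path <- ebic_select(x)$ebic_path
  expect_true(all(diff(path$n_edges) >= 0))  # grid is descending in lambda
})

test_that("weights carry the sparsity pattern of the estimated precision", {
  gt <- make_precision_matrix(p = 12, within_density = 0.4, seed = 7)
  co <- simulate_cohort(300, gt, seed = 7)
  net <- ebic_select(preprocess_cohort(co)$processed$t0$values)
  expect_equal(net$weights, t(net$weights))
  expect_true(all(diag(net$weights) == 0))
  expect_true(all(abs(net$weights) <= 1))
  expect_identical(net$weights != 0,
                   abs(net$theta) > 1e-8 & !diag(nrow(net$theta)))
})

test_that("bootstrap aggregation tracks edge stability", {
  gt <- make_precision_matrix(p = 8, within_density = 0, seed = 8)
  gt$differential_edges <- NULL
  gt$precision[1, 2] <- gt$precision[2, 1] <- -0.45  # one strong edge
  diag(gt$precision) <- pmax(1, 1.1 * (rowSums(abs(gt$precision)) -
                                         diag(gt$precision)))
  co <- simulate_cohort(500, gt, seed = 8)
  x <- preprocess_cohort(co)$processed$t0$values
  bs <- bootstrap_network(x, n_boot = 30, nlambda = 30, seed = 9)
  expect_gte(bs$inclusion_frequency[1, 2], 0.9)
  expect_gt(abs(bs$median_weights[1, 2]), 0.2)
  # null edges are rarely and weakly included
  null_ut <- upper.tri(bs$median_weights)
  null_ut[1, 2] <- FALSE
  expect_lte(max(bs$inclusion_frequency[null_ut]), 0.5)
  expect_true(all(bs$median_weights[bs$inclusion_frequency == 0] == 0))
  # a single resample is its own median
  bs1 <- bootstrap_network(x, n_boot = 1, nlambda = 30, seed = 10)
  expect_true(all(bs1$inclusion_frequency %in% c(0, 1)))
  expect_identical(bs1$median_weights != 0, bs1$inclusion_frequency == 1)
})

test_that("walktrap resolves planted structure and degenerate graphs", {
  # two 4-cliques: exactly the two blocks
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 0.5; w[5:8, 5:8] <- 0.5; diag(w) <- 0
  part <- walktrap_communities(w)
  expect_equal(length(unique(part$labels)), 2)
  expect_equal(adjusted_rand(part$labels, rep(1:2, each = 4)), 1)
  # complete graph: a single community
  k <- matrix(0.4, 6, 6); diag(k) <- 0
  expect_equal(length(unique(walktrap_communities(k)$labels)), 1)
  # empty graph: all singletons, modularity 0
  e <- walktrap_communities(matrix(0, 5, 5))
  expect_equal(unname(e$labels), 1:5)
  expect_equal(e$modularity, 0)
  # isolated node: same partition plus a singleton
  w9 <- rbind(cbind(w, 0), 0)
  part9 <- walktrap_communities(w9)
  expect_equal(adjusted_rand(part9$labels[1:8], part$labels), 1)
  expect_equal(sum(table(part9$labels) == 1), 1)
})

test_that("identical groups give a zero comparison statistic with p = 1", {
  set.seed(11)
  x <- matrix(rnorm(40 * 6), 40, 6)
  x2 <- rbind(x, x)
  outc <- rep(c(0, 1), each = 40)
  cmp <- compare_networks(x2, outc, n_perm = 30, seed = 12, nlambda = 20)
  expect_equal(cmp$stat_structure, 0)
  expect_equal(cmp$stat_global_strength, 0)
  expect_equal(cmp$p_structure, 1)
  expect_error(compare_networks(x2, rep(1, 80), n_perm = 10), "distinct")
})

test_that("network comparison is symmetric in the group labelling", {
  gt <- make_precision_matrix(p = 6, seed = 13)
  co <- simulate_cohort(60, gt, seed = 13)
  x <- preprocess_cohort(co)$processed$t0$values
  outc <- rep(c(0, 1), 30)
  c1 <- compare_networks(x, outc, n_perm = 50, seed = 14, nlambda = 20)
  c2 <- compare_networks(x, 1 - outc, n_perm = 50, seed = 14, nlambda = 20)
  expect_equal(c1$stat_structure, c2$stat_structure)
  expect_equal(c1$stat_global_strength, c2$stat_global_strength)
  expect_equal(c1$p_structure, c2$p_structure)
  expect_equal(c1$p_global, c2$p_global)
})

test_that("per-edge differences equal the observed group difference", {
  gt <- make_precision_matrix(p = 6, within_density = 0.6, seed = 15)
  co <- simulate_cohort(80, gt, seed = 15)
  x <- preprocess_cohort(co)$processed$t0$values
  cmp <- compare_networks(x, rnorm(80), n_perm = 20, seed = 16, nlambda = 20)
  if (nrow(cmp$per_edge)) {
    d <- cmp$weights_low - cmp$weights_high
    expect_equal(cmp$per_edge$diff,
                 d[cbind(cmp$per_edge$i, cmp$per_edge$j)])
    expect_true(all(cmp$per_edge$p_raw > 0 & cmp$per_edge$p_raw <= 1))
  }
})

test_that("the outcome can enter the network as an explicit node", {
  gt <- make_precision_matrix(p = 5, seed = 17)
  co <- simulate_cohort(120, gt, seed = 17)
  x <- preprocess_cohort(co)$processed$t8$values
  cmp <- compare_networks(x, co$clinical$hrsd_t8, n_perm = 10, seed = 18,
                          nlambda = 20, include_outcome_node = TRUE)
  expect_equal(nrow(cmp$weights_low), 6)
  expect_true("HRSD" %in% colnames(cmp$weights_low))
})

test_that("interaction validation flags planted moderation only", {
  set.seed(19)
  n <- 300
  grp <- rep(0:1, each = n / 2)
  met_b <- rnorm(n)
  met_a <- met_b * grp + rnorm(n, 0, 0.5)
  v <- validate_interaction(met_a, met_b, grp)
  expect_lt(v$p_value, 1e-6)
  expect_warning(v0 <- validate_interaction(met_a, met_b, rep(1, n)),
                 "constant")
  expect_true(is.na(v0$coefficient))
  # independent inputs: moderate t statistics in most replicates
  tstats <- replicate(20, {
    a <- rnorm(100); b <- rnorm(100); o <- rnorm(100)
    abs(validate_interaction(a, b, o)$coefficient /
          validate_interaction(a, b, o)$se)
  })
  expect_gte(mean(tstats < 2.5), 0.9)
})
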