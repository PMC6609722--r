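#' Pearson sample correlation matrix
#'
#' @param x Numeric data matrix (subjects x metabolites, complete, n >= 3)
#'   or a `processed_matrix`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(x) {
  if (inherits(x, "processed_matrix")) x <- x$values
  stopifnot(is.matrix(x), nrow(x) >= 3)
  if (anyNA(x)) stop("missing values not allowed; impute first")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  cor(x)
}

#' Graphical lasso
#'
#' L1-penalised maximum-likelihood estimation of a sparse precision matrix:
#' maximises `log det(Theta) - tr(S Theta) - lambda * sum_{i!=j} |Theta_ij|`
#' by blockwise coordinate descent. With `lambda = 0` on a well-conditioned
#' `S` the solution equals the matrix inverse; with
#' `lambda >= max |offdiag(S)|` it is diagonal.
#'
#' @param S Symmetric correlation (or covariance) matrix.
#' @param lambda Penalty, >= 0.
#' @param tol Convergence tolerance on the working covariance update.
#' @param max_iter Maximum outer sweeps.
#' @return List with `theta` (precision estimate, symmetric positive
#'   definite), `w` (estimated covariance `theta^{-1}` at convergence),
#'   `lambda`, `converged`, `gap` (duality-gap proxy).
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-7, max_iter = 200) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S), lambda >= 0)
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  fit <- .glasso_path_cpp(S, lambda, tol, as.integer(max_iter))
  if (!fit$converged[1]) {
    stop(sprintf("graphical lasso did not converge in %d iterations (duality gap %.3e)",
                 max_iter, fit$gap[1]))
  }
  theta <- fit$theta[[1]]
  dimnames(theta) <- dimnames(S)
  list(theta = theta, w = fit$w[[1]], lambda = lambda,
       converged = TRUE, gap = fit$gap[1])
}

#' Precision matrix to partial correlations
#'
#' `w_ij = -theta_ij / sqrt(theta_ii * theta_jj)` off the diagonal, zero on
#' it. For a positive-definite precision all `|w_ij| < 1`.
#'
#' @param theta Symmetric precision matrix with positive diagonal.
#' @return Partial-correlation weight matrix.
#' @export
precision_to_partial_correlations <- function(theta) {
  stopifnot(is.matrix(theta), nrow(theta) == ncol(theta))
  d <- diag(theta)
  if (any(d <= 0)) stop("precision diagonal must be positive")
  w <- -theta / sqrt(outer(d, d))
  diag(w) <- 0
  w
}

# Default penalty grid: nlambda log-spaced values from lambda_max (smallest
# penalty giving an empty graph) down to lambda_min_ratio * lambda_max.
lambda_grid_default <- function(S, nlambda = 100, lambda_min_ratio = 0.01) {
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax <= 0) lmax <- 0.1
  exp(seq(log(lmax), log(lambda_min_ratio * lmax), length.out = nlambda))
}

ebic_score <- function(theta, S, n, gamma, refit = TRUE, edge_tol = 1e-8) {
  p <- nrow(theta)
  supp <- abs(theta) > edge_tol
  E <- sum(supp[upper.tri(supp)])
  if (refit) {
    # score the candidate support at its restricted (unpenalised) MLE,
    # removing the l1 shrinkage bias from the model comparison
    diag(supp) <- TRUE
    theta <- .glasso_support_mle_cpp(S, supp * 1L, 1e-7, 200L)$theta
  }
  ld <- determinant(theta, logarithm = TRUE)$modulus
  loglik <- (n / 2) * (as.numeric(ld) - sum(S * theta))
  c(ebic = -2 * loglik + E * log(n) + 4 * gamma * E * log(p), n_edges = E)
}

#' EBIC-selected partial-correlation network
#'
#' Fits the graphical lasso along a decreasing penalty path (warm-started)
#' and picks the penalty minimising the Extended Bayesian Information
#' Criterion `EBIC = -2 l(Theta) + E log(n) + 4 gamma E log(p)`, where `E`
#' counts nonzero upper-diagonal precision entries; ties break toward the
#' larger (sparser) penalty.
#'
#' @param x Data matrix (subjects x metabolites) or `processed_matrix`.
#' @param lambda_grid Optional positive, sorted penalty grid; defaults to
#'   `nlambda` log-spaced values from `lambda_max` down to
#'   `lambda_min_ratio * lambda_max`.
#' @param gamma EBIC hyperparameter (default 0.5; 0 recovers plain BIC).
#' @param nlambda,lambda_min_ratio Grid shape when `lambda_grid` is NULL.
#' @param refit Score each candidate support at its restricted
#'   (unpenalised) maximum likelihood, as in the EBIC covariance-selection
#'   formulation, and report the selected support's restricted-MLE partial
#'   correlations (relaxed graphical lasso; default TRUE). FALSE scores
#'   and reports the penalised estimate itself.
#' @param tol,max_iter Passed to the graphical-lasso solver.
#' @return A `pcn` object: list with `weights` (partial correlations, zero
#'   diagonal), `theta`, `lambda`, `ebic`, `ebic_path` (data frame over the
#'   grid), `node_labels`, `sample_size`, `gamma`.
#' @export
ebic_select <- function(x, lambda_grid = NULL, gamma = 0.5, nlambda = 100,
                        lambda_min_ratio = 0.01, refit = TRUE,
                        tol = 1e-7, max_iter = 200) {
  if (inherits(x, "processed_matrix")) x <- x$values
  S <- sample_correlation(x)
  n <- nrow(x)
  if (is.null(lambda_grid)) {
    lambda_grid <- lambda_grid_default(S, nlambda, lambda_min_ratio)
  }
  stopifnot(all(lambda_grid > 0))
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  fit <- .glasso_path_cpp(S, lambda_grid, tol, as.integer(max_iter))
  # identical supports share one score: evaluate each support once
  scores <- matrix(NA_real_, length(lambda_grid), 2,
                   dimnames = list(NULL, c("ebic", "n_edges")))
  prev_key <- NULL
  for (l in seq_along(lambda_grid)) {
    key <- which(abs(fit$theta[[l]][upper.tri(S)]) > 1e-8)
    if (!is.null(prev_key) && identical(key, prev_key) && refit) {
      scores[l, ] <- scores[l - 1, ]
    } else {
      scores[l, ] <- ebic_score(fit$theta[[l]], S, n, gamma, refit = refit)
    }
    prev_key <- key
  }
  path <- data.frame(lambda = lambda_grid, ebic = scores[, "ebic"],
                     n_edges = scores[, "n_edges"],
                     converged = fit$converged)
  # ties toward larger lambda: grid is descending, pick the first minimum
  best <- which(path$ebic <= min(path$ebic) + 1e-9)[1]
  theta <- fit$theta[[best]]
  if (refit) {
    # report the support-restricted MLE (relaxed graphical lasso): the
    # sparsity pattern is the EBIC-selected glasso support, but the edge
    # weights are free of the uneven l1 shrinkage of the penalised fit
    supp <- abs(theta) > 1e-8
    diag(supp) <- TRUE
    theta <- .glasso_support_mle_cpp(S, supp * 1L, tol, as.integer(max_iter))$theta
    theta[!supp] <- 0
  }
  dimnames(theta) <- dimnames(S)
  w <- precision_to_partial_correlations(theta)
  w[abs(w) < 1e-10] <- 0
  structure(list(weights = w, theta = theta, lambda = lambda_grid[best],
                 ebic = path$ebic[best], ebic_path = path,
                 node_labels = colnames(x) %||% paste0("V", seq_len(ncol(x))),
                 sample_size = n, gamma = gamma),
            class = "pcn")
}

#' Bootstrap-aggregated network
#'
#' Resamples subjects with replacement, re-runs EBIC selection per resample
#' (or refits at the fixed original penalty with `fix_lambda = TRUE`) and
#' summarises edges by their elementwise median weight and inclusion
#' frequency. Resamples that produce a zero-variance column are redrawn and
#' counted.
#'
#' @param x Data matrix or `processed_matrix`.
#' @param n_boot Number of bootstrap resamples (the conventional choice is
#'   1000).
#' @param seed Integer seed.
#' @param fix_lambda Reuse the penalty selected on the full data instead of
#'   re-selecting per resample (default FALSE).
#' @inheritParams ebic_select
#' @return A `bootstrap_summary`: list with `median_weights`,
#'   `inclusion_frequency`, `n_boot`, `n_redrawn`, `node_labels`.
#' @export
bootstrap_network <- function(x, n_boot = 1000, lambda_grid = NULL,
                              gamma = 0.5, nlambda = 100,
                              lambda_min_ratio = 0.01, seed = 1,
                              fix_lambda = FALSE) {
  if (inherits(x, "processed_matrix")) x <- x$values
  stopifnot(n_boot >= 1)
  set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  fixed_lambda <- NULL
  if (fix_lambda) {
    fixed_lambda <- ebic_select(x, lambda_grid, gamma, nlambda,
                                lambda_min_ratio)$lambda
  }
  acc <- array(NA_real_, c(p, p, n_boot))
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx, , drop = FALSE]
      if (all(apply(xb, 2, sd) > 0)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100 * n_boot) stop("too many degenerate resamples")
    }
    wb <- if (fix_lambda) {
      fit <- graphical_lasso(sample_correlation(xb), fixed_lambda)
      w <- precision_to_partial_correlations(fit$theta)
      w[abs(w) < 1e-10] <- 0
      w
    } else {
      ebic_select(xb, lambda_grid, gamma, nlambda, lambda_min_ratio)$weights
    }
    acc[, , b] <- wb
  }
  med <- apply(acc, c(1, 2), median)
  freq <- apply(acc, c(1, 2), function(v) mean(v != 0))
  diag(med) <- 0; diag(freq) <- 0
  labels <- colnames(x) %||% paste0("V", seq_len(p))
  dimnames(med) <- dimnames(freq) <- list(labels, labels)
  structure(list(median_weights = med, inclusion_frequency = freq,
                 n_boot = n_boot, n_redrawn = n_redrawn,
                 node_labels = labels),
            class = "bootstrap_summary")
}

network_weights <- function(network) {
  if (inherits(network, "pcn")) return(network$weights)
  if (inherits(network, "bootstrap_summary")) return(network$median_weights)
  if (is.matrix(network)) return(network)
  stop("expected a pcn, bootstrap_summary, or weight matrix")
}

#' Walktrap community detection
#'
#' Converts edge weights to non-negative similarities (absolute partial
#' correlations), runs the walktrap agglomerative algorithm on random walks
#' of the given length, and returns the partition of maximal modularity.
#' A graph without edges yields one singleton community per node.
#'
#' @param network A `pcn`, `bootstrap_summary`, or weight matrix.
#' @param steps Random-walk length (default 4).
#' @return A `community_partition`: list with `labels` (named integer
#'   community per node), `modularity`, `steps`.
#' @export
walktrap_communities <- function(network, steps = 4) {
  w <- abs(network_weights(network))
  p <- nrow(w)
  labels_nodes <- colnames(w) %||% paste0("V", seq_len(p))
  if (all(w == 0)) {
    return(structure(list(labels = setNames(seq_len(p), labels_nodes),
                          modularity = 0, steps = steps),
                     class = "community_partition"))
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wt <- igraph::cluster_walktrap(g, steps = steps)
  structure(list(labels = setNames(as.integer(igraph::membership(wt)),
                                   labels_nodes),
                 modularity = max(igraph::modularity(wt), 0),
                 steps = steps),
            class = "community_partition")
}

comparison_stats <- function(w1, w2) {
  ut <- upper.tri(w1)
  diffs <- w1 - w2
  c(M = max(abs(diffs[ut])),
    S = abs(sum(abs(w1[ut])) - sum(abs(w2[ut]))))
}

#' Permutation-based differential network comparison
#'
#' Splits subjects at the median of the outcome (ties to the low group),
#' estimates an EBIC-selected network per group, and tests the maximal
#' absolute edge difference (structure statistic M) and the global-strength
#' difference (S) against a permutation null built by shuffling group
#' labels and re-estimating both networks. Per-edge permutation p-values
#' (family: edges nonzero in either observed network) are Holm-adjusted.
#' With `include_outcome_node = TRUE` the standardized outcome enters the
#' data matrix as an additional node before estimation.
#'
#' @param x Data matrix or `processed_matrix` (one visit).
#' @param outcome Numeric per-subject score (e.g. week-8 HRSD-17).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param include_outcome_node Add the outcome as a network node (default
#'   FALSE).
#' @inheritParams ebic_select
#' @return A `network_comparison`: observed statistics, permutation
#'   p-values (`p_structure`, `p_global`, add-one convention), `per_edge`
#'   data frame, the two group networks and group sizes.
#' @export
compare_networks <- function(x, outcome, n_perm = 1000, seed = 1,
                             include_outcome_node = FALSE,
                             lambda_grid = NULL, gamma = 0.5, nlambda = 100,
                             lambda_min_ratio = 0.01) {
  if (inherits(x, "processed_matrix")) x <- x$values
  stopifnot(nrow(x) == length(outcome))
  if (length(unique(outcome)) < 2) stop("outcome must have >= 2 distinct values")
  med <- median(outcome)
  low <- outcome <= med
  if (sum(low) < 10 || sum(!low) < 10) {
    stop("degenerate median split: each group needs >= 10 subjects")
  }
  if (include_outcome_node) {
    x <- cbind(x, HRSD = as.numeric(scale(outcome)))
  }
  est <- function(rows) {
    ebic_select(x[rows, , drop = FALSE], lambda_grid, gamma, nlambda,
                lambda_min_ratio)$weights
  }
  w_low <- est(low)
  w_high <- est(!low)
  obs <- comparison_stats(w_low, w_high)
  ut <- upper.tri(w_low)
  edge_family <- which(ut & (w_low != 0 | w_high != 0), arr.ind = TRUE)
  obs_edge_diff <- (w_low - w_high)[edge_family]

  set.seed(seed)
  n <- nrow(x)
  exceed_M <- 0L; exceed_S <- 0L
  exceed_edge <- rep(0L, nrow(edge_family))
  for (b in seq_len(n_perm)) {
    perm_low <- rep(FALSE, n)
    perm_low[sample.int(n, sum(low))] <- TRUE
    wp1 <- est(perm_low)
    wp2 <- est(!perm_low)
    st <- comparison_stats(wp1, wp2)
    if (st["M"] >= obs["M"]) exceed_M <- exceed_M + 1L
    if (st["S"] >= obs["S"]) exceed_S <- exceed_S + 1L
    if (nrow(edge_family)) {
      dp <- (wp1 - wp2)[edge_family]
      exceed_edge <- exceed_edge + (abs(dp) >= abs(obs_edge_diff))
    }
  }
  per_edge <- data.frame(
    i = edge_family[, 1], j = edge_family[, 2],
    node_a = colnames(x)[edge_family[, 1]],
    node_b = colnames(x)[edge_family[, 2]],
    diff = obs_edge_diff,
    p_raw = (1 + exceed_edge) / (1 + n_perm),
    stringsAsFactors = FALSE
  )
  per_edge$p_adjusted <- if (nrow(per_edge)) {
    p.adjust(per_edge$p_raw, method = "holm")
  } else numeric(0)
  structure(list(stat_structure = unname(obs["M"]),
                 stat_global_strength = unname(obs["S"]),
                 p_structure = (1 + exceed_M) / (1 + n_perm),
                 p_global = (1 + exceed_S) / (1 + n_perm),
                 per_edge = per_edge,
                 weights_low = w_low, weights_high = w_high,
                 n_low = sum(low), n_high = sum(!low),
                 n_perm = n_perm,
                 include_outcome_node = include_outcome_node),
            class = "network_comparison")
}

#' Linear-regression validation of a differential interaction
#'
#' Fits `met_a ~ met_b + outcome + met_b:outcome (+ covariates)` by least
#' squares and reports the product-term coefficient with its t-test
#' p-value — the follow-up check applied to edges flagged by the
#' differential network analysis.
#'
#' @param met_a,met_b Numeric metabolite vectors.
#' @param outcome Numeric outcome vector.
#' @param covariates Optional data frame or matrix of extra covariates.
#' @return List with `coefficient`, `se`, `p_value` for the interaction
#'   term (NA with a warning when the outcome is constant).
#' @export
validate_interaction <- function(met_a, met_b, outcome, covariates = NULL) {
  stopifnot(length(met_a) == length(met_b), length(met_a) == length(outcome))
  if (sd(outcome) == 0) {
    warning("constant outcome: interaction term dropped")
    return(list(coefficient = NA_real_, se = NA_real_, p_value = NA_real_))
  }
  d <- data.frame(met_a = met_a, met_b = met_b, outcome = outcome)
  if (!is.null(covariates)) d <- cbind(d, as.data.frame(covariates))
  X <- model.matrix(~ . + met_b:outcome - met_a, data = d)
  if (qr(X)$rank < ncol(X)) {
    stop("collinear design in interaction validation")
  }
  fit <- lm(met_a ~ . + met_b:outcome, data = d)
  s <- summary(fit)$coefficients
  row <- grep("met_b:outcome", rownames(s))
  list(coefficient = s[row, 1], se = s[row, 2], p_value = s[row, 4])
}
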