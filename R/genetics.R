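#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: sums the
#' probabilities of all heterozygote counts no more probable than the
#' observed one. Probabilities are computed by log-factorial arithmetic and
#' renormalised over the attainable configurations.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total >= 1).
#' @return Exact p-value in `(0, 1]`, invariant to swapping `n_AA`/`n_aa`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0, n_AA + n_Aa + n_aa >= 1)
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa           # rare-or-not; symmetric either way
  n_rare <- min(n_a, 2 * n - n_a)
  if (n_rare == 0) return(1)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_common <- n - h - hom_rare
    h * log(2) - lgamma(hom_rare + 1) - lgamma(h + 1) - lgamma(hom_common + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- match(n_Aa, hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}

genotype_counts <- function(d) {
  d <- d[!is.na(d)]
  c(n0 = sum(d == 0), n1 = sum(d == 1), n2 = sum(d == 2))
}

variant_stats <- function(dosages) {
  call_rate <- colMeans(!is.na(dosages))
  f <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  hwe_p <- apply(dosages, 2, function(d) {
    ct <- genotype_counts(d)
    if (sum(ct) == 0) return(NA_real_)
    hwe_exact_test(ct[1], ct[2], ct[3])
  })
  data.frame(variant_id = colnames(dosages), call_rate = call_rate,
             maf = maf, hwe_p = hwe_p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Variant quality control
#'
#' Drops variants with call rate below `min_call_rate` (i.e. more than 5%
#' missing under the default), minor allele frequency below `min_maf`, or
#' exact HWE p-value below `hwe_threshold`. The QC report counts drops per
#' rule (a variant may fail several) and the unique total.
#'
#' @param G A `genotype_matrix`.
#' @param min_call_rate,min_maf,hwe_threshold QC thresholds (defaults 0.95,
#'   0.05, 1e-5, the conventional GWAS filters).
#' @return The filtered `genotype_matrix` with a `qc_report` element
#'   (per-variant stats, per-rule and unique drop counts).
#' @export
variant_qc <- function(G, min_call_rate = 0.95, min_maf = 0.05,
                       hwe_threshold = 1e-5) {
  stopifnot(inherits(G, "genotype_matrix"),
            min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5, hwe_threshold >= 0)
  stats <- variant_stats(G$dosages)
  fail_call <- stats$call_rate < min_call_rate
  fail_maf <- stats$maf < min_maf
  fail_hwe <- !is.na(stats$hwe_p) & stats$hwe_p < hwe_threshold
  drop <- fail_call | fail_maf | fail_hwe
  if (all(drop)) warning("all variants removed by QC")
  keep <- !drop
  G$dosages <- G$dosages[, keep, drop = FALSE]
  G$variant_meta <- G$variant_meta[keep, , drop = FALSE]
  G$qc_report <- list(
    per_variant = stats,
    n_fail_call_rate = sum(fail_call),
    n_fail_maf = sum(fail_maf),
    n_fail_hwe = sum(fail_hwe),
    n_dropped = sum(drop),
    n_retained = sum(keep),
    thresholds = c(min_call_rate = min_call_rate, min_maf = min_maf,
                   hwe_threshold = hwe_threshold)
  )
  G
}

#' Genotype principal components
#'
#' PCA of the column-standardized dosage matrix (missing dosages
#' mean-imputed per variant; monomorphic variants skipped); scores are
#' orthogonal and ordered by decreasing explained variance.
#'
#' @param G A `genotype_matrix`.
#' @param k Number of components (default 5, the conventional adjustment set).
#' @return Subjects x k matrix of PC scores with an `explained_variance`
#'   attribute.
#' @export
compute_pcs <- function(G, k = 5) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (k <= 0) stop("k must be positive")
  d <- G$dosages
  for (j in seq_len(ncol(d))) {
    miss <- is.na(d[, j])
    if (any(miss)) d[miss, j] <- mean(d[, j], na.rm = TRUE)
  }
  sds <- apply(d, 2, sd)
  d <- d[, sds > 0, drop = FALSE]
  if (k >= min(dim(d))) stop("k must be below min(subjects, variants)")
  pc <- prcomp(d, center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  attr(scores, "explained_variance") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  scores
}

#' Standardized metabolite log-ratio trait
#'
#' `log2(numerator) - log2(denominator)` per subject, centred and scaled to
#' unit variance; subjects beyond `sd_limit` standard deviations are
#' excluded and the trait re-centred and re-scaled (a conventional exclusion of
#' values more than 4 SDs from the mean).
#'
#' @param x A `processed_matrix` (its unscaled `log2_values` are used) or a
#'   subjects x metabolites matrix of log2 abundances.
#' @param numerator_id,denominator_id Metabolite column ids.
#' @param sd_limit Outlier exclusion limit (default 4).
#' @return A `ratio_trait`: list with `values` (named, mean 0 / sd 1 over
#'   retained subjects), `excluded_subjects`, `numerator`, `denominator`.
#' @export
make_ratio_trait <- function(x, numerator_id, denominator_id, sd_limit = 4) {
  l <- if (inherits(x, "processed_matrix")) x$log2_values else x
  stopifnot(is.matrix(l))
  if (!numerator_id %in% colnames(l)) stop("missing metabolite: ", numerator_id)
  if (!denominator_id %in% colnames(l)) stop("missing metabolite: ", denominator_id)
  r <- l[, numerator_id] - l[, denominator_id]
  if (is.null(names(r))) names(r) <- rownames(l) %||% paste0("S", seq_along(r))
  if (sd(r) == 0) stop("ratio trait has zero variance")
  z <- (r - mean(r)) / sd(r)
  excl <- abs(z) > sd_limit
  kept <- r[!excl]
  if (sd(kept) == 0) stop("ratio trait has zero variance after exclusion")
  vals <- (kept - mean(kept)) / sd(kept)
  structure(list(values = vals,
                 excluded_subjects = names(r)[excl],
                 numerator = numerator_id, denominator = denominator_id,
                 sd_limit = sd_limit),
            class = "ratio_trait")
}

# least squares with se/t/p for the dosage column, complete rows only
fast_assoc <- function(y, dosage, covar) {
  ok <- !is.na(dosage) & !is.na(y)
  if (!is.null(covar)) ok <- ok & complete.cases(covar)
  n <- sum(ok)
  d <- dosage[ok]
  if (n < 3 || sd(d) == 0) {
    return(c(beta = NA_real_, se = NA_real_, statistic = NA_real_,
             p = NA_real_, n = n))
  }
  X <- cbind(intercept = 1, dosage = d,
             if (!is.null(covar)) as.matrix(covar)[ok, , drop = FALSE])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop("collinear covariates in association model: ",
         paste(colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]], collapse = ", "))
  }
  yk <- y[ok]
  xtxi <- solve(crossprod(X))
  beta <- drop(xtxi %*% crossprod(X, yk))
  res <- yk - drop(X %*% beta)
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(xtxi))
  tval <- unname(beta[2] / se[2])
  c(beta = unname(beta[2]), se = unname(se[2]), statistic = unname(tval),
    p = 2 * pt(-abs(tval), df), n = n)
}

#' Additive genetic association scan for a ratio trait
#'
#' Per variant, a least-squares fit of the trait on the dosage plus
#' covariates (typically age, sex and PCs 1-5; optionally the
#' HRSD-17 score); subjects with a missing dosage are dropped per variant
#' and monomorphic variants are reported as NA.
#'
#' @param trait A `ratio_trait` or named numeric vector.
#' @param G A (QC-filtered) `genotype_matrix`.
#' @param covariates Optional data frame/matrix of numeric covariates,
#'   rows aligned with the genotype subjects.
#' @param outcome Optional numeric outcome score appended as an extra
#'   covariate.
#' @return An `association_table` data frame: `feature_id`, `chrom`, `pos`,
#'   `effect`, `se`, `statistic`, `p_value`, `q_value`, `n`, `model_tag`.
#' @export
assoc_scan <- function(trait, G, covariates = NULL, outcome = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  vals <- if (inherits(trait, "ratio_trait")) trait$values else trait
  subj <- rownames(G$dosages)
  if (!is.null(names(vals)) && !is.null(subj)) {
    y <- vals[match(subj, names(vals))]
  } else {
    stopifnot(length(vals) == nrow(G$dosages))
    y <- vals
  }
  covar <- covariates
  if (!is.null(covar)) {
    covar <- as.matrix(as.data.frame(covar))
    stopifnot(nrow(covar) == nrow(G$dosages))
  }
  if (!is.null(outcome)) {
    stopifnot(length(outcome) == nrow(G$dosages))
    covar <- cbind(covar, outcome = outcome)
  }
  out <- t(vapply(seq_len(ncol(G$dosages)), function(j) {
    fast_assoc(y, G$dosages[, j], covar)
  }, numeric(5)))
  tab <- data.frame(feature_id = colnames(G$dosages),
                    chrom = G$variant_meta$chrom,
                    pos = G$variant_meta$pos,
                    effect = out[, "beta"], se = out[, "se"],
                    statistic = out[, "statistic"], p_value = out[, "p"],
                    n = out[, "n"], stringsAsFactors = FALSE)
  ok <- !is.na(tab$p_value)
  tab$q_value <- NA_real_
  tab$q_value[ok] <- bh_adjust(tab$p_value[ok])
  tab$model_tag <- if (is.null(outcome)) "assoc_additive" else "assoc_additive_outcome_adj"
  class(tab) <- c("association_table", "data.frame")
  tab
}
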