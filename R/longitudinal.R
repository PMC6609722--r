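#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR-adjusted q-values: sort p ascending, take
#' `q(i) = min_{j >= i} p(j) * m / j`, cap at 1, return in original order.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1] and be non-missing")
  }
  p.adjust(p_values, method = "BH")
}

#' Random-intercept linear mixed model
#'
#' Fits `outcome ~ fixed_design + (1 | subject)` by REML (lme4) and reports
#' Wald z-tests for the fixed effects plus the between-subject and residual
#' variance components. A zero-variance outcome short-circuits to the exact
#' degenerate solution (all-zero estimates and variance components when the
#' outcome is identically zero).
#'
#' @param outcome Numeric response, one value per visit row.
#' @param fixed_design Numeric design matrix (include an intercept column if
#'   wanted), same number of rows.
#' @param subject_ids Grouping factor, same length.
#' @return List with `estimates` (data frame: term, estimate, se, statistic,
#'   p_value), `varcomp` (`between_subject`, `residual`), `logLik`, and the
#'   lme4 `fit` (NULL in degenerate cases).
#' @export
fit_random_intercept <- function(outcome, fixed_design, subject_ids) {
  fixed_design <- as.matrix(fixed_design)
  if (is.null(colnames(fixed_design))) {
    colnames(fixed_design) <- paste0("x", seq_len(ncol(fixed_design)))
  }
  stopifnot(length(outcome) == nrow(fixed_design),
            length(subject_ids) == length(outcome))
  if (length(unique(subject_ids)) < 2) stop("need at least 2 subjects")
  qr_x <- qr(fixed_design)
  if (qr_x$rank < ncol(fixed_design)) {
    dropped <- colnames(fixed_design)[qr_x$pivot[(qr_x$rank + 1):ncol(fixed_design)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  if (sd(outcome) == 0) {
    beta <- qr.coef(qr_x, outcome)
    beta[is.na(beta)] <- 0
    est <- data.frame(term = colnames(fixed_design), estimate = beta,
                      se = 0, statistic = NA_real_, p_value = NA_real_,
                      row.names = NULL, stringsAsFactors = FALSE)
    return(list(estimates = est,
                varcomp = c(between_subject = 0, residual = 0),
                logLik = NA_real_, fit = NULL))
  }
  df <- data.frame(.y = outcome, .sid = factor(subject_ids))
  fit <- suppressMessages(lme4::lmer(
    .y ~ 0 + fixed_design + (1 | .sid), data = df, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  if (any(grepl("failed to converge", msgs, ignore.case = TRUE))) {
    stop("mixed model failed to converge: ", paste(msgs, collapse = "; "))
  }
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- beta / se
  vc <- lme4::VarCorr(fit)
  est <- data.frame(term = colnames(fixed_design), estimate = unname(beta),
                    se = unname(se), statistic = unname(z),
                    p_value = 2 * pnorm(-abs(unname(z))),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(estimates = est,
       varcomp = c(between_subject = as.numeric(vc$.sid[1, 1]),
                   residual = attr(vc, "sc")^2),
       logLik = as.numeric(logLik(fit)),
       fit = fit)
}

#' Default metabolite ratios for the scans
#'
#' Serotonin turnover and related pairs analysed alongside single
#' metabolites: 5HIAA/5HT, I3AA/TRP, MHPG/TYR, PXAN/XAN, URIC/XAN,
#' XAN/XANTH, 4HPAC/TYR. Ratios are differences of log2 abundances.
#'
#' @return Data frame with `ratio_id`, `numerator`, `denominator`.
#' @export
default_ratios <- function() {
  data.frame(
    ratio_id = c("5HIAA/5HT", "I3AA/TRP", "MHPG/TYR", "PXAN/XAN",
                 "URIC/XAN", "XAN/XANTH", "4HPAC/TYR"),
    numerator = c("5HIAA", "I3AA", "MHPG", "PXAN", "URIC", "XAN", "4HPAC"),
    denominator = c("5HT", "TRP", "TYR", "XAN", "XAN", "XANTH", "TYR"),
    stringsAsFactors = FALSE
  )
}

# Build the per-feature value matrix for a visit: scaled metabolite values
# plus (optionally) log2-ratio columns standardized by pooled moments.
feature_matrix <- function(processed, ratios, pooled_stats = NULL) {
  v <- processed$values
  if (is.null(ratios) || nrow(ratios) == 0) return(v)
  have <- ratios$numerator %in% colnames(v) & ratios$denominator %in% colnames(v)
  ratios <- ratios[have, , drop = FALSE]
  if (nrow(ratios) == 0) return(v)
  r <- sapply(seq_len(nrow(ratios)), function(k) {
    processed$log2_values[, ratios$numerator[k]] -
      processed$log2_values[, ratios$denominator[k]]
  })
  r <- matrix(r, nrow = nrow(v))
  colnames(r) <- ratios$ratio_id
  if (!is.null(pooled_stats)) {
    r <- sweep(sweep(r, 2, pooled_stats$mean[colnames(r)], "-"),
               2, pooled_stats$sd[colnames(r)], "/")
  }
  cbind(v, r)
}

# Pooled mean/sd of ratio columns across the supplied visits, so ratios are
# standardized consistently with the pooled scaling of single metabolites.
ratio_pooled_stats <- function(processed_list, ratios) {
  if (is.null(ratios) || nrow(ratios) == 0) return(NULL)
  stacked <- do.call(rbind, lapply(processed_list, function(pm) {
    sapply(seq_len(nrow(ratios)), function(k) {
      pm$log2_values[, ratios$numerator[k]] - pm$log2_values[, ratios$denominator[k]]
    })
  }))
  stacked <- matrix(stacked, ncol = nrow(ratios))
  list(mean = setNames(colMeans(stacked), ratios$ratio_id),
       sd = setNames(apply(stacked, 2, sd), ratios$ratio_id))
}

scan_one <- function(y, X, sid) {
  res <- tryCatch(fit_random_intercept(y, X, sid), error = function(e) e)
  if (inherits(res, "error")) {
    return(c(effect = NA_real_, se = NA_real_, statistic = NA_real_,
             p_value = NA_real_))
  }
  row <- res$estimates[res$estimates$term == "target", ]
  c(effect = row$estimate, se = row$se, statistic = row$statistic,
    p_value = row$p_value)
}

#' Drug-exposure scan at week 4 or week 8
#'
#' For each metabolite (and configured log2-ratio), fits a random-intercept
#' mixed model of the processed value on a time-point indicator
#' (baseline vs target week), adjusting for age, sex and baseline HRSD-17;
#' the time-indicator coefficient is the standardized exposure effect.
#' Benjamini-Hochberg q-values are appended (the conventional cutoff is 10%).
#'
#' @param processed Named list of `processed_matrix` for `t0`, `t4`, `t8`
#'   (from [preprocess_cohort()] with pooled scaling).
#' @param clinical Clinical data frame with `age`, `sex`, `hrsd_t0` and
#'   subject order matching the matrices.
#' @param week 4 or 8.
#' @param ratios Ratio definition data frame (see [default_ratios()]);
#'   NULL for single metabolites only.
#' @return An `association_table` data frame: `feature_id`, `effect`, `se`,
#'   `statistic`, `p_value`, `q_value`, `model_tag`.
#' @export
exposure_scan <- function(processed, clinical, week = 8,
                          ratios = default_ratios()) {
  if (!week %in% c(4, 8)) stop("week must be 4 or 8")
  tp <- paste0("t", week)
  stopifnot(all(c("t0", tp) %in% names(processed)))
  pooled <- ratio_pooled_stats(processed[c("t0", tp)], ratios)
  f0 <- feature_matrix(processed$t0, ratios, pooled)
  f1 <- feature_matrix(processed[[tp]], ratios, pooled)
  stopifnot(nrow(f0) == nrow(f1), nrow(f0) == nrow(clinical))
  n <- nrow(f0)
  sid <- rep(clinical$subject_id, 2)
  X <- cbind(intercept = 1,
             target = rep(c(0, 1), each = n),
             age = rep(clinical$age, 2),
             sex = rep(as.numeric(clinical$sex == "M"), 2),
             hrsd_baseline = rep(clinical$hrsd_t0, 2))
  out <- t(vapply(colnames(f0), function(m) {
    scan_one(c(f0[, m], f1[, m]), X, sid)
  }, numeric(4)))
  tab <- data.frame(feature_id = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  ok <- !is.na(tab$p_value)
  tab$q_value <- NA_real_
  tab$q_value[ok] <- bh_adjust(tab$p_value[ok])
  tab$model_tag <- sprintf("exposure_week%d", week)
  class(tab) <- c("association_table", "data.frame")
  tab
}

#' Metabolite-symptom association scan
#'
#' Per metabolite (and ratio), fits a random-intercept model of the
#' processed value on the time-varying HRSD-17 score across all visits,
#' adjusting for age and sex; reports the HRSD coefficient with BH q-values.
#' With `regressor = "change"` both metabolite and HRSD enter as
#' change-from-baseline at the follow-up visits.
#'
#' @inheritParams exposure_scan
#' @param regressor `"value"` (default) or `"change"`.
#' @return An `association_table` data frame.
#' @export
symptom_association_scan <- function(processed, clinical,
                                     ratios = default_ratios(),
                                     regressor = c("value", "change")) {
  regressor <- match.arg(regressor)
  tps <- intersect(c("t0", "t4", "t8"), names(processed))
  if (length(tps) < 2) stop("need at least 2 time points")
  pooled <- ratio_pooled_stats(processed[tps], ratios)
  feats <- lapply(processed[tps], feature_matrix, ratios = ratios,
                  pooled_stats = pooled)
  hrsd <- lapply(tps, function(t) clinical[[paste0("hrsd_", t)]])
  names(hrsd) <- tps
  if (regressor == "change") {
    base_f <- feats[["t0"]]; base_h <- hrsd[["t0"]]
    tps_use <- setdiff(tps, "t0")
    feats <- lapply(feats[tps_use], function(f) f - base_f)
    hrsd <- lapply(hrsd[tps_use], function(h) h - base_h)
    tps <- tps_use
  }
  n <- nrow(clinical)
  sid <- rep(clinical$subject_id, length(tps))
  h <- unlist(hrsd, use.names = FALSE)
  if (sd(h) == 0) {
    warning("HRSD scores constant across all visits; coefficients set to NA")
    tab <- data.frame(feature_id = colnames(feats[[1]]), effect = NA_real_,
                      se = NA_real_, statistic = NA_real_, p_value = NA_real_,
                      q_value = NA_real_, model_tag = "symptom_degenerate",
                      stringsAsFactors = FALSE)
    class(tab) <- c("association_table", "data.frame")
    return(tab)
  }
  X <- cbind(intercept = 1, target = h,
             age = rep(clinical$age, length(tps)),
             sex = rep(as.numeric(clinical$sex == "M"), length(tps)))
  out <- t(vapply(colnames(feats[[1]]), function(m) {
    y <- unlist(lapply(feats, function(f) f[, m]), use.names = FALSE)
    scan_one(y, X, sid)
  }, numeric(4)))
  tab <- data.frame(feature_id = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  ok <- !is.na(tab$p_value)
  tab$q_value <- NA_real_
  tab$q_value[ok] <- bh_adjust(tab$p_value[ok])
  tab$model_tag <- paste0("symptom_", regressor)
  class(tab) <- c("association_table", "data.frame")
  tab
}

#' Two-step time-course regression
#'
#' Step 1: per metabolite, a least-squares fit of the processed value on
#' polynomial time terms, a group dummy and group-by-time interactions; the
#' group terms are tested jointly by an F-test against the time-only model,
#' and the p-values are FDR-adjusted — metabolites under the cutoff are
#' flagged selected. Step 2: for the selected metabolites, backward
#' stepwise elimination at `alpha` (interactions dropped before their main
#' effects); the surviving group-difference terms are reported.
#'
#' @param processed Named list of `processed_matrix` for exactly 3 visits.
#' @param groups Logical or 2-level vector per subject (e.g. responder).
#' @param degree Polynomial degree in time (default 2; must be < number of
#'   visits).
#' @param alpha Stepwise retention significance level (default 0.05).
#' @param fdr FDR cutoff for step-1 selection (default 0.05).
#' @return A `timecourse_result`: list with `table` (per-metabolite
#'   `global_fit_p`, `q_value`, `selected`, `r_squared`) and
#'   `group_difference_terms` (per selected metabolite: term, coefficient,
#'   p_value).
#' @export
timecourse_two_step <- function(processed, groups, degree = 2, alpha = 0.05,
                                fdr = 0.05) {
  tps <- intersect(c("t0", "t4", "t8"), names(processed))
  if (length(tps) != 3) stop("exactly 3 time points are required")
  if (degree >= length(tps)) stop("degree must be below the number of time points")
  g <- as.numeric(as.factor(groups)) - 1
  if (length(unique(g)) != 2) stop("groups must have exactly 2 levels")
  if (min(table(g)) < 5) stop("each group needs at least 5 subjects")
  n <- nrow(processed[[1]]$values)
  stopifnot(length(g) == n)
  tnum <- rep(seq_along(tps) - 1, each = n)
  gg <- rep(g, length(tps))
  time_terms <- sapply(seq_len(degree), function(d) tnum^d)
  colnames(time_terms) <- paste0("time", seq_len(degree))
  group_cols <- cbind(group = gg, gg * time_terms)
  colnames(group_cols) <- c("group", paste0("group_time", seq_len(degree)))
  mets <- colnames(processed[[1]]$values)

  res <- lapply(mets, function(m) {
    y <- unlist(lapply(processed[tps], function(pm) pm$values[, m]),
                use.names = FALSE)
    if (sd(y) == 0) {
      return(list(p = NA_real_, r2 = NA_real_, terms = NULL))
    }
    d_red <- data.frame(y = y, time_terms)
    d_full <- data.frame(y = y, time_terms, group_cols, check.names = FALSE)
    fit_red <- lm(y ~ ., data = d_red)
    fit_full <- lm(y ~ ., data = d_full)
    a <- anova(fit_red, fit_full)
    list(p = a$`Pr(>F)`[2], r2 = summary(fit_full)$r.squared,
         d_full = d_full)
  })
  pv <- vapply(res, `[[`, numeric(1), "p")
  ok <- !is.na(pv)
  qv <- rep(NA_real_, length(pv))
  if (any(ok)) qv[ok] <- bh_adjust(pv[ok])
  selected <- !is.na(qv) & qv < fdr

  # a main effect is droppable only once its interactions are gone
  droppable <- function(trm, keep) {
    if (trm == "group") return(!any(grepl("^group_time", keep)))
    if (grepl("^time", trm)) {
      d <- sub("^time", "", trm)
      return(!(paste0("group_time", d) %in% keep))
    }
    TRUE
  }
  terms_out <- list()
  for (k in which(selected)) {
    d <- res[[k]]$d_full
    keep <- setdiff(names(d), "y")
    repeat {
      fit <- lm(y ~ ., data = d[, c("y", keep), drop = FALSE])
      s <- summary(fit)$coefficients
      pvals <- setNames(s[-1, 4], rownames(s)[-1])
      cand <- keep[vapply(keep, droppable, logical(1), keep = keep)]
      cand_p <- pvals[intersect(names(pvals), cand)]
      if (length(cand_p) == 0 || max(cand_p, na.rm = TRUE) <= alpha) break
      keep <- setdiff(keep, names(which.max(cand_p)))
      if (length(keep) == 0) break
    }
    if (length(keep)) {
      fit <- lm(y ~ ., data = d[, c("y", keep), drop = FALSE])
      s <- summary(fit)$coefficients
      idx <- match(keep, rownames(s))
      surv <- data.frame(term = keep, coefficient = s[idx, 1],
                         p_value = s[idx, 4], row.names = NULL,
                         stringsAsFactors = FALSE)
      surv <- surv[grepl("^group", surv$term), , drop = FALSE]
    } else {
      surv <- data.frame(term = character(), coefficient = numeric(),
                         p_value = numeric(), stringsAsFactors = FALSE)
    }
    terms_out[[mets[k]]] <- surv
  }
  structure(list(table = data.frame(metabolite = mets, global_fit_p = pv,
                                    q_value = qv, selected = selected,
                                    r_squared = vapply(res, `[[`, numeric(1), "r2"),
                                    stringsAsFactors = FALSE),
                 group_difference_terms = terms_out,
                 degree = degree, alpha = alpha, fdr = fdr),
            class = "timecourse_result")
}

#' Genomic-control inflation factor
#'
#' Median chi-square statistic of the p-values divided by the null median
#' (0.4549); values near 1 indicate a calibrated scan.
#'
#' @param p_values Numeric p-values in `(0, 1]`.
#' @return The inflation factor lambda.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  median(qchisq(1 - p_values, df = 1)) / qchisq(0.5, df = 1)
}
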