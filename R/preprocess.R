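#' Missingness quality control
#'
#' Drops metabolites whose fraction of missing abundances strictly exceeds
#' the threshold (the conventional rule is 20%).
#'
#' @param abundances Subjects x metabolites matrix of raw abundances with
#'   `NA` marking missing values.
#' @param threshold Maximum tolerated missing fraction, in `(0, 1]`.
#' @return List with `matrix` (filtered columns), `retained`, `dropped`
#'   (character vectors of metabolite ids) and `missing_fraction` (named,
#'   all metabolites).
#' @export
qc_missingness <- function(abundances, threshold = 0.20) {
  stopifnot(is.matrix(abundances), threshold > 0, threshold <= 1)
  frac <- colMeans(is.na(abundances))
  keep <- frac <= threshold
  if (!any(keep)) stop("all metabolites exceed the missingness threshold")
  list(matrix = abundances[, keep, drop = FALSE],
       retained = colnames(abundances)[keep],
       dropped = colnames(abundances)[!keep],
       missing_fraction = frac)
}

#' k-nearest-neighbour imputation
#'
#' Replaces each missing cell by the mean of that metabolite's values among
#' the `k` nearest subjects. Distances are Euclidean over mutually observed
#' columns after per-metabolite standardisation, rescaled by the fraction of
#' columns observed (so subjects with few shared observations are not
#' artificially close). Observed cells are never altered.
#'
#' @param x Subjects x metabolites matrix with `NA`s.
#' @param k Number of neighbours (default 10; must be < number of subjects).
#' @return Complete matrix of the same shape.
#' @export
knn_impute <- function(x, k = 10) {
  stopifnot(is.matrix(x), k >= 1, k < nrow(x))
  if (!anyNA(x)) return(x)
  all_missing_subj <- rowSums(!is.na(x)) == 0
  if (any(all_missing_subj)) {
    stop("subject(s) with all metabolites missing: ",
         paste(rownames(x)[all_missing_subj], collapse = ", "))
  }
  no_ref <- colSums(!is.na(x)) == 0
  if (any(no_ref)) {
    stop("metabolite(s) with no observed values: ",
         paste(colnames(x)[no_ref], collapse = ", "))
  }
  mu <- colMeans(x, na.rm = TRUE)
  sds <- apply(x, 2, sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- 1
  z <- sweep(sweep(x, 2, mu, "-"), 2, sds, "/")
  n <- nrow(x)
  obs <- !is.na(x)
  out <- x
  need <- which(rowSums(!obs) > 0)
  for (i in need) {
    # squared distance to every other subject over mutually observed columns
    di <- rep(Inf, n)
    zi <- z[i, ]
    oi <- obs[i, ]
    for (j in seq_len(n)[-i]) {
      shared <- oi & obs[j, ]
      ns <- sum(shared)
      if (ns == 0) next
      di[j] <- sum((zi[shared] - z[j, shared])^2) / (ns / ncol(x))
    }
    ord <- order(di)
    for (m in which(!oi)) {
      cand <- ord[obs[ord, m] & is.finite(di[ord])]
      if (length(cand) == 0) {
        out[i, m] <- mu[m]
      } else {
        out[i, m] <- mean(x[cand[seq_len(min(k, length(cand)))], m])
      }
    }
  }
  out
}

#' Log2 transform and unit-variance scaling
#'
#' Elementwise log2 followed by per-metabolite division by the sample
#' (n - 1) standard deviation, with optional mean-centering (the default).
#'
#' @param x Complete matrix of strictly positive abundances.
#' @param center Subtract per-column means before scaling (default TRUE).
#' @return A `processed_matrix`: list with `values` (scaled),
#'   `log2_values` (log2, unscaled — used for ratio traits), and
#'   `transform_log` (record of applied steps).
#' @export
log2_scale <- function(x, center = TRUE) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("matrix must be complete; impute first")
  if (any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive abundance at subject %s, metabolite %s",
                 rownames(x)[bad[1]] %||% bad[1],
                 colnames(x)[bad[2]] %||% bad[2]))
  }
  l <- log2(x)
  sds <- apply(l, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance metabolite column(s): ",
         paste(colnames(l)[sds == 0], collapse = ", "))
  }
  v <- if (center) sweep(l, 2, colMeans(l), "-") else l
  v <- sweep(v, 2, sds, "/")
  structure(list(values = v, log2_values = l,
                 transform_log = list(log2 = TRUE, center = center,
                                      scale = "sd (n-1)")),
            class = "processed_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label treatment outcome from HRSD-17 scores
#'
#' Response is at least a 50% reduction from baseline to exit, remission an
#' exit score of 7 or less, and complete non-response less than a 30%
#' reduction; the three labels are computed independently (a subject can be
#' both responder and remitter).
#'
#' @param hrsd_baseline,hrsd_exit Non-negative scores (vectors allowed);
#'   baseline must be > 0.
#' @param subject_id Optional ids for the output rows.
#' @return Data frame with `subject_id`, `pct_reduction`, `responder`,
#'   `remitter`, `complete_nonresponder`.
#' @examples
#' classify_response(20, 10)  # exactly 50%: responder
#' @export
classify_response <- function(hrsd_baseline, hrsd_exit, subject_id = NULL) {
  if (any(hrsd_baseline < 0) || any(hrsd_exit < 0)) {
    stop("HRSD scores must be non-negative")
  }
  if (any(hrsd_baseline == 0)) stop("baseline HRSD must be positive")
  n <- max(length(hrsd_baseline), length(hrsd_exit))
  b <- rep_len(hrsd_baseline, n); e <- rep_len(hrsd_exit, n)
  pct <- 100 * (b - e) / b
  data.frame(
    subject_id = subject_id %||% paste0("S", seq_len(n)),
    pct_reduction = pct,
    responder = pct >= 50,
    remitter = e <= 7,
    complete_nonresponder = pct < 30,
    stringsAsFactors = FALSE
  )
}

#' Preprocess a longitudinal cohort end to end
#'
#' Runs the fixed pipeline per time point — missingness QC, kNN imputation —
#' then log2-transforms and unit-variance-scales the three visit matrices
#' jointly (stacked over visits), so that between-visit abundance shifts are
#' preserved in standardized units. Metabolites failing QC at any visit are
#' dropped everywhere to keep the matrices aligned.
#'
#' @param dataset A `cohort_dataset`.
#' @param missing_threshold QC threshold (default 0.20).
#' @param k Imputation neighbours (default 10).
#' @param center Center columns during scaling (default TRUE).
#' @param pool_scaling Scale the visits jointly (default TRUE); FALSE scales
#'   each visit matrix independently (removes between-visit shifts).
#' @return List with `processed` (named list of `processed_matrix` per
#'   visit), `labels` (response labels from baseline to week 8), `clinical`,
#'   and `retained` metabolite ids.
#' @export
preprocess_cohort <- function(dataset, missing_threshold = 0.20, k = 10,
                              center = TRUE, pool_scaling = TRUE) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  qc <- lapply(dataset$abundances, qc_missingness, threshold = missing_threshold)
  retained <- Reduce(intersect, lapply(qc, `[[`, "retained"))
  if (length(retained) == 0) stop("no metabolite passes QC at every visit")
  imputed <- lapply(qc, function(q) {
    m <- q$matrix[, retained, drop = FALSE]
    if (anyNA(m)) knn_impute(m, k = k) else m
  })
  tps <- names(imputed)
  if (pool_scaling) {
    stacked <- do.call(rbind, imputed)
    pm <- log2_scale(stacked, center = center)
    n <- nrow(imputed[[1]])
    processed <- lapply(seq_along(tps), function(t) {
      idx <- ((t - 1) * n + 1):(t * n)
      structure(list(values = pm$values[idx, , drop = FALSE],
                     log2_values = pm$log2_values[idx, , drop = FALSE],
                     transform_log = c(pm$transform_log,
                                       list(pooled_over_visits = TRUE,
                                            qc_threshold = missing_threshold,
                                            knn_k = k))),
                class = "processed_matrix")
    })
  } else {
    processed <- lapply(imputed, function(m) {
      pm <- log2_scale(m, center = center)
      pm$transform_log <- c(pm$transform_log,
                            list(pooled_over_visits = FALSE,
                                 qc_threshold = missing_threshold, knn_k = k))
      pm
    })
  }
  names(processed) <- tps
  for (t in tps) {
    rownames(processed[[t]]$values) <- dataset$clinical$subject_id
    rownames(processed[[t]]$log2_values) <- dataset$clinical$subject_id
  }
  labels <- classify_response(dataset$clinical$hrsd_t0, dataset$clinical$hrsd_t8,
                              subject_id = dataset$clinical$subject_id)
  list(processed = processed, labels = labels,
       clinical = dataset$clinical, retained = retained)
}
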