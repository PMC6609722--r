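#' Build a block-structured ground-truth precision matrix
#'
#' Plants a sparse Gaussian graphical model whose off-diagonal support lies
#' inside community blocks (plus optional sparse between-community edges).
#' The diagonal is rescaled for diagonal dominance so the matrix is always
#' positive definite; community labels are recorded alongside.
#'
#' @param p Number of metabolites (>= 2).
#' @param n_communities Number of community blocks (>= 1); sizes as even as
#'   possible.
#' @param within_density Probability that a within-block pair receives an
#'   edge, in `[0, 1]`.
#' @param edge_strength Magnitude of planted precision off-diagonals
#'   (positive; signs are randomised).
#' @param between_density Probability of an edge between blocks (default 0).
#' @param topology Within-block wiring: `"random"` (Erdős–Rényi at
#'   `within_density`, the default) or `"crown"` (each block a crown
#'   graph: complete bipartite between two halves minus a perfect
#'   matching; `within_density` is ignored). Crown blocks are
#'   vertex-transitive with diameter 3 and no local cliques, so the
#'   planted blocks are themselves the modularity-optimal communities —
#'   the appropriate gold standard for community-recovery benchmarks,
#'   whereas Erdős–Rényi blocks can carry chance substructure that random
#'   walks legitimately resolve into sub-communities.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `ground_truth` object: list with `precision` (p x p positive
#'   definite), `community_labels` (integer per metabolite),
#'   `exposure_effects` (p x 2 matrix of standardized shifts at weeks 4 and
#'   8, initialised to zero), `differential_edges` (NULL), `genetic_effects`
#'   (NULL).
#' @examples
#' gt <- make_precision_matrix(p = 6, n_communities = 2, within_density = 1,
#'                             edge_strength = 0.3, seed = 1)
#' min(eigen(gt$precision, symmetric = TRUE, only.values = TRUE)$values) > 0
#' @export
make_precision_matrix <- function(p, n_communities = 2, within_density = 0.5,
                                  edge_strength = 0.3, between_density = 0,
                                  topology = c("random", "crown"),
                                  seed = 1) {
  stopifnot(p >= 2, n_communities >= 1, within_density >= 0,
            within_density <= 1, edge_strength > 0)
  topology <- match.arg(topology)
  set.seed(seed)
  labels <- sort(rep_len(seq_len(n_communities), p))
  omega <- diag(p)
  if (topology == "random") {
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        dens <- if (labels[i] == labels[j]) within_density else between_density
        if (dens > 0 && runif(1) < dens) {
          val <- edge_strength * sample(c(-1, 1), 1)
          omega[i, j] <- omega[j, i] <- val
        }
      }
    }
  } else {
    for (b in seq_len(n_communities)) {
      idx <- which(labels == b)
      bs <- length(idx)
      if (bs < 2) next
      half <- ceiling(bs / 2)
      for (i in seq_len(half)) {
        for (j in (half + 1):bs) {
          if (j - half == i) next  # remove the perfect matching
          val <- edge_strength * sample(c(-1, 1), 1)
          omega[idx[i], idx[j]] <- omega[idx[j], idx[i]] <- val
        }
      }
    }
    if (between_density > 0) {
      for (i in seq_len(p - 1)) {
        for (j in (i + 1):p) {
          if (labels[i] != labels[j] && runif(1) < between_density) {
            val <- edge_strength * sample(c(-1, 1), 1)
            omega[i, j] <- omega[j, i] <- val
          }
        }
      }
    }
  }
  # diagonal dominance guarantees positive definiteness
  rs <- rowSums(abs(omega)) - diag(omega)
  diag(omega) <- pmax(1, 1.1 * rs)
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    diag(omega) <- diag(omega) + (1e-8 - min(ev) + 0.05)
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("internal: precision matrix not positive definite")
  }
  structure(list(precision = omega,
                 community_labels = labels,
                 exposure_effects = matrix(0, p, 2,
                                           dimnames = list(NULL, c("week4", "week8"))),
                 differential_edges = NULL,
                 genetic_effects = NULL),
            class = "ground_truth")
}

default_hrsd_params <- function() {
  data.frame(
    group = rep(c("responder", "nonresponder"), each = 3),
    time = rep(c("t0", "t4", "t8"), 2),
    mean = c(21.86, 10.10, 5.79, 22.03, 15.03, 14.90),
    sd = c(5.17, 5.77, 3.27, 4.28, 6.58, 4.15),
    stringsAsFactors = FALSE
  )
}

# Apply differential edges to a base precision matrix for one group.
# Weights are target partial correlations; theta_ij = -w sqrt(th_ii th_jj).
apply_differential_edges <- function(omega, edges, column) {
  if (is.null(edges) || nrow(edges) == 0) return(omega)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    w <- edges[[column]][r]
    omega[i, j] <- omega[j, i] <- -w * sqrt(omega[i, i] * omega[j, j])
  }
  omega
}

#' Simulate a longitudinal pharmacometabolomics cohort
#'
#' Draws baseline latent metabolite vectors from the inverse of the
#' ground-truth precision matrix, propagates them to weeks 4 and 8 with
#' AR(1) subject-level carryover plus the specified standardized exposure
#' shifts, maps latents to positive raw abundances by `2^(mu + sigma * z)`,
#' and simulates HRSD-17 trajectories from a responder/nonresponder mixture
#' (baseline resampled until >= 14, matching the usual trial inclusion rule).
#' Declared differential edges are realised through group-specific precision
#' matrices that differ only at those edges.
#'
#' @param n_subjects Number of subjects (>= 10).
#' @param ground_truth A `ground_truth` object from
#'   [make_precision_matrix()]; set its `exposure_effects` /
#'   `differential_edges` fields to plant signals. `differential_edges` is a
#'   data frame with columns `i`, `j`, `w_low`, `w_high` (target partial
#'   correlations for the low-HRSD (responder) and high-HRSD groups).
#' @param response_rate Bernoulli responder probability (default 0.693, the
#'   week-8 response rate emulated by default).
#' @param hrsd_params Data frame with columns `group`
#'   (`responder`/`nonresponder`), `time` (`t0`,`t4`,`t8`), `mean`, `sd`;
#'   defaults to the emulated cohort means/SDs.
#' @param rho AR(1) carryover of latent deviations between visits
#'   (default 0.6).
#' @param mu,sigma Per-metabolite location and scale on the log2 abundance
#'   scale (scalar or length p; defaults 10 and 1).
#' @param subject_intercept_sd SD of an optional per-subject, per-metabolite
#'   random intercept added to all visits (default 0, so the baseline
#'   covariance equals the inverse precision exactly).
#' @param symptom_coupling Optional list `list(metabolite =, coef =)` adding
#'   `coef * standardized HRSD` to one metabolite's latent at every visit,
#'   for testing the symptom-association scan.
#' @param metabolite_ids Optional character vector of column names; defaults
#'   to the packaged 31-metabolite panel when p = 31, else `M1..Mp`.
#' @param seed Integer seed.
#' @return A `cohort_dataset`: list with `abundances` (named list of
#'   subjects x metabolites matrices `t0`, `t4`, `t8`), `clinical` (data
#'   frame with `subject_id`, `age`, `sex`, `drug_arm`, `hrsd_t0`,
#'   `hrsd_t4`, `hrsd_t8`, `responder`), and `metabolite_ids`.
#' @export
simulate_cohort <- function(n_subjects = 290, ground_truth,
                            response_rate = 0.693,
                            hrsd_params = default_hrsd_params(),
                            rho = 0.6, mu = 10, sigma = 1,
                            subject_intercept_sd = 0,
                            symptom_coupling = NULL,
                            metabolite_ids = NULL,
                            seed = 1) {
  stopifnot(n_subjects >= 10, response_rate > 0, response_rate < 1,
            inherits(ground_truth, "ground_truth"))
  need <- expand.grid(group = c("responder", "nonresponder"),
                      time = c("t0", "t4", "t8"), stringsAsFactors = FALSE)
  have <- paste(hrsd_params$group, hrsd_params$time)
  missing_cfg <- setdiff(paste(need$group, need$time), have)
  if (length(missing_cfg)) {
    stop("hrsd_params missing entries for: ", paste(missing_cfg, collapse = "; "))
  }
  p <- nrow(ground_truth$precision)
  mu <- rep_len(mu, p); sigma <- rep_len(sigma, p)
  if (is.null(metabolite_ids)) {
    metabolite_ids <- if (p == 31) metabolite_panel()$metabolite_id
                      else paste0("M", seq_len(p))
  }
  stopifnot(length(metabolite_ids) == p)

  set.seed(seed)
  responder <- rbinom(n_subjects, 1, response_rate) == 1

  edges <- ground_truth$differential_edges
  if (!is.null(edges)) {
    stopifnot(all(c("i", "j", "w_low", "w_high") %in% names(edges)),
              all(edges$i < edges$j), all(edges$j <= p), all(edges$i >= 1))
  }
  omega_low <- apply_differential_edges(ground_truth$precision, edges, "w_low")
  omega_high <- apply_differential_edges(ground_truth$precision, edges, "w_high")
  # shared ridge keeps non-edge entries bit-identical between groups
  ev_min <- min(eigen(omega_low, symmetric = TRUE, only.values = TRUE)$values,
                eigen(omega_high, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-8) {
    ridge <- 1e-8 - ev_min + 0.05
    diag(omega_low) <- diag(omega_low) + ridge
    diag(omega_high) <- diag(omega_high) + ridge
  }
  sigma_low <- solve(omega_low)
  sigma_high <- solve(omega_high)
  chol_low <- chol(sigma_low)
  chol_high <- chol(sigma_high)

  draw_latent <- function() {
    z <- matrix(rnorm(n_subjects * p), n_subjects, p)
    out <- matrix(0, n_subjects, p)
    # responders are the low-HRSD (better outcome) group
    if (any(responder)) out[responder, ] <- z[responder, , drop = FALSE] %*% chol_low
    if (any(!responder)) out[!responder, ] <- z[!responder, , drop = FALSE] %*% chol_high
    out
  }

  delta <- ground_truth$exposure_effects
  z0 <- draw_latent()
  z4 <- sweep(rho * z0 + sqrt(1 - rho^2) * draw_latent(), 2, delta[, 1], "+")
  z8dev <- rho * sweep(z4, 2, delta[, 1], "-") + sqrt(1 - rho^2) * draw_latent()
  z8 <- sweep(z8dev, 2, delta[, 2], "+")
  if (subject_intercept_sd > 0) {
    u <- matrix(rnorm(n_subjects * p, sd = subject_intercept_sd), n_subjects, p)
    z0 <- z0 + u; z4 <- z4 + u; z8 <- z8 + u
  }

  hp <- function(group, time) {
    row <- hrsd_params[hrsd_params$group == group & hrsd_params$time == time, ]
    c(row$mean[1], row$sd[1])
  }
  draw_hrsd <- function(time, floor14 = FALSE) {
    out <- integer(n_subjects)
    for (g in c("responder", "nonresponder")) {
      idx <- if (g == "responder") responder else !responder
      n_g <- sum(idx)
      if (n_g == 0) next
      par <- hp(g, time)
      vals <- pmax(0L, as.integer(round(rnorm(n_g, par[1], par[2]))))
      if (floor14) {
        bad <- vals < 14
        while (any(bad)) {
          vals[bad] <- pmax(0L, as.integer(round(rnorm(sum(bad), par[1], par[2]))))
          bad <- vals < 14
        }
      }
      out[idx] <- vals
    }
    out
  }
  hrsd0 <- draw_hrsd("t0", floor14 = TRUE)
  hrsd4 <- draw_hrsd("t4")
  hrsd8 <- draw_hrsd("t8")

  if (!is.null(symptom_coupling)) {
    m <- symptom_coupling$metabolite
    if (is.character(m)) m <- match(m, metabolite_ids)
    stopifnot(!is.na(m), m >= 1, m <= p)
    cf <- symptom_coupling$coef
    all_h <- c(hrsd0, hrsd4, hrsd8)
    std <- function(h) (h - mean(all_h)) / sd(all_h)
    z0[, m] <- z0[, m] + cf * std(hrsd0)
    z4[, m] <- z4[, m] + cf * std(hrsd4)
    z8[, m] <- z8[, m] + cf * std(hrsd8)
  }

  to_abund <- function(z) {
    a <- 2^(sweep(sweep(z, 2, sigma, "*"), 2, mu, "+"))
    dimnames(a) <- list(sprintf("S%03d", seq_len(n_subjects)), metabolite_ids)
    a
  }
  clinical <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    age = pmin(85L, pmax(18L, as.integer(round(rnorm(n_subjects, 39.8, 13.1))))),
    sex = sample(c("F", "M"), n_subjects, replace = TRUE, prob = c(0.66, 0.34)),
    drug_arm = sample(c("citalopram", "escitalopram"), n_subjects, replace = TRUE),
    hrsd_t0 = hrsd0, hrsd_t4 = hrsd4, hrsd_t8 = hrsd8,
    responder = responder,
    stringsAsFactors = FALSE
  )
  structure(list(abundances = list(t0 = to_abund(z0), t4 = to_abund(z4),
                                   t8 = to_abund(z8)),
                 clinical = clinical,
                 metabolite_ids = metabolite_ids),
            class = "cohort_dataset")
}

#' Set abundance cells missing completely at random
#'
#' Each abundance cell is independently set missing with the given
#' probability (MCAR); the clinical table is untouched. With `rate = 0` the
#' dataset is returned unchanged, and a fixed seed yields an identical
#' missingness mask on rerun.
#'
#' @param dataset A `cohort_dataset`.
#' @param rate Missingness probability in `[0, 0.5]`.
#' @param seed Integer seed.
#' @return The dataset with `NA`s injected into its abundance matrices.
#' @export
inject_missing <- function(dataset, rate, seed = 1) {
  stopifnot(inherits(dataset, "cohort_dataset"), rate >= 0, rate <= 0.5)
  if (rate == 0) return(dataset)
  set.seed(seed)
  dataset$abundances <- lapply(dataset$abundances, function(a) {
    mask <- matrix(runif(length(a)) < rate, nrow(a), ncol(a))
    a[mask] <- NA_real_
    a
  })
  dataset
}

#' Simulate biallelic genotype dosages
#'
#' Draws hard dosages in `{0, 1, 2}` binomially at per-variant minor allele
#' frequencies uniform in `maf_range` (Hardy-Weinberg proportions), with
#' optional per-variant MCAR missingness for QC testing. Causal variant
#' annotations are carried along for [simulate_trait()].
#'
#' @param n_subjects,n_variants Dimensions of the dosage matrix.
#' @param maf_range Two values in `(0, 0.5]`.
#' @param causal Optional data frame with columns `variant_index`,
#'   `trait_name`, `beta`.
#' @param missing_rate Per-cell missingness probability (default 0).
#' @param seed Integer seed.
#' @return A `genotype_matrix`: list with `dosages` (subjects x variants),
#'   `variant_meta` (id, chrom, pos, ref, alt), `causal`.
#' @export
simulate_genotypes <- function(n_subjects, n_variants,
                               maf_range = c(0.05, 0.5), causal = NULL,
                               missing_rate = 0, seed = 1) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (!is.null(causal)) {
    stopifnot(all(c("variant_index", "trait_name", "beta") %in% names(causal)))
    if (any(causal$variant_index < 1 | causal$variant_index > n_variants)) {
      stop("causal variant_index out of range 1..", n_variants)
    }
  }
  set.seed(seed)
  maf <- runif(n_variants, maf_range[1], maf_range[2])
  dos <- vapply(maf, function(f) rbinom(n_subjects, 2L, f),
                integer(n_subjects))
  dos <- matrix(as.numeric(dos), n_subjects, n_variants)
  if (missing_rate > 0) {
    dos[matrix(runif(length(dos)) < missing_rate, n_subjects, n_variants)] <- NA_real_
  }
  dimnames(dos) <- list(sprintf("S%03d", seq_len(n_subjects)),
                        sprintf("rs%06d", seq_len(n_variants)))
  meta <- data.frame(
    variant_id = colnames(dos),
    chrom = sample(1:22, n_variants, replace = TRUE),
    pos = sample.int(1e8, n_variants),
    ref = "A", alt = "G",
    maf_true = maf,
    stringsAsFactors = FALSE
  )
  structure(list(dosages = dos, variant_meta = meta, causal = causal),
            class = "genotype_matrix")
}

#' Simulate a quantitative trait from causal genotypes
#'
#' Builds `sum(beta * dosage) + N(0, noise_sd^2)` per subject from the
#' genotype object's causal annotations (missing causal dosages are
#' mean-imputed for trait construction).
#'
#' @param genotypes A `genotype_matrix`.
#' @param causal Causal table (defaults to the one stored in `genotypes`);
#'   NULL gives pure noise.
#' @param noise_sd Residual SD (default 1).
#' @param seed Integer seed.
#' @return Named numeric vector of trait values.
#' @export
simulate_trait <- function(genotypes, causal = genotypes$causal,
                           noise_sd = 1, seed = 1) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  set.seed(seed)
  n <- nrow(genotypes$dosages)
  y <- rnorm(n, 0, noise_sd)
  if (!is.null(causal) && nrow(causal)) {
    for (r in seq_len(nrow(causal))) {
      d <- genotypes$dosages[, causal$variant_index[r]]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      y <- y + causal$beta[r] * d
    }
  }
  names(y) <- rownames(genotypes$dosages)
  y
}
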