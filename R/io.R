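#' Write a cohort to plain-text files
#'
#' One abundance TSV per time point (rows = subjects, columns = metabolite
#' ids), a clinical TSV, and the ground truth (if supplied) as JSON.
#'
#' @param dataset A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @param ground_truth Optional `ground_truth` to serialise alongside.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(dataset, dir, ground_truth = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tp in names(dataset$abundances)) {
    a <- dataset$abundances[[tp]]
    df <- data.frame(subject_id = rownames(a), a, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, file.path(dir, sprintf("abundance_%s.tsv", tp)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(dataset$clinical, file.path(dir, "clinical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ground_truth)) {
    gt <- list(precision = ground_truth$precision,
               community_labels = ground_truth$community_labels,
               exposure_effects = ground_truth$exposure_effects,
               differential_edges = ground_truth$differential_edges,
               genetic_effects = ground_truth$genetic_effects)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         digits = NA, auto_unbox = TRUE, null = "null")
  }
  invisible(dir)
}

#' Read a cohort from plain-text files
#'
#' Inverse of [write_cohort()]: loads the per-time-point abundance TSVs and
#' the clinical table.
#'
#' @param dir Directory written by [write_cohort()] (or with user-supplied
#'   files in the same layout).
#' @return A `cohort_dataset`.
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "^abundance_t[0-9]+\\.tsv$")
  if (length(files) == 0) stop("no abundance_t*.tsv files in ", dir)
  tps <- sub("^abundance_(t[0-9]+)\\.tsv$", "\\1", files)
  abund <- lapply(files, function(f) {
    df <- read.delim(file.path(dir, f), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$subject_id
    m
  })
  names(abund) <- tps
  ord <- order(as.integer(sub("t", "", tps)))
  abund <- abund[ord]
  clinical <- read.delim(file.path(dir, "clinical.tsv"),
                         stringsAsFactors = FALSE)
  for (tp in names(abund)) {
    stopifnot(identical(rownames(abund[[tp]]), clinical$subject_id))
  }
  structure(list(abundances = abund, clinical = clinical,
                 metabolite_ids = colnames(abund[[1]])),
            class = "cohort_dataset")
}

#' Write genotype dosages as TSV
#'
#' Dosage TSV (rows = subjects, columns = variant ids, missing as NA) plus
#' a variant metadata TSV.
#'
#' @param G A `genotype_matrix`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_genotypes <- function(G, dir) {
  stopifnot(inherits(G, "genotype_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(subject_id = rownames(G$dosages), G$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, file.path(dir, "dosages.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(G$variant_meta, file.path(dir, "variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read genotype dosages from TSV
#'
#' @param dir Directory written by [write_genotypes()].
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(dir) {
  df <- read.delim(file.path(dir, "dosages.tsv"), check.names = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- df$subject_id
  meta <- read.delim(file.path(dir, "variants.tsv"), stringsAsFactors = FALSE)
  structure(list(dosages = d, variant_meta = meta, causal = NULL),
            class = "genotype_matrix")
}

#' Write genotypes as a minimal VCF
#'
#' GT-only, one ALT allele per record; dosage 0/1/2 maps to `0/0`, `0/1`,
#' `1/1`, missing to `./.`.
#'
#' @param G A `genotype_matrix`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_vcf <- function(G, file) {
  stopifnot(inherits(G, "genotype_matrix"))
  meta <- G$variant_meta
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(G$dosages)), collapse = "\t"))
  body <- vapply(seq_len(ncol(G$dosages)), function(j) {
    d <- G$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(meta$chrom[j], meta$pos[j], meta$variant_id[j], meta$ref[j],
            meta$alt[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read a minimal GT-only VCF into dosages
#'
#' Uses vcfR when available; dosage = count of ALT alleles.
#'
#' @param file VCF path (uncompressed).
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(file) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(file, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g) | g %in% c("./.", ".|."),
             NA_real_,
             vapply(strsplit(gsub("\\|", "/", g), "/"), function(a) {
               sum(a == "1")
             }, numeric(1)))
    }
    d <- t(apply(gt, 1, count_alt))
    d <- matrix(as.numeric(d), nrow(gt), ncol(gt),
                dimnames = list(rownames(gt), colnames(gt)))
    meta <- data.frame(variant_id = vcfR::getID(v),
                       chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
                       ref = vcfR::getREF(v), alt = vcfR::getALT(v),
                       stringsAsFactors = FALSE)
  } else {
    lines <- readLines(file)
    hdr <- grep("^#CHROM", lines)
    cols <- strsplit(lines[hdr], "\t")[[1]]
    subjects <- cols[-(1:9)]
    rows <- strsplit(lines[(hdr + 1):length(lines)], "\t")
    meta <- data.frame(
      variant_id = vapply(rows, `[`, character(1), 3),
      chrom = vapply(rows, `[`, character(1), 1),
      pos = as.integer(vapply(rows, `[`, character(1), 2)),
      ref = vapply(rows, `[`, character(1), 4),
      alt = vapply(rows, `[`, character(1), 5),
      stringsAsFactors = FALSE)
    d <- t(vapply(rows, function(r) {
      g <- gsub("\\|", "/", r[-(1:9)])
      ifelse(g == "./.", NA_real_,
             vapply(strsplit(g, "/"), function(a) sum(a == "1"), numeric(1)))
    }, numeric(length(subjects))))
    dimnames(d) <- list(meta$variant_id, subjects)
  }
  structure(list(dosages = t(d), variant_meta = meta, causal = NULL),
            class = "genotype_matrix")
}

#' Write an association table as TSV
#'
#' @param table An `association_table`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_association_table <- function(table, file) {
  write.table(as.data.frame(table), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Export a network as edge-list TSV and JSON
#'
#' Edge list columns: `node_a`, `node_b`, `weight` and (when available)
#' `inclusion_frequency`; the JSON carries the full matrices and metadata.
#'
#' @param network A `pcn` or `bootstrap_summary`.
#' @param prefix Output path prefix (writes `<prefix>_edges.tsv` and
#'   `<prefix>.json`).
#' @return The prefix, invisibly.
#' @export
write_network <- function(network, prefix) {
  w <- network_weights(network)
  labels <- colnames(w)
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  edges <- data.frame(node_a = labels[idx[, 1]], node_b = labels[idx[, 2]],
                      weight = w[idx], stringsAsFactors = FALSE)
  if (inherits(network, "bootstrap_summary")) {
    edges$inclusion_frequency <- network$inclusion_frequency[idx]
  }
  write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  payload <- unclass(network)
  jsonlite::write_json(payload, paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(prefix)
}

#' Write a processed matrix with its transform record
#'
#' Values as TSV (rows = subjects) plus a JSON sidecar recording the
#' applied preprocessing steps.
#'
#' @param pm A `processed_matrix`.
#' @param prefix Output path prefix (writes `<prefix>.tsv`,
#'   `<prefix>_log2.tsv` and `<prefix>_transform.json`).
#' @return The prefix, invisibly.
#' @export
write_processed <- function(pm, prefix) {
  stopifnot(inherits(pm, "processed_matrix"))
  for (part in c("values", "log2_values")) {
    m <- pm[[part]]
    df <- data.frame(subject_id = rownames(m) %||% seq_len(nrow(m)), m,
                     check.names = FALSE, stringsAsFactors = FALSE)
    suffix <- if (part == "values") ".tsv" else "_log2.tsv"
    write.table(df, paste0(prefix, suffix), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  jsonlite::write_json(pm$transform_log, paste0(prefix, "_transform.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a processed matrix written by [write_processed()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `processed_matrix`.
#' @export
read_processed <- function(prefix) {
  load_part <- function(suffix) {
    df <- read.delim(paste0(prefix, suffix), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$subject_id
    m
  }
  structure(list(values = load_part(".tsv"),
                 log2_values = load_part("_log2.tsv"),
                 transform_log = jsonlite::read_json(
                   paste0(prefix, "_transform.json"), simplifyVector = TRUE)),
            class = "processed_matrix")
}
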