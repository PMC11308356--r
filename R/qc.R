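#' Quality-control configuration
#'
#' Two profiles are used in practice: the ROH profile keeps every allele
#' frequency (`min_maf = NULL`) because MAF pruning removes exactly the
#' homozygous stretches ROH detection looks for, while the diversity profile
#' adds a MAF >= 0.05 filter for heterozygosity and Ne estimation.
#'
#' @param max_snp_missing_rate drop SNPs with missing-call fraction above
#'   this (default 0.10).
#' @param max_sample_missing_rate drop samples with missing fraction above
#'   this (default 0.10).
#' @param min_maf minor-allele-frequency floor, or `NULL` to disable.
#' @param profile shortcut: `"roh"` sets `min_maf = NULL`, `"diversity"`
#'   sets `min_maf = 0.05`; explicit arguments override.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(max_snp_missing_rate = 0.10,
                      max_sample_missing_rate = 0.10,
                      min_maf = NULL,
                      profile = c("roh", "diversity")) {
  profile <- match.arg(profile)
  if (missing(min_maf) && profile == "diversity") min_maf <- 0.05
  stopifnot(max_snp_missing_rate >= 0, max_snp_missing_rate <= 1,
            max_sample_missing_rate >= 0, max_sample_missing_rate <= 1,
            is.null(min_maf) || (min_maf >= 0 && min_maf <= 0.5))
  structure(list(max_snp_missing_rate = max_snp_missing_rate,
                 max_sample_missing_rate = max_sample_missing_rate,
                 min_maf = min_maf, profile = profile),
            class = "qc_config")
}

#' Apply quality control to a genotype matrix
#'
#' Filters are applied in a fixed, logged order: (1) autosome restriction
#' (already enforced by the container), (2) SNP call rate, (3) sample call
#' rate, (4) optional MAF — one pass, no iteration. MAF is computed on the
#' non-missing alleles of the matrix remaining after the call-rate filters.
#' The operation is idempotent: re-running it on its own output removes
#' nothing.
#'
#' @param g a [genotype_matrix].
#' @param cfg a [qc_config].
#' @return A list of class `qc_result` with elements `genotypes` (filtered
#'   [genotype_matrix]) and `report` (per-stage removal counts, removed
#'   sample ids).
#' @export
apply_qc <- function(g, cfg = qc_config()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "qc_config"))
  n_in <- nrow(g$calls); m_in <- ncol(g$calls)

  snp_miss <- colMeans(is.na(g$calls))
  keep_snp <- snp_miss <= cfg$max_snp_missing_rate
  n_snp_callrate <- sum(!keep_snp)
  g <- g[, keep_snp]

  samp_miss <- if (ncol(g$calls) > 0) rowMeans(is.na(g$calls)) else
    rep(0, nrow(g$calls))
  keep_samp <- samp_miss <= cfg$max_sample_missing_rate
  removed_samples <- g$samples$sample_id[!keep_samp]
  g <- g[keep_samp, ]

  n_snp_maf <- 0L
  if (!is.null(cfg$min_maf) && ncol(g$calls) > 0) {
    p <- allele_freq(g)
    maf <- pmin(p, 1 - p)
    keep_maf <- !is.na(maf) & maf >= cfg$min_maf
    n_snp_maf <- sum(!keep_maf)
    g <- g[, keep_maf]
  }

  if (nrow(g$calls) == 0L) stop("QC removed every sample")
  if (ncol(g$calls) == 0L) stop("QC removed every SNP")

  report <- list(n_snps_in = m_in, n_snps_out = ncol(g$calls),
                 n_samples_in = n_in, n_samples_out = nrow(g$calls),
                 removed = c(snp_callrate = n_snp_callrate,
                             sample_callrate = length(removed_samples),
                             snp_maf = n_snp_maf),
                 removed_sample_ids = removed_samples,
                 config = cfg)
  structure(list(genotypes = g, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat("QC:", r$n_snps_in, "->", r$n_snps_out, "SNPs;",
      r$n_samples_in, "->", r$n_samples_out, "samples\n")
  cat("  removed: SNP call-rate", r$removed[["snp_callrate"]],
      "| samples", r$removed[["sample_callrate"]],
      "| MAF", r$removed[["snp_maf"]], "\n")
  invisible(x)
}

qc_report_df <- function(x) {
  r <- x$report
  data.frame(stage = c("input", "snp_callrate", "sample_callrate", "snp_maf",
                       "output"),
             n_snps = c(r$n_snps_in, r$removed[["snp_callrate"]], 0,
                        r$removed[["snp_maf"]], r$n_snps_out),
             n_samples = c(r$n_samples_in, 0, r$removed[["sample_callrate"]],
                           0, r$n_samples_out))
}

#' Principal component analysis of genotypes
#'
#' Sample-level PCA for outlier / mix-up screening. Each SNP column is
#' standardized as `(x - 2p) / sqrt(2p(1-p))` with `p` the allele-b
#' frequency; missing calls are mean-imputed (to `2p`, i.e. zero after
#' centering) before standardization; monomorphic SNPs are excluded.
#' Coordinates are deterministic up to the sign of each axis.
#'
#' @param g a post-QC [genotype_matrix].
#' @param k number of components (>= 1).
#' @return data.frame: `sample_id`, `population`, `PC1` ... `PCk`.
#' @export
geno_pca <- function(g, k = 2) {
  stopifnot(inherits(g, "genotype_matrix"), k >= 1)
  p <- allele_freq(g)
  poly <- !is.na(p) & p > 0 & p < 1
  x <- g$calls[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(x, 2, 2 * p)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  k <- min(k, nrow(x) - 1L, ncol(x))
  sv <- svd(x, nu = k, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  colnames(pcs) <- paste0("PC", seq_len(k))
  cbind(data.frame(sample_id = g$samples$sample_id,
                   population = g$samples$population,
                   stringsAsFactors = FALSE),
        as.data.frame(pcs))
}
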