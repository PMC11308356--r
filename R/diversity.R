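#' Per-sample observed heterozygosity
#'
#' Counts heterozygous calls per sample over its non-missing genotypes.
#' Also reports the method-of-moments inbreeding estimate used by array
#' toolkits: `f_hat = (obs_hom - exp_hom) / (n - exp_hom)`, where the
#' expected homozygous count sums `1 - 2p(1-p) * 2n/(2n-1)` over the
#' sample's non-missing SNPs (small-sample-corrected expected
#' heterozygosity from the cohort allele frequencies).
#'
#' @param g a post-QC [genotype_matrix] (diversity profile).
#' @return data.frame: `sample_id`, `n_nonmissing`, `n_het`, `h_obs`,
#'   `f_hat`. Samples with zero non-missing calls get `NA` `h_obs` and are
#'   to be excluded from cohort means.
#' @export
observed_het <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  nm <- !is.na(g$calls)
  n_nonmissing <- rowSums(nm)
  n_het <- rowSums(g$calls == 1L, na.rm = TRUE)
  h_obs <- ifelse(n_nonmissing > 0, n_het / n_nonmissing, NA_real_)

  p <- allele_freq(g)
  an <- 2 * colSums(nm)                           # non-missing allele count
  eh <- ifelse(an > 1, 2 * p * (1 - p) * an / (an - 1), 0)
  eh[is.na(eh)] <- 0
  exp_hom <- nm %*% (1 - eh)
  obs_hom <- n_nonmissing - n_het
  f_hat <- ifelse(n_nonmissing - exp_hom > 0,
                  (obs_hom - exp_hom) / (n_nonmissing - exp_hom), NA_real_)
  data.frame(sample_id = g$samples$sample_id, n_nonmissing = n_nonmissing,
             n_het = n_het, h_obs = h_obs, f_hat = as.numeric(f_hat),
             stringsAsFactors = FALSE)
}

#' Cohort expected (and observed) heterozygosity
#'
#' Expected heterozygosity is the per-SNP `2p(1-p)` averaged over SNPs (the
#' quantity is per-locus by definition), optionally with the small-sample
#' correction `2n/(2n-1)` where `2n` is the SNP's non-missing allele count.
#' Monomorphic SNPs contribute zero and stay in the mean.
#'
#' @param g a post-QC [genotype_matrix].
#' @param correction `"small_sample"` (default) or `"none"`.
#' @return A list of class `cohort_het`: `mean_h_obs`, `mean_h_exp`,
#'   `n_samples`, `n_snps`.
#' @export
expected_het <- function(g, correction = c("small_sample", "none")) {
  correction <- match.arg(correction)
  p <- allele_freq(g)
  he <- 2 * p * (1 - p)
  if (correction == "small_sample") {
    an <- 2 * colSums(!is.na(g$calls))
    he <- ifelse(an > 1, he * an / (an - 1), 0)
  }
  he[is.na(he)] <- 0
  ho <- observed_het(g)
  structure(list(mean_h_obs = mean(ho$h_obs, na.rm = TRUE),
                 mean_h_exp = mean(he),
                 n_samples = nrow(g$calls), n_snps = ncol(g$calls)),
            class = "cohort_het")
}

#' @export
print.cohort_het <- function(x, ...) {
  cat(sprintf("cohort heterozygosity (%d samples, %d SNPs): H_O = %.4f, H_E = %.4f\n",
              x$n_samples, x$n_snps, x$mean_h_obs, x$mean_h_exp))
  invisible(x)
}
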