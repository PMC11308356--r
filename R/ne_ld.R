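#' Configuration for LD-decay Ne estimation
#'
#' Defaults follow common SNP-array practice for recent effective
#' population size: SNP pairs between 0.05 and 40 Mb apart, 30 equal-width
#' distance bins, mutation adjustment `alpha = 2.2`, genome-wide
#' recombination rate 1.24e-8 per bp, and a recombination-rate modifier
#' mapping map distance to recombination fraction (Sved & Feldman style by
#' default; `haldane` and `linear` are available for sensitivity checks).
#' The `1/(beta * n)` sample-size adjustment uses `beta = 1`, matching the
#' null expectation of the composite (unphased genotype) r2.
#'
#' @param min_pair_dist_bp,max_pair_dist_bp SNP-pair distance range (bp).
#' @param n_bins number of equal-width distance bins.
#' @param alpha mutation adjustment in `Ne = (1/(4c)) (1/r2_adj - alpha)`.
#' @param recomb_rate_per_bp Morgans per bp.
#' @param modifier distance-to-recombination mapping.
#' @param sample_size_beta `beta` in the `r2 - 1/(beta n)` adjustment.
#' @param min_maf MAF floor applied before pairing.
#' @param birth_years optional `c(from, to)` birth-year cohort filter.
#' @param max_pairs_per_bin optional cap on pairs per bin (subsampled with
#'   `seed`); `Inf` enumerates every pair.
#' @param seed RNG seed used only when subsampling pairs.
#' @return A list of class `ne_config`.
#' @export
ne_config <- function(min_pair_dist_bp = 50000, max_pair_dist_bp = 40e6,
                      n_bins = 30, alpha = 2.2, recomb_rate_per_bp = 1.24e-8,
                      modifier = c("sved_feldman", "haldane", "linear"),
                      sample_size_beta = 1, min_maf = 0.05,
                      birth_years = NULL, max_pairs_per_bin = Inf,
                      seed = 1L) {
  modifier <- match.arg(modifier)
  stopifnot(min_pair_dist_bp < max_pair_dist_bp, n_bins >= 1, alpha > 0,
            recomb_rate_per_bp > 0, sample_size_beta %in% c(1, 2),
            min_maf >= 0, min_maf <= 0.5)
  structure(as.list(environment()), class = "ne_config")
}

#' Map physical distance to recombination fraction
#'
#' Distance in bp is first converted to map distance
#' `d = dist_bp * recomb_rate_per_bp` (Morgans), then to a recombination
#' fraction: `linear` uses `c = d`; `haldane` uses `c = (1 - exp(-2d))/2`
#' (no crossover interference); `sved_feldman` uses the quadratic
#' approximation `c = d (1 - d/2)`, which agrees with the others to first
#' order at small d and stays below 0.5 over the usable range.
#'
#' @param dist_bp numeric vector of distances (bp).
#' @param cfg an [ne_config].
#' @return Recombination fractions.
#' @export
dist_to_c <- function(dist_bp, cfg = ne_config()) {
  d <- dist_bp * cfg$recomb_rate_per_bp
  switch(cfg$modifier,
         linear = d,
         haldane = (1 - exp(-2 * d)) / 2,
         sved_feldman = d * (1 - d / 2))
}

#' Pairwise composite r2 between SNPs
#'
#' For every intra-chromosomal SNP pair within the configured distance
#' range, the squared Pearson correlation of genotype codes across samples
#' with both calls non-missing — the composite-genotype LD measure for
#' unphased data. SNPs failing the MAF floor and pairs with fewer than two
#' complete observations are skipped.
#'
#' @param g a [genotype_matrix] (diversity-profile QC recommended).
#' @param cfg an [ne_config].
#' @return data.frame: `dist_bp`, `r2`, `n` (complete observations).
#' @export
pairwise_r2 <- function(g, cfg = ne_config()) {
  stopifnot(inherits(g, "genotype_matrix"))
  p <- allele_freq(g)
  maf_ok <- !is.na(p) & pmin(p, 1 - p) >= cfg$min_maf
  out <- list()
  for (ch in unique(g$map$chrom)) {
    jj <- which(g$map$chrom == ch & maf_ok)
    if (length(jj) < 2) next
    x <- g$calls[, jj, drop = FALSE]
    pos <- g$map$pos_bp[jj]
    suppressWarnings(
      r <- stats::cor(x, use = "pairwise.complete.obs"))
    nmat <- crossprod(!is.na(x))
    m <- length(jj)
    iu <- which(upper.tri(r))
    dist <- abs(pos[((iu - 1) %/% m) + 1] - pos[((iu - 1) %% m) + 1])
    keep <- dist >= cfg$min_pair_dist_bp & dist <= cfg$max_pair_dist_bp &
      nmat[iu] >= 2 & !is.na(r[iu])
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(dist_bp = dist[keep],
                                          r2 = r[iu][keep]^2,
                                          n = nmat[iu][keep])
  }
  if (length(out) == 0L)
    return(data.frame(dist_bp = numeric(), r2 = numeric(), n = integer()))
  do.call(rbind, out)
}

#' Bin SNP pairs by distance and apply the sample-size adjustment
#'
#' Bins partition the configured distance range into `n_bins` equal-width
#' intervals. Each pair's r2 is adjusted to `r2 - 1/(beta n)` with `n` its
#' complete-observation count, then averaged per bin. Empty bins are
#' omitted with a warning; an optional per-bin pair cap subsamples with the
#' config seed.
#'
#' @param pairs data.frame from [pairwise_r2].
#' @param cfg an [ne_config].
#' @return data.frame: `bin_index`, `mean_dist_bp`, `mean_r2_adj`,
#'   `n_pairs`.
#' @export
bin_and_adjust <- function(pairs, cfg = ne_config()) {
  breaks <- seq(cfg$min_pair_dist_bp, cfg$max_pair_dist_bp,
                length.out = cfg$n_bins + 1)
  bin <- findInterval(pairs$dist_bp, breaks, rightmost.closed = TRUE)
  bin[bin < 1 | bin > cfg$n_bins] <- NA
  pairs <- pairs[!is.na(bin), , drop = FALSE]
  bin <- bin[!is.na(bin)]
  if (is.finite(cfg$max_pairs_per_bin)) {
    set.seed(cfg$seed)
    keep <- sort(unlist(lapply(split(seq_along(bin), bin), function(ix) {
      if (length(ix) <= cfg$max_pairs_per_bin) ix
      else sample(ix, cfg$max_pairs_per_bin)
    })))
    pairs <- pairs[keep, , drop = FALSE]
    bin <- bin[keep]
  }
  r2_adj <- pairs$r2 - 1 / (cfg$sample_size_beta * pairs$n)
  got <- sort(unique(bin))
  if (length(got) < cfg$n_bins)
    warning(cfg$n_bins - length(got), " empty distance bin(s) omitted")
  data.frame(bin_index = got,
             mean_dist_bp = as.numeric(tapply(pairs$dist_bp, bin, mean)),
             mean_r2_adj = as.numeric(tapply(r2_adj, bin, mean)),
             n_pairs = as.integer(table(bin)))
}

#' Effective population size trajectory from binned LD
#'
#' Each distance bin maps to a recombination fraction `c` ([dist_to_c] on
#' its mean distance), a time `t = 1/(2c)` generations ago, and an estimate
#' `Ne = (1/(4c)) (1/mean_r2_adj - alpha)`. Bins with non-positive adjusted
#' r2 or negative Ne are excluded with a warning. Points are ordered newest
#' (largest c) to oldest.
#'
#' @param bins data.frame from [bin_and_adjust].
#' @param cfg an [ne_config].
#' @return data.frame of class `ne_trajectory`: `bin_index`,
#'   `mean_dist_bp`, `c`, `t_generations`, `mean_r2_adj`, `n_pairs`, `ne`.
#' @export
ne_from_bins <- function(bins, cfg = ne_config()) {
  cc <- dist_to_c(bins$mean_dist_bp, cfg)
  ok <- bins$mean_r2_adj > 0
  ne <- rep(NA_real_, nrow(bins))
  ne[ok] <- (1 / (4 * cc[ok])) * (1 / bins$mean_r2_adj[ok] - cfg$alpha)
  drop <- !ok | ne < 0
  if (any(drop))
    warning(sum(drop), " bin(s) dropped (non-positive adjusted r2 or negative Ne)")
  out <- data.frame(bin_index = bins$bin_index,
                    mean_dist_bp = bins$mean_dist_bp, c = cc,
                    t_generations = 1 / (2 * cc),
                    mean_r2_adj = bins$mean_r2_adj,
                    n_pairs = bins$n_pairs, ne = ne)[!drop, , drop = FALSE]
  out <- out[order(out$c, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, config = cfg, class = c("ne_trajectory", "data.frame"))
}

#' Estimate the recent Ne trajectory from genotypes
#'
#' Convenience wrapper: optional birth-year cohort filter, then
#' [pairwise_r2] -> [bin_and_adjust] -> [ne_from_bins]. The estimator
#' itself involves no sampling, so the trajectory is deterministic for a
#' fixed input and config.
#'
#' @param g a [genotype_matrix] (diversity-profile QC recommended).
#' @param cfg an [ne_config].
#' @return An `ne_trajectory` data.frame (see [ne_from_bins]).
#' @export
estimate_ne <- function(g, cfg = ne_config()) {
  if (!is.null(cfg$birth_years)) {
    by <- g$samples$birth_year
    keep <- !is.na(by) & by >= cfg$birth_years[1] & by <= cfg$birth_years[2]
    if (!any(keep)) stop("no samples in the birth-year cohort")
    g <- g[keep, ]
  }
  ne_from_bins(bin_and_adjust(pairwise_r2(g, cfg), cfg), cfg)
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("Ne trajectory:", nrow(x), "points; most recent (t =",
      round(x$t_generations[1], 2), "generations) Ne =",
      round(x$ne[1], 1), "\n")
  invisible(x)
}
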