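#' Sliding-window ROH detection parameters
#'
#' Defaults reproduce a conservative 670K-array scan: a 10-SNP scanning
#' window tolerating no heterozygous or missing call, a per-SNP
#' in-run proportion threshold of 0.05, runs split at inter-SNP gaps over
#' 100 kb, and run-level filters of >= 10 SNPs, >= 100 kb, >= 0.05 SNP/kb
#' density, and at most one heterozygous and one missing call per run.
#' The 500 kb `min_length_bp` variant is the usual sensitivity re-run.
#'
#' @param window_size SNPs per scanning window.
#' @param window_max_het,window_max_miss maximum heterozygous / missing
#'   calls for a window to count as homozygous.
#' @param snp_inrun_threshold a SNP enters a run when the proportion of
#'   homozygous windows covering it exceeds this.
#' @param max_gap_bp split candidate runs at larger inter-SNP gaps.
#' @param min_density_snp_per_kb minimum SNPs per kb within a run.
#' @param min_snp minimum SNPs per run.
#' @param min_length_bp minimum run length (bp); length is
#'   `end_bp - start_bp`.
#' @param run_max_het,run_max_miss run-level tolerance, applied as a
#'   post-filter on candidate runs.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_size = 10, window_max_het = 0,
                       window_max_miss = 0, snp_inrun_threshold = 0.05,
                       max_gap_bp = 100000, min_density_snp_per_kb = 0.05,
                       min_snp = 10, min_length_bp = 100000,
                       run_max_het = 1, run_max_miss = 1) {
  stopifnot(window_size >= 1, window_max_het >= 0, window_max_miss >= 0,
            snp_inrun_threshold >= 0, snp_inrun_threshold < 1,
            max_gap_bp > 0, min_density_snp_per_kb >= 0, min_snp >= 1,
            min_length_bp > 0, run_max_het >= 0, run_max_miss >= 0)
  structure(as.list(environment()), class = "roh_params")
}

roh_class_breaks <- c(0, 1, 2, 4, 8, Inf)
roh_class_labels <- c("0.1-1", "1-2", "2-4", "4-8", ">8")

roh_length_class <- function(length_bp) {
  cut(length_bp / 1e6, breaks = roh_class_breaks, labels = roh_class_labels,
      right = TRUE)
}

#' Window homozygosity flags for one sample on one chromosome
#'
#' Every contiguous block of `window_size` SNPs (stride 1) is a window; a
#' window is homozygous iff its heterozygous-call count is at most
#' `window_max_het` and its missing-call count at most `window_max_miss`.
#'
#' @param calls integer vector of calls (0/1/2/`NA`) ordered by position.
#' @param params a [roh_params].
#' @return Logical vector of length `length(calls) - window_size + 1`
#'   (empty when the chromosome has fewer SNPs than the window).
#' @export
window_homozygosity <- function(calls, params = roh_params()) {
  m <- length(calls); w <- params$window_size
  if (m < w) return(logical(0))
  het <- as.integer(!is.na(calls) & calls == 1L)
  mis <- as.integer(is.na(calls))
  roll <- function(x) {
    cs <- cumsum(x)
    cs[w:m] - c(0, cs[seq_len(m - w)])
  }
  roll(het) <= params$window_max_het & roll(mis) <= params$window_max_miss
}

#' Per-SNP in-run flags from window flags
#'
#' For each SNP the proportion of homozygous windows among the windows that
#' cover it is computed with the actual covering-window count as denominator
#' (SNPs near chromosome ends are covered by fewer windows; no padding).
#' The SNP is flagged when the proportion exceeds `snp_inrun_threshold`;
#' SNPs covered by no window are flagged `FALSE`.
#'
#' @param window_flags output of [window_homozygosity].
#' @param n_snp number of SNPs on the chromosome.
#' @param params a [roh_params].
#' @return Logical vector of length `n_snp`.
#' @export
snp_inrun_flags <- function(window_flags, n_snp, params = roh_params()) {
  w <- params$window_size
  nw <- length(window_flags)
  if (nw == 0L) return(rep(FALSE, n_snp))
  j <- seq_len(n_snp)
  lo <- pmax(1L, j - w + 1L)                 # first window covering SNP j
  hi <- pmin(j, nw)                          # last window covering SNP j
  cs <- c(0, cumsum(window_flags))
  hom <- cs[hi + 1L] - cs[lo]
  cov <- hi - lo + 1L
  ok <- cov > 0L
  flag <- rep(FALSE, n_snp)
  flag[ok] <- hom[ok] / cov[ok] > params$snp_inrun_threshold
  flag
}

#' Assemble runs of homozygosity from per-SNP flags
#'
#' Maximal stretches of consecutive flagged SNPs are candidate runs;
#' candidates are split wherever consecutive SNP spacing exceeds
#' `max_gap_bp`, and each piece survives iff it meets `min_snp`,
#' `min_length_bp`, `min_density_snp_per_kb`, `run_max_het` and
#' `run_max_miss`. Run coordinates are the first and last SNP positions;
#' length is `end_bp - start_bp`.
#'
#' @param snp_flags logical vector from [snp_inrun_flags].
#' @param calls aligned call vector.
#' @param positions aligned 1-based bp positions (strictly increasing).
#' @param params a [roh_params].
#' @return data.frame of runs: `start_bp`, `end_bp`, `length_bp`, `n_snp`,
#'   `n_het`, `n_miss`, `class`.
#' @export
call_runs <- function(snp_flags, calls, positions, params = roh_params()) {
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      length_bp = integer(), n_snp = integer(),
                      n_het = integer(), n_miss = integer(),
                      class = roh_length_class(numeric()))
  if (!any(snp_flags)) return(empty)
  r <- rle(snp_flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- vector("list", sum(r$values))
  k <- 0L
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]
    idx <- s:e
    # split at gaps
    gap_after <- which(diff(positions[idx]) > params$max_gap_bp)
    piece_start <- c(s, s + gap_after)
    piece_end <- c(s + gap_after - 1L, e)
    for (p in seq_along(piece_start)) {
      ps <- piece_start[p]; pe <- piece_end[p]
      n_snp <- pe - ps + 1L
      len <- positions[pe] - positions[ps]
      if (n_snp < params$min_snp || len < params$min_length_bp) next
      if (len > 0 && n_snp / (len / 1000) < params$min_density_snp_per_kb) next
      seg <- calls[ps:pe]
      n_het <- sum(seg == 1L, na.rm = TRUE)
      n_miss <- sum(is.na(seg))
      if (n_het > params$run_max_het || n_miss > params$run_max_miss) next
      k <- k + 1L
      out[[k]] <- data.frame(start_bp = positions[ps], end_bp = positions[pe],
                             length_bp = len, n_snp = n_snp, n_het = n_het,
                             n_miss = n_miss)
    }
  }
  if (k == 0L) return(empty)
  res <- do.call(rbind, out[seq_len(k)])
  res$class <- roh_length_class(res$length_bp)
  res
}

#' Detect runs of homozygosity
#'
#' Applies the sliding-window scan ([window_homozygosity] ->
#' [snp_inrun_flags] -> [call_runs]) to every sample and chromosome of a
#' genotype matrix. The input should carry ROH-profile QC (call-rate filters
#' only, no MAF pruning). Output is deterministic for a fixed input.
#'
#' @param g a [genotype_matrix].
#' @param params a [roh_params].
#' @return A data.frame of class `roh_set`: `sample_id`, `chrom`,
#'   `start_bp`, `end_bp`, `length_bp`, `n_snp`, `n_het`, `n_miss`,
#'   `class`; the parameter set and the full sample registry travel as
#'   attributes `params` and `samples`.
#' @export
detect_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(params, "roh_params"))
  chroms <- unique(g$map$chrom)
  chunks <- list()
  for (ch in chroms) {
    jj <- which(g$map$chrom == ch)
    pos <- g$map$pos_bp[jj]
    for (i in seq_len(nrow(g$calls))) {
      calls <- g$calls[i, jj]
      wf <- window_homozygosity(calls, params)
      fl <- snp_inrun_flags(wf, length(calls), params)
      runs <- call_runs(fl, calls, pos, params)
      if (nrow(runs) > 0) {
        runs <- cbind(data.frame(sample_id = g$samples$sample_id[i],
                                 chrom = ch, stringsAsFactors = FALSE),
                      runs)
        chunks[[length(chunks) + 1L]] <- runs
      }
    }
  }
  res <- if (length(chunks)) do.call(rbind, chunks) else
    cbind(data.frame(sample_id = character(), chrom = character(),
                     stringsAsFactors = FALSE),
          call_runs(logical(0), integer(0), integer(0), params))
  rownames(res) <- NULL
  structure(res, params = params, samples = g$samples,
            class = c("roh_set", "data.frame"))
}

#' @export
print.roh_set <- function(x, ...) {
  cat("roh_set:", nrow(x), "runs in",
      length(unique(x$sample_id)), "of", nrow(attr(x, "samples")),
      "samples\n")
  if (nrow(x) > 0) {
    cat("  mean length:", round(mean(x$length_bp) / 1e6, 3), "Mb; classes:\n")
    print(table(x$class))
  }
  invisible(x)
}

#' @export
summary.roh_set <- function(object, ...) descriptive_table(object)
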