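#' Autosomal genome lengths covered by the marker map
#'
#' Per-chromosome covered length is last SNP bp minus first SNP bp; the
#' autosomal total `L_auto` is their sum unless pinned to a constant (e.g.
#' 2281 Mb for a 670K equine array map) for replication of published
#' F_ROH values.
#'
#' @param map marker map of a [genotype_matrix] (or the object itself).
#' @param L_auto optional override for the autosomal total, in bp.
#' @return A list of class `genome_lengths`: `per_chrom` (named bp vector)
#'   and `L_auto` (bp).
#' @export
genome_lengths <- function(map, L_auto = NULL) {
  if (inherits(map, "genotype_matrix")) map <- map$map
  spans <- tapply(map$pos_bp, map$chrom, function(p) max(p) - min(p))
  per_chrom <- as.numeric(spans)
  names(per_chrom) <- names(spans)
  if (is.null(L_auto)) L_auto <- sum(per_chrom)
  stopifnot(L_auto > 0)
  structure(list(per_chrom = per_chrom, L_auto = L_auto),
            class = "genome_lengths")
}

#' Genomic inbreeding coefficients from ROH
#'
#' `F_ROH` is each individual's summed ROH length divided by the autosomal
#' genome length, computed genome-wide, per length class and per chromosome
#' (the chromosome values use the corresponding chromosome's covered
#' length). Samples with no runs get zero. Per-class values sum exactly to
#' the total because every run falls in exactly one class.
#'
#' @param runs a `roh_set` from [detect_roh] (or a compatible data.frame).
#' @param samples sample registry data.frame with `sample_id`; defaults to
#'   the registry attached to `runs`.
#' @param lengths a [genome_lengths].
#' @return A list of class `froh_table`: `by_sample` (data.frame with
#'   `froh_total` and one `froh_<class>` column per length class),
#'   `by_chromosome` (samples x chromosomes matrix) and `summary`
#'   (mean/min/max/sd of the total and each class over samples).
#' @export
froh <- function(runs, samples = attr(runs, "samples"), lengths) {
  stopifnot(!is.null(samples), inherits(lengths, "genome_lengths"))
  ids <- samples$sample_id
  bad <- setdiff(unique(runs$chrom), names(lengths$per_chrom))
  if (length(bad))
    stop("runs on chromosome(s) absent from genome lengths: ",
         paste(bad, collapse = ", "))
  sum_by <- function(sub) {
    v <- tapply(sub$length_bp, factor(sub$sample_id, levels = ids), sum)
    v[is.na(v)] <- 0
    as.numeric(v)
  }
  total <- sum_by(runs) / lengths$L_auto
  by_class <- sapply(roh_class_labels, function(cl)
    sum_by(runs[runs$class == cl, , drop = FALSE]) / lengths$L_auto)
  if (length(ids) == 1L) by_class <- matrix(by_class, nrow = 1,
                                            dimnames = list(NULL, roh_class_labels))
  colnames(by_class) <- paste0("froh_", roh_class_labels)
  chroms <- names(lengths$per_chrom)
  by_chrom <- sapply(chroms, function(ch)
    sum_by(runs[runs$chrom == ch, , drop = FALSE]) / lengths$per_chrom[[ch]])
  if (length(ids) == 1L) by_chrom <- matrix(by_chrom, nrow = 1,
                                            dimnames = list(NULL, chroms))
  rownames(by_chrom) <- ids
  by_sample <- cbind(data.frame(sample_id = ids, froh_total = total,
                                stringsAsFactors = FALSE),
                     as.data.frame(by_class))
  stats <- function(v) c(mean = mean(v), min = min(v), max = max(v),
                         sd = stats::sd(v))
  summ <- rbind(total = stats(total),
                t(apply(by_class, 2, stats)))
  structure(list(by_sample = by_sample, by_chromosome = by_chrom,
                 summary = summ, L_auto = lengths$L_auto),
            class = "froh_table")
}

#' @export
print.froh_table <- function(x, ...) {
  cat("F_ROH over", nrow(x$by_sample), "samples (L_auto =",
      round(x$L_auto / 1e6), "Mb)\n")
  print(round(x$summary, 4))
  invisible(x)
}

#' Descriptive ROH table by length class
#'
#' One row per length class (and per population when the sample registry
#' carries labels): number of animals with at least one run in the class,
#' run count, the class's share of all runs, mean runs per animal in the
#' class, and mean run length in Mb.
#'
#' @param runs a `roh_set` from [detect_roh].
#' @param samples sample registry; defaults to the one attached to `runs`.
#' @return data.frame: `population`, `class`, `n_ind`, `n_roh`, `roh_pct`,
#'   `s_roh`, `l_roh_mb`.
#' @export
descriptive_table <- function(runs, samples = attr(runs, "samples")) {
  stopifnot(!is.null(samples))
  pop_of <- samples$population
  if (all(is.na(pop_of))) pop_of <- rep("all", nrow(samples))
  run_pop <- pop_of[match(runs$sample_id, samples$sample_id)]
  out <- list()
  for (pop in unique(pop_of)) {
    rr <- runs[run_pop %in% pop, , drop = FALSE]
    tot <- nrow(rr)
    for (cl in roh_class_labels) {
      cc <- rr[rr$class == cl, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        population = pop, class = cl,
        n_ind = length(unique(cc$sample_id)),
        n_roh = nrow(cc),
        roh_pct = if (tot > 0) 100 * nrow(cc) / tot else 0,
        s_roh = if (length(unique(cc$sample_id)) > 0)
          nrow(cc) / length(unique(cc$sample_id)) else 0,
        l_roh_mb = if (nrow(cc) > 0) mean(cc$length_bp) / 1e6 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-SNP ROH incidence
#'
#' For every SNP, the fraction of the population's individuals having at
#' least one run whose interval covers the SNP position. The denominator is
#' all samples in the registry, not only samples with runs.
#'
#' @param runs a `roh_set` from [detect_roh].
#' @param g the [genotype_matrix] the runs were called on (its marker map
#'   defines the SNP grid).
#' @param samples sample registry; defaults to the one attached to `runs`.
#' @return data.frame of class `roh_incidence`: `chrom`, `id`, `pos_bp`,
#'   `incidence`.
#' @export
island_incidence <- function(runs, g, samples = attr(runs, "samples")) {
  stopifnot(inherits(g, "genotype_matrix"), !is.null(samples))
  n <- nrow(samples)
  inc <- numeric(nrow(g$map))
  for (ch in unique(g$map$chrom)) {
    jj <- which(g$map$chrom == ch)
    pos <- g$map$pos_bp[jj]
    rr <- runs[runs$chrom == ch, , drop = FALSE]
    if (nrow(rr) == 0L) next
    cnt <- numeric(length(pos) + 1L)
    # runs of one sample on one chromosome are disjoint, so counting
    # covering runs counts covering samples
    lo <- findInterval(rr$start_bp - 1L, pos) + 1L  # first SNP >= start
    hi <- findInterval(rr$end_bp, pos)              # last SNP <= end
    ok <- lo <= hi
    for (k in which(ok)) {
      cnt[lo[k]] <- cnt[lo[k]] + 1
      cnt[hi[k] + 1L] <- cnt[hi[k] + 1L] - 1
    }
    inc[jj] <- cumsum(cnt[-length(cnt)]) / n
  }
  structure(data.frame(chrom = g$map$chrom, id = g$map$id,
                       pos_bp = g$map$pos_bp, incidence = inc,
                       stringsAsFactors = FALSE),
            class = c("roh_incidence", "data.frame"))
}

#' Call ROH islands from an incidence track
#'
#' Islands are maximal stretches of consecutive SNPs whose incidence is
#' strictly above the threshold ("shared by over 70%" with the default);
#' coordinates are the first and last SNP of the stretch.
#'
#' @param incidence a `roh_incidence` data.frame from [island_incidence].
#' @param threshold incidence threshold (strict `>`), default 0.70.
#' @return data.frame: `chrom`, `start_bp`, `end_bp`, `length_kb`, `n_snp`,
#'   `peak_incidence`, `threshold`.
#' @export
call_islands <- function(incidence, threshold = 0.70) {
  out <- list()
  for (ch in unique(incidence$chrom)) {
    sub <- incidence[incidence$chrom == ch, , drop = FALSE]
    above <- sub$incidence > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      s <- starts[i]; e <- ends[i]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = sub$pos_bp[s], end_bp = sub$pos_bp[e],
        length_kb = (sub$pos_bp[e] - sub$pos_bp[s]) / 1000,
        n_snp = e - s + 1L,
        peak_incidence = max(sub$incidence[s:e]),
        threshold = threshold, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), length_kb = numeric(),
                      n_snp = integer(), peak_incidence = numeric(),
                      threshold = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Overlap two island sets
#'
#' Reports every pair of islands (one from each set) with positive bp
#' overlap on the same chromosome — the cross-population comparison of
#' selection signatures.
#'
#' @param a,b island data.frames from [call_islands].
#' @return data.frame: `chrom`, `a_start_bp`, `a_end_bp`, `b_start_bp`,
#'   `b_end_bp`, `shared_start_bp`, `shared_end_bp`, `overlap_bp`.
#' @export
overlap_islands <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    s <- max(a$start_bp[i], b$start_bp[j])
    e <- min(a$end_bp[i], b$end_bp[j])
    if (e <= s) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = a$chrom[i], a_start_bp = a$start_bp[i], a_end_bp = a$end_bp[i],
      b_start_bp = b$start_bp[j], b_end_bp = b$end_bp[j],
      shared_start_bp = s, shared_end_bp = e, overlap_bp = e - s,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), a_start_bp = integer(),
                      a_end_bp = integer(), b_start_bp = integer(),
                      b_end_bp = integer(), shared_start_bp = integer(),
                      shared_end_bp = integer(), overlap_bp = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Genome fraction where the ROH settings can detect a run
#'
#' Genotype-free validation of the scan settings against the marker map:
#' maximal SNP stretches with all inter-SNP gaps at most `max_gap_bp` are
#' formed, and each stretch meeting `min_snp`, `min_length_bp` and the
#' density floor contributes its bp span. The returned fraction is the
#' summed contribution over `L_auto`; values near 1 indicate the map
#' supports detection almost everywhere.
#'
#' @param map marker map (or [genotype_matrix]).
#' @param params a [roh_params].
#' @param lengths a [genome_lengths]; defaults to map-derived lengths.
#' @return Fraction of `L_auto` in which a run could be detected.
#' @export
coverage_validation <- function(map, params = roh_params(),
                                lengths = genome_lengths(map)) {
  if (inherits(map, "genotype_matrix")) map <- map$map
  detectable <- 0
  for (ch in unique(map$chrom)) {
    pos <- sort(map$pos_bp[map$chrom == ch])
    cut_after <- which(diff(pos) > params$max_gap_bp)
    st <- c(1L, cut_after + 1L)
    en <- c(cut_after, length(pos))
    for (k in seq_along(st)) {
      n_snp <- en[k] - st[k] + 1L
      len <- pos[en[k]] - pos[st[k]]
      if (n_snp < params$min_snp || len < params$min_length_bp) next
      if (len > 0 && n_snp / (len / 1000) < params$min_density_snp_per_kb) next
      detectable <- detectable + len
    }
  }
  detectable / lengths$L_auto
}

#' Correlation between genomic and pedigree inbreeding
#'
#' Pearson correlation (with the two-sided t-test p-value) between
#' per-sample F_ROH and F_PED over matched ids.
#'
#' @param froh named numeric vector or data.frame with `sample_id` and a
#'   value column (`froh_total` or `value`).
#' @param fped same structure for the pedigree coefficients.
#' @return list: `r`, `p_value`, `n`.
#' @export
froh_fped_correlation <- function(froh, fped) {
  as_named <- function(x, cols) {
    if (is.data.frame(x)) {
      val <- intersect(cols, names(x))[1]
      stats::setNames(x[[val]], x$sample_id)
    } else x
  }
  froh <- as_named(froh, c("froh_total", "value"))
  fped <- as_named(fped, c("f_ped", "value"))
  ids <- intersect(names(froh), names(fped))
  if (length(ids) < 3) stop("need at least 3 matched samples")
  ct <- stats::cor.test(froh[ids], fped[ids], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(ids))
}
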