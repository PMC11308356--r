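# Independent brute-force oracles used to check the package's fast paths.
# Everything here is written with plain nested loops and direct definitions,
# deliberately avoiding the vectorized machinery in R/.

# window status by explicit enumeration
oracle_window_flags <- function(calls, params) {
  m <- length(calls); w <- params$window_size
  if (m < w) return(logical(0))
  flags <- logical(m - w + 1)
  for (i in seq_len(m - w + 1)) {
    seg <- calls[i:(i + w - 1)]
    flags[i] <- sum(seg == 1, na.rm = TRUE) <= params$window_max_het &&
      sum(is.na(seg)) <= params$window_max_miss
  }
  flags
}

# per-SNP flag: proportion of homozygous windows among covering windows
oracle_snp_flags <- function(calls, params) {
  m <- length(calls)
  win <- oracle_window_flags(calls, params)
  flags <- rep(FALSE, m)
  for (j in seq_len(m)) {
    cov <- c()
    for (i in seq_along(win)) {
      if (i <= j && j <= i + params$window_size - 1) cov <- c(cov, win[i])
    }
    if (length(cov) > 0)
      flags[j] <- (sum(cov) / length(cov)) > params$snp_inrun_threshold
  }
  flags
}

# exhaustive interval enumeration: an interval is a candidate iff all its
# SNPs are flagged, no internal gap exceeds max_gap_bp, and it cannot be
# extended in either direction without breaking one of those two rules;
# candidates then pass the run-level filters
oracle_runs <- function(calls, pos, params) {
  m <- length(calls)
  flags <- oracle_snp_flags(calls, params)
  ok_pair <- function(i, j) {
    if (!all(flags[i:j])) return(FALSE)
    if (j > i && any(diff(pos[i:j]) > params$max_gap_bp)) return(FALSE)
    TRUE
  }
  res <- list()
  for (i in seq_len(m)) for (j in i:m) {
    if (!ok_pair(i, j)) next
    extendable <- (i > 1 && ok_pair(i - 1, j)) || (j < m && ok_pair(i, j + 1))
    if (extendable) next
    n_snp <- j - i + 1
    len <- pos[j] - pos[i]
    if (n_snp < params$min_snp || len < params$min_length_bp) next
    if (len > 0 && n_snp / (len / 1000) < params$min_density_snp_per_kb) next
    seg <- calls[i:j]
    if (sum(seg == 1, na.rm = TRUE) > params$run_max_het) next
    if (sum(is.na(seg)) > params$run_max_miss) next
    res[[length(res) + 1]] <- data.frame(start_bp = pos[i], end_bp = pos[j],
                                         length_bp = pos[j] - pos[i],
                                         n_snp = n_snp)
  }
  if (length(res) == 0)
    return(data.frame(start_bp = integer(), end_bp = integer(),
                      length_bp = integer(), n_snp = integer()))
  do.call(rbind, res)
}

# random single-chromosome ROH instance (calls + positions + parameters)
random_roh_instance <- function() {
  m <- sample(1:50, 1)
  calls <- sample(c(0L, 0L, 0L, 2L, 2L, 1L, NA), m, replace = TRUE)
  pos <- cumsum(sample(c(rep(2000, 8), 50000, 200000), m, replace = TRUE))
  params <- roh_params(
    window_size = sample(2:6, 1),
    window_max_het = sample(0:1, 1),
    window_max_miss = sample(0:1, 1),
    snp_inrun_threshold = sample(c(0, 0.05, 0.3), 1),
    max_gap_bp = sample(c(60000, 100000), 1),
    min_density_snp_per_kb = sample(c(0, 0.05), 1),
    min_snp = sample(2:6, 1),
    min_length_bp = sample(c(5000, 20000), 1),
    run_max_het = sample(0:2, 1),
    run_max_miss = sample(0:2, 1))
  list(calls = calls, pos = pos, params = params)
}

# run detection through the package pipeline on one chromosome
detect_one <- function(calls, pos, params) {
  wf <- window_homozygosity(calls, params)
  fl <- snp_inrun_flags(wf, length(calls), params)
  call_runs(fl, calls, pos, params)
}

# path-counting inbreeding oracle: F = sum over common ancestors and
# non-overlapping ancestor-path pairs of (1/2)^(n1+n2+1) (1+F_A)
oracle_fped <- function(p) {
  idx <- stats::setNames(seq_len(nrow(p)), p$id)
  fmemo <- rep(NA_real_, nrow(p))
  paths_up <- function(i) {
    res <- list(c(i))
    for (par in c(p$sire[i], p$dam[i])) {
      if (is.na(par)) next
      for (pp in paths_up(idx[[par]])) res[[length(res) + 1]] <- c(i, pp)
    }
    res
  }
  f_of <- function(i) {
    if (!is.na(fmemo[i])) return(fmemo[i])
    s <- p$sire[i]; d <- p$dam[i]
    if (is.na(s) || is.na(d)) {
      fmemo[i] <<- 0
      return(0)
    }
    ps <- paths_up(idx[[s]])
    pd <- paths_up(idx[[d]])
    f <- 0
    for (p1 in ps) for (p2 in pd) {
      a <- p1[length(p1)]
      if (a != p2[length(p2)]) next
      if (length(intersect(p1[-length(p1)], p2[-length(p2)])) > 0) next
      f <- f + 0.5^(length(p1) + length(p2) - 1) * (1 + f_of(a))
    }
    fmemo[i] <<- f
    f
  }
  stats::setNames(vapply(seq_len(nrow(p)), f_of, numeric(1)), p$id)
}

# layered random pedigree: g generations of fixed size, parents drawn from
# the previous generation (bounded depth keeps path enumeration tractable)
random_layered_pedigree <- function(n_gen = 5, per_gen = 20) {
  recs <- data.frame(id = paste0("A0_", seq_len(per_gen)),
                     sire = NA_character_, dam = NA_character_,
                     stringsAsFactors = FALSE)
  prev <- recs$id
  for (g in seq_len(n_gen - 1)) {
    ids <- paste0("A", g, "_", seq_len(per_gen))
    sire <- sample(prev, per_gen, replace = TRUE)
    dam <- sample(prev, per_gen, replace = TRUE)
    clash <- sire == dam
    while (any(clash)) {
      dam[clash] <- sample(prev, sum(clash), replace = TRUE)
      clash <- sire == dam
    }
    recs <- rbind(recs, data.frame(id = ids, sire = sire, dam = dam,
                                   stringsAsFactors = FALSE))
    prev <- ids
  }
  pedigree(recs)
}

# tiny genotype_matrix builder for hand fixtures
toy_genotypes <- function(calls, pos = NULL, chrom = "1", ids = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 10000L
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(calls)))
  genotype_matrix(calls,
                  data.frame(chrom = rep(chrom, length.out = m),
                             id = paste0("m", seq_len(m)), pos_bp = pos,
                             stringsAsFactors = FALSE),
                  ids)
}
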