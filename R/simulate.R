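#' Simulation configuration
#'
#' Describes an array-like genotyping experiment at desk scale while
#' keeping the marker density of a 670K equine array on a 2281 Mb genome
#' (about 0.29 SNP/kb): by default 10 chromosomes of 17 Mb carrying 5,000
#' jittered SNPs each. Founder allele frequencies are drawn from a
#' configurable law (uniform MAF by default; `beta` for a Beta(a, b)
#' spectrum), recombination follows the same genome-wide rate assumed by
#' the Ne estimator, and genotyping noise (missingness, call errors) is
#' injected after the identity-by-descent truth is recorded.
#'
#' @param n_chromosomes number of autosomes.
#' @param chromosome_length_bp chromosome length (bp).
#' @param n_snps_per_chrom SNPs per chromosome.
#' @param spacing `"jittered"` (uniform grid with random offsets) or
#'   `"uniform"`.
#' @param freq_law `"uniform"` (MAF uniform on `[maf_min, 0.5]`), `"beta"`
#'   (allele-b frequency ~ Beta(`beta_a`, `beta_b`)) or `"fixed"`
#'   (all frequencies `fixed_p`).
#' @param maf_min,beta_a,beta_b,fixed_p frequency-law parameters.
#' @param recomb_rate_per_bp Morgans per bp (default 1.24e-8).
#' @param missing_rate,genotype_error_rate genotyping noise rates.
#' @param seed RNG seed (mandatory: every generator is deterministic
#'   given the config).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 10, chromosome_length_bp = 17e6,
                       n_snps_per_chrom = 5000,
                       spacing = c("jittered", "uniform"),
                       freq_law = c("uniform", "beta", "fixed"),
                       maf_min = 0.05, beta_a = 2, beta_b = 2,
                       fixed_p = 0.5, recomb_rate_per_bp = 1.24e-8,
                       missing_rate = 0, genotype_error_rate = 0, seed) {
  spacing <- match.arg(spacing)
  freq_law <- match.arg(freq_law)
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(n_chromosomes >= 1, chromosome_length_bp > 0,
            n_snps_per_chrom >= 1, missing_rate >= 0, missing_rate <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1)
  seed <- as.integer(seed)
  structure(as.list(environment()), class = "sim_config")
}

sim_map <- function(cfg) {
  maps <- lapply(seq_len(cfg$n_chromosomes), function(ch) {
    m <- cfg$n_snps_per_chrom
    step <- cfg$chromosome_length_bp / m
    pos <- if (cfg$spacing == "uniform") round(step * (seq_len(m) - 0.5))
    else sort(round(step * (seq_len(m) - 1) + stats::runif(m, 1, step)))
    pos <- pmax(1, pos)
    pos <- unique(pos)
    data.frame(chrom = as.character(ch),
               id = sprintf("snp_%d_%d", ch, seq_along(pos)),
               pos_bp = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

sim_freqs <- function(cfg, m) {
  switch(cfg$freq_law,
         uniform = stats::runif(m, cfg$maf_min, 0.5),
         beta = stats::rbeta(m, cfg$beta_a, cfg$beta_b),
         fixed = rep(cfg$fixed_p, m))
}

#' Simulate a founder haplotype pool
#'
#' Draws a marker map and founder haplotypes site-wise independently from
#' the configured allele-frequency law. Each founder chromosome copy gets
#' a unique haplotype id (1 .. 2 * n_founders) so identity-by-descent can
#' be tracked exactly through later gene dropping.
#'
#' @param cfg a [sim_config].
#' @param n_founders number of diploid founders.
#' @return A list of class `founder_pool`: `map`, `freqs`, `haps`
#'   (markers x 2 * n_founders 0/1 matrix), `n_founders`, `cfg`.
#' @export
simulate_founders <- function(cfg, n_founders) {
  set.seed(cfg$seed)
  map <- sim_map(cfg)
  m <- nrow(map)
  p <- sim_freqs(cfg, m)
  haps <- matrix(stats::rbinom(m * 2 * n_founders, 1, rep(p, 2 * n_founders)),
                 nrow = m)
  structure(list(map = map, freqs = p, haps = haps,
                 n_founders = n_founders, cfg = cfg),
            class = "founder_pool")
}

#' Genotypes of the founder pool
#'
#' Pairs each founder's two haplotypes into diploid genotype calls — a
#' Hardy-Weinberg cohort drawn exactly from the configured frequency law.
#'
#' @param founders a `founder_pool` from [simulate_founders].
#' @return A [genotype_matrix] with one sample per founder.
#' @export
founder_genotypes <- function(founders) {
  n <- founders$n_founders
  calls <- t(founders$haps[, 2 * seq_len(n) - 1, drop = FALSE] +
               founders$haps[, 2 * seq_len(n), drop = FALSE])
  genotype_matrix(calls, founders$map,
                  data.frame(sample_id = sprintf("F%d", seq_len(n)),
                             stringsAsFactors = FALSE),
                  autosomes = as.character(seq_len(founders$cfg$n_chromosomes)))
}

chrom_ranges <- function(map) {
  first <- !duplicated(map$chrom)
  lasts <- !duplicated(map$chrom, fromLast = TRUE)
  list(first = which(first), last = which(lasts))
}

# flip a fraction of calls to a uniformly chosen different code, then
# blank a fraction; truth is recorded before this is applied
inject_noise <- function(calls, missing_rate, error_rate) {
  if (error_rate > 0) {
    idx <- which(stats::runif(length(calls)) < error_rate & !is.na(calls))
    if (length(idx)) {
      shift <- sample(1:2, length(idx), replace = TRUE)
      calls[idx] <- (calls[idx] + shift) %% 3L
    }
  }
  if (missing_rate > 0)
    calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
  calls
}

#' Gene-drop genotypes down a pedigree with recombination
#'
#' Founder chromosome copies are dropped through the pedigree: every
#' transmitted gamete is a recombinant mosaic of the parent's two
#' haplotypes (Poisson crossover count, uniform breakpoints). True
#' autozygous segments are the maximal SNP stretches where an individual's
#' two inherited founder-haplotype ids coincide, recorded before
#' missingness and genotyping error are injected.
#'
#' Uses the RNG stream seeded with `cfg$seed + 1` so the drop is
#' reproducible independently of founder simulation.
#'
#' @param p a [pedigree]; its founders are matched to the pool's founders
#'   in pedigree order (the pool must be at least as large).
#' @param founders a `founder_pool` from [simulate_founders].
#' @param cfg a [sim_config] (noise rates and recombination rate are read
#'   from it).
#' @return A list of class `gene_drop_sim`: `genotypes` (a
#'   [genotype_matrix] over all pedigree individuals), `truth` (data.frame
#'   `sample_id`, `chrom`, `start_bp`, `end_bp`, `length_bp`, `n_snp` of
#'   true autozygous segments), `pedigree`.
#' @export
gene_drop <- function(p, founders, cfg = founders$cfg) {
  stopifnot(inherits(p, "pedigree"), inherits(founders, "founder_pool"))
  set.seed(cfg$seed + 1L)
  map <- founders$map
  m <- nrow(map)
  cr <- chrom_ranges(map)
  is_founder <- is.na(p$sire) & is.na(p$dam)
  if (sum(is_founder) > founders$n_founders)
    stop("pedigree has more founders than the simulated pool")
  n <- nrow(p)
  idx <- stats::setNames(seq_len(n), p$id)
  h1 <- matrix(0L, m, n); h2 <- matrix(0L, m, n)   # founder-haplotype ids
  fk <- 0L
  for (i in seq_len(n)) {
    if (is_founder[i]) {
      fk <- fk + 1L
      h1[, i] <- 2L * fk - 1L
      h2[, i] <- 2L * fk
    } else {
      s <- idx[[p$sire[i]]]; d <- idx[[p$dam[i]]]
      h1[, i] <- meiosis_cpp(h1[, s], h2[, s], cr$first, cr$last,
                             map$pos_bp, cfg$recomb_rate_per_bp)
      h2[, i] <- meiosis_cpp(h1[, d], h2[, d], cr$first, cr$last,
                             map$pos_bp, cfg$recomb_rate_per_bp)
    }
  }
  al <- founders$haps
  calls <- matrix(0L, n, m)
  for (i in seq_len(n))
    calls[i, ] <- al[cbind(seq_len(m), h1[, i])] +
      al[cbind(seq_len(m), h2[, i])]
  truth <- truth_segments(h1, h2, map, p$id)
  calls <- inject_noise(calls, cfg$missing_rate, cfg$genotype_error_rate)
  g <- genotype_matrix(calls, map,
                       data.frame(sample_id = p$id,
                                  birth_year = p$birth_year,
                                  stringsAsFactors = FALSE),
                       autosomes = as.character(seq_len(cfg$n_chromosomes)))
  structure(list(genotypes = g, truth = truth, pedigree = p),
            class = "gene_drop_sim")
}

truth_segments <- function(h1, h2, map, ids) {
  out <- list()
  for (ch in unique(map$chrom)) {
    jj <- which(map$chrom == ch)
    pos <- map$pos_bp[jj]
    for (i in seq_along(ids)) {
      auto <- h1[jj, i] == h2[jj, i]
      if (!any(auto)) next
      r <- rle(auto)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        out[[length(out) + 1L]] <- data.frame(
          sample_id = ids[i], chrom = ch,
          start_bp = pos[starts[k]], end_bp = pos[ends[k]],
          length_bp = pos[ends[k]] - pos[starts[k]],
          n_snp = ends[k] - starts[k] + 1L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      length_bp = integer(), n_snp = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' True autozygous genome fraction per sample
#'
#' Summed truth-segment length over the map-covered genome length, for
#' every sample in the simulated cohort (zero when a sample has no
#' segments).
#'
#' @param sim a `gene_drop_sim` from [gene_drop].
#' @param min_length_bp count only segments at least this long.
#' @return Named numeric vector over the cohort's sample ids.
#' @export
true_autozygosity <- function(sim, min_length_bp = 0) {
  lengths <- genome_lengths(sim$genotypes$map)
  ids <- sim$genotypes$samples$sample_id
  tr <- sim$truth[sim$truth$length_bp >= min_length_bp, , drop = FALSE]
  v <- tapply(tr$length_bp, factor(tr$sample_id, levels = ids), sum)
  v[is.na(v)] <- 0
  stats::setNames(as.numeric(v) / lengths$L_auto, ids)
}

#' Recovery of simulated autozygous segments by detected ROH
#'
#' Compares a detected run set against the simulator's truth: `recall_bp`
#' is the fraction of truth-segment base pairs (segments at least
#' `min_truth_bp` long) overlapped by a detected run of the same sample,
#' and `precision_bp` is the fraction of detected run base pairs lying
#' inside any truth segment at least `min_precision_bp` long.
#'
#' @param sim a `gene_drop_sim` from [gene_drop].
#' @param runs a `roh_set` from [detect_roh] on the simulated genotypes.
#' @param min_truth_bp truth segments shorter than this are ignored for
#'   recall (default 1 Mb).
#' @param min_precision_bp truth segments at least this long count as true
#'   territory for precision (default 100 kb).
#' @return list: `recall_bp`, `precision_bp`, `truth_bp`, `detected_bp`.
#' @export
truth_recovery <- function(sim, runs, min_truth_bp = 1e6,
                           min_precision_bp = 1e5) {
  ov <- function(a_start, a_end, b_start, b_end) {
    # total bp of a-intervals covered by the union of b-intervals
    total <- 0
    if (length(b_start) == 0L) return(0)
    o <- order(b_start)
    b_start <- b_start[o]; b_end <- b_end[o]
    for (k in seq_along(a_start)) {
      s <- a_start[k]; e <- a_end[k]
      js <- which(b_end > s & b_start < e)
      for (j in js) total <- total + min(e, b_end[j]) - max(s, b_start[j])
    }
    total
  }
  tr <- sim$truth[sim$truth$length_bp >= min_truth_bp, , drop = FALSE]
  tr_p <- sim$truth[sim$truth$length_bp >= min_precision_bp, , drop = FALSE]
  truth_bp <- sum(tr$length_bp)
  det_bp <- sum(runs$length_bp)
  hit <- 0; det_in_truth <- 0
  for (id in unique(c(tr$sample_id, runs$sample_id))) {
    for (ch in unique(c(tr$chrom[tr$sample_id == id],
                        runs$chrom[runs$sample_id == id]))) {
      t1 <- tr[tr$sample_id == id & tr$chrom == ch, , drop = FALSE]
      tp <- tr_p[tr_p$sample_id == id & tr_p$chrom == ch, , drop = FALSE]
      r1 <- runs[runs$sample_id == id & runs$chrom == ch, , drop = FALSE]
      hit <- hit + ov(t1$start_bp, t1$end_bp, r1$start_bp, r1$end_bp)
      det_in_truth <- det_in_truth +
        ov(r1$start_bp, r1$end_bp, tp$start_bp, tp$end_bp)
    }
  }
  list(recall_bp = if (truth_bp > 0) hit / truth_bp else NA_real_,
       precision_bp = if (det_bp > 0) det_in_truth / det_bp else NA_real_,
       truth_bp = truth_bp, detected_bp = det_bp)
}

#' Simulate a random-mating pedigree
#'
#' Discrete generations of constant census size: every individual draws
#' two distinct parents uniformly from the previous generation. With a
#' small founder pool this builds up inbreeding loops quickly, giving a
#' cohort with variable autozygosity.
#'
#' @param n_founders founders in generation 0.
#' @param n_generations number of descendant generations.
#' @param n_per_gen census size of each descendant generation (scalar or
#'   vector of length `n_generations`).
#' @param seed RNG seed.
#' @return A [pedigree]; `birth_year` encodes the generation number.
#' @export
sim_pedigree <- function(n_founders, n_generations, n_per_gen, seed) {
  set.seed(as.integer(seed))
  n_per_gen <- rep_len(n_per_gen, n_generations)
  recs <- data.frame(id = sprintf("G0_%d", seq_len(n_founders)),
                     sire = NA_character_, dam = NA_character_,
                     birth_year = 0L, stringsAsFactors = FALSE)
  prev <- recs$id
  for (g in seq_len(n_generations)) {
    ids <- sprintf("G%d_%d", g, seq_len(n_per_gen[g]))
    parents <- t(vapply(ids, function(...) sample(prev, 2), character(2)))
    recs <- rbind(recs, data.frame(id = ids, sire = parents[, 1],
                                   dam = parents[, 2], birth_year = g,
                                   stringsAsFactors = FALSE))
    prev <- ids
  }
  pedigree(recs)
}

#' Wright-Fisher forward simulation
#'
#' Constant-size diploid population under discrete non-overlapping
#' generations, random mating with replacement, recombination as in
#' [gene_drop], and no mutation (standing variation only). A random sample
#' of the final generation is emitted as genotypes — the substrate for Ne
#' recovery tests where the census size is the true effective size.
#'
#' @param cfg a [sim_config] (its seed drives the whole simulation).
#' @param N_diploid census (= effective) population size.
#' @param n_generations generations of random mating.
#' @param sample_size individuals sampled from the final generation.
#' @return A [genotype_matrix] with attributes `true_ne` and
#'   `n_generations`.
#' @export
wright_fisher <- function(cfg, N_diploid, n_generations,
                          sample_size = N_diploid) {
  stopifnot(N_diploid >= 2, sample_size <= N_diploid)
  founders <- simulate_founders(cfg, N_diploid)   # sets cfg$seed
  map <- founders$map
  cr <- chrom_ranges(map)
  haps <- wf_evolve_cpp(founders$haps, cr$first, cr$last, map$pos_bp,
                        cfg$recomb_rate_per_bp, n_generations)
  take <- sort(sample(N_diploid, sample_size))
  calls <- t(haps[, 2 * take - 1, drop = FALSE] +
               haps[, 2 * take, drop = FALSE])
  calls <- inject_noise(calls, cfg$missing_rate, cfg$genotype_error_rate)
  g <- genotype_matrix(calls, map,
                       data.frame(sample_id = sprintf("wf_%d", take),
                                  stringsAsFactors = FALSE),
                       autosomes = as.character(seq_len(cfg$n_chromosomes)))
  attr(g, "true_ne") <- N_diploid
  attr(g, "n_generations") <- n_generations
  g
}

#' Write a simulated dataset to disk
#'
#' Genotypes via [write_plink]; truth segments as a TSV and a BED track.
#'
#' @param sim a `gene_drop_sim`.
#' @param prefix output path prefix.
#' @param dialect PLINK dialect, see [write_plink].
#' @return `prefix`, invisibly.
#' @export
emit_simulation <- function(sim, prefix, dialect = "binary") {
  write_plink(sim$genotypes, prefix, dialect)
  utils::write.table(sim$truth, paste0(prefix, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- sim$truth[sim$truth$start_bp < sim$truth$end_bp, , drop = FALSE]
  if (nrow(tr) > 0)
    export_bed(data.frame(chrom = tr$chrom, start_bp = tr$start_bp,
                          end_bp = tr$end_bp, name = tr$sample_id),
               paste0(prefix, ".truth.bed"))
  else file.create(paste0(prefix, ".truth.bed"))
  invisible(prefix)
}
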