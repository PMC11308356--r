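mk_runs <- function(df, samples) {
  df$class <- equidiv:::roh_length_class(df$length_bp)
  structure(df, samples = data.frame(sample_id = samples,
                                     population = NA_character_,
                                     stringsAsFactors = FALSE),
            class = c("roh_set", "data.frame"))
}

toy_lengths <- function(per_chrom, L_auto = NULL) {
  structure(list(per_chrom = per_chrom,
                 L_auto = if (is.null(L_auto)) sum(per_chrom) else L_auto),
            class = "genome_lengths")
}

test_that("F_ROH is summed run length over genome length", {
  runs0 <- mk_runs(data.frame(sample_id = character(), chrom = character(),
                              start_bp = integer(), end_bp = integer(),
                              length_bp = integer()), c("a", "b"))
  lens <- toy_lengths(c("1" = 2281e6))
  fr0 <- froh(runs0, lengths = lens)
  expect_equal(fr0$by_sample$froh_total, c(0, 0))

  runs1 <- mk_runs(data.frame(sample_id = "a", chrom = "1",
                              start_bp = 1, end_bp = 228.1e6 + 1,
                              length_bp = 228.1e6), c("a", "b"))
  fr1 <- froh(runs1, lengths = toy_lengths(c("1" = 2281e6), L_auto = 2281e6))
  expect_equal(fr1$by_sample$froh_total, c(0.1, 0))
  # a run on a chromosome without a declared length is an error
  expect_error(froh(mk_runs(data.frame(sample_id = "a", chrom = "9",
                                       start_bp = 1, end_bp = 2e6,
                                       length_bp = 2e6), "a"),
                    lengths = lens), "absent")
})

test_that("per-class F_ROH sums exactly to the total on simulated runs", {
  cfg <- sim_config(n_chromosomes = 4, n_snps_per_chrom = 1500,
                    chromosome_length_bp = 8e6, seed = 301)
  ped <- sim_pedigree(12, 3, c(14, 14, 30), seed = 302)
  sim <- gene_drop(ped, simulate_founders(cfg, 12), cfg)
  runs <- detect_roh(sim$genotypes, roh_params())
  lens <- genome_lengths(sim$genotypes$map)
  fr <- froh(runs, lengths = lens)
  class_cols <- paste0("froh_", equidiv:::roh_class_labels)
  expect_equal(rowSums(fr$by_sample[, class_cols]), fr$by_sample$froh_total,
               tolerance = 1e-12, ignore_attr = TRUE)
  # cohort mean equals brute-force sum(lengths) / (n * L_auto)
  expect_equal(mean(fr$by_sample$froh_total),
               sum(runs$length_bp) / (nrow(sim$genotypes$samples) * lens$L_auto))
  # longer minimum length can only lower F_ROH
  runs500 <- detect_roh(sim$genotypes, roh_params(min_length_bp = 500000))
  fr500 <- froh(runs500, lengths = lens)
  expect_true(all(fr500$by_sample$froh_total <= fr$by_sample$froh_total + 1e-15))
})

test_that("descriptive table classifies runs and recounts correctly", {
  runs <- mk_runs(data.frame(sample_id = c("a", "a", "b"), chrom = "1",
                             start_bp = c(1, 1, 1),
                             end_bp = c(1.5e6 + 1, 1e6 + 1, 2e6 + 1),
                             length_bp = c(1.5e6, 1e6, 2e6)),
                  c("a", "b"))
  tab <- descriptive_table(runs)
  r12 <- tab[tab$class == "1-2", ]
  # runs of exactly 1 Mb and 2 Mb land in (0.1,1] and (1,2]
  expect_equal(tab$n_roh[tab$class == "0.1-1"], 1)
  expect_equal(r12$n_roh, 2)
  expect_equal(r12$n_ind, 2)
  expect_equal(r12$s_roh, 1)
  expect_equal(r12$l_roh_mb, 1.75)
  expect_equal(sum(tab$n_roh), 3)
  expect_equal(sum(tab$roh_pct), 100)
})

test_that("descriptive table matches an independent group-by recount", {
  cfg <- sim_config(n_chromosomes = 3, n_snps_per_chrom = 1200,
                    chromosome_length_bp = 8e6, seed = 305)
  ped <- sim_pedigree(10, 3, c(12, 12, 25), seed = 306)
  sim <- gene_drop(ped, simulate_founders(cfg, 10), cfg)
  runs <- detect_roh(sim$genotypes, roh_params())
  tab <- descriptive_table(runs)
  for (cl in unique(as.character(runs$class))) {
    sub <- runs[as.character(runs$class) == cl, ]
    row <- tab[tab$class == cl, ]
    expect_equal(row$n_roh, nrow(sub))
    expect_equal(row$n_ind, length(unique(sub$sample_id)))
    expect_equal(row$l_roh_mb, mean(sub$length_bp) / 1e6)
    expect_equal(row$roh_pct, 100 * nrow(sub) / nrow(runs))
  }
})

test_that("island incidence equals a brute-force interval-stabbing count", {
  set.seed(34)
  g <- toy_genotypes(matrix(0L, 4, 50), pos = sort(sample(1:1e6, 50)))
  runs <- mk_runs(data.frame(
    sample_id = c("s1", "s1", "s2", "s3"),
    chrom = "1",
    start_bp = c(1000, 600000, 2000, 100),
    end_bp = c(300000, 900000, 500000, 999999),
    length_bp = c(299000, 300000, 498000, 999899)),
    paste0("s", 1:4))
  inc <- island_incidence(runs, g)
  for (j in seq_len(nrow(g$map))) {
    pos <- g$map$pos_bp[j]
    covered <- unique(runs$sample_id[runs$start_bp <= pos &
                                       runs$end_bp >= pos])
    expect_equal(inc$incidence[j], length(covered) / 4)
  }
  # no runs -> all zero
  inc0 <- island_incidence(runs[0, ], g,
                           samples = attr(runs, "samples"))
  expect_true(all(inc0$incidence == 0))
})

test_that("islands are maximal stretches above the strict 70% threshold", {
  m <- 100
  inc <- structure(data.frame(chrom = "1", id = paste0("m", 1:m),
                              pos_bp = (1:m) * 10000,
                              incidence = rep(0.2, m)),
                   class = c("roh_incidence", "data.frame"))
  expect_equal(nrow(call_islands(inc)), 0)
  # engineered sweep: 25 SNPs at 0.9 flanked by 0.2
  inc$incidence[40:64] <- 0.9
  isl <- call_islands(inc, threshold = 0.70)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$n_snp, 25L)
  expect_equal(isl$start_bp, 40 * 10000)
  expect_equal(isl$end_bp, 64 * 10000)
  expect_equal(isl$peak_incidence, 0.9)
  # incidence exactly at the threshold is excluded ("over 70%")
  inc$incidence[40:64] <- 0.70
  expect_equal(nrow(call_islands(inc, threshold = 0.70)), 0)
})

test_that("islands at a higher threshold nest within lower-threshold islands", {
  set.seed(35)
  for (rep in 1:25) {
    m <- 80
    inc <- structure(data.frame(chrom = "1", id = paste0("m", 1:m),
                                pos_bp = (1:m) * 5000,
                                incidence = round(runif(m), 2)),
                     class = c("roh_incidence", "data.frame"))
    lo <- call_islands(inc, threshold = 0.7)
    hi <- call_islands(inc, threshold = 0.8)
    for (k in seq_len(nrow(hi))) {
      expect_true(any(lo$start_bp <= hi$start_bp[k] &
                        lo$end_bp >= hi$end_bp[k]))
    }
  }
})

test_that("island overlap reports shared intervals", {
  a <- data.frame(chrom = c("1", "2"), start_bp = c(100, 500),
                  end_bp = c(200, 900))
  b <- data.frame(chrom = c("1", "3"), start_bp = c(150, 500),
                  end_bp = c(300, 900))
  ov <- overlap_islands(a, b)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$shared_start_bp, 150)
  expect_equal(ov$shared_end_bp, 200)
  expect_equal(nrow(overlap_islands(a, data.frame(chrom = "9",
                                                  start_bp = 1,
                                                  end_bp = 2))), 0)
  # two real island coordinates on the same chromosome share 94,340 bp
  ice <- data.frame(chrom = "17", start_bp = 18706560, end_bp = 18829942)
  exm <- data.frame(chrom = "17", start_bp = 18735602, end_bp = 18829942)
  expect_equal(overlap_islands(ice, exm)$overlap_bp, 94340)
})

test_that("coverage validation follows the genotype-free construction", {
  p <- roh_params()
  # uniform 20 kb spacing: the whole covered length is detectable
  map1 <- data.frame(chrom = "1", id = paste0("m", 1:10000),
                     pos_bp = (1:10000) * 20000)
  expect_equal(coverage_validation(map1, p), 1.0)
  # one 200 kb gap splits the map; both halves remain detectable
  pos <- c(seq(1, by = 2000, length.out = 150),
           seq(1 + 149 * 2000 + 200000, by = 2000, length.out = 150))
  map2 <- data.frame(chrom = "1", id = paste0("m", 1:300), pos_bp = pos)
  span_left <- 149 * 2000
  span_right <- 149 * 2000
  L <- pos[300] - pos[1]
  expect_equal(coverage_validation(map2, p), (span_left + span_right) / L)
  # everywhere sparser than the density floor -> zero
  map3 <- data.frame(chrom = "1", id = paste0("m", 1:500),
                     pos_bp = (1:500) * 30000)
  expect_equal(coverage_validation(map3, p), 0)
})

test_that("Pearson correlation of F_ROH and F_PED matches the formula", {
  x <- c(0.1, 0.2, 0.3, 0.15, 0.25)
  names(x) <- paste0("s", 1:5)
  expect_equal(froh_fped_correlation(x, x)$r, 1)
  y <- sort(x, decreasing = TRUE)
  names(y) <- names(sort(x))
  expect_equal(froh_fped_correlation(sort(x), y)$r, -1)

  set.seed(36)
  a <- runif(40); b <- 0.5 * a + rnorm(40, 0, 0.1)
  names(a) <- names(b) <- paste0("id", 1:40)
  got <- froh_fped_correlation(a, b)
  r_manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  t_stat <- r_manual * sqrt(38 / (1 - r_manual^2))
  expect_equal(got$r, r_manual, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(-abs(t_stat), 38), tolerance = 1e-12)
})
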