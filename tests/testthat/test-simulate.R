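test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 300,
                    chromosome_length_bp = 5e6, seed = 91)
  f1 <- simulate_founders(cfg, 10)
  f2 <- simulate_founders(cfg, 10)
  expect_identical(f1$haps, f2$haps)
  expect_identical(f1$map, f2$map)

  ped <- sim_pedigree(6, 3, 8, seed = 92)
  s1 <- gene_drop(ped, f1, cfg)
  s2 <- gene_drop(ped, f2, cfg)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$truth, s2$truth)

  w1 <- wright_fisher(cfg, 20, 10, 15)
  w2 <- wright_fisher(cfg, 20, 10, 15)
  expect_identical(w1$calls, w2$calls)
})

test_that("founder frequencies follow the configured law", {
  cfg <- sim_config(n_chromosomes = 1, n_snps_per_chrom = 2000,
                    chromosome_length_bp = 10e6, freq_law = "fixed",
                    fixed_p = 0.5, seed = 93)
  fo <- simulate_founders(cfg, 100)
  p_hat <- rowMeans(fo$haps)
  expect_equal(mean(p_hat), 0.5, tolerance = 0.01)
  expect_lt(max(abs(p_hat - 0.5)), 0.25)   # binomial(200) spread
})

test_that("offspring of unrelated founders carry no autozygous segments", {
  cfg <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 400,
                    chromosome_length_bp = 8e6, seed = 94)
  ped <- pedigree(data.frame(id = c("F1", "F2", "K"),
                             sire = c(NA, NA, "F1"),
                             dam = c(NA, NA, "F2")))
  sim <- gene_drop(ped, simulate_founders(cfg, 2), cfg)
  expect_equal(nrow(sim$truth), 0)
})

test_that("full-sib offspring are autozygous over a quarter of the genome", {
  fracs <- numeric(200)
  ped <- pedigree(data.frame(
    id = c("A", "B", "S1", "S2", "X"),
    sire = c(NA, NA, "A", "A", "S1"),
    dam = c(NA, NA, "B", "B", "S2")))
  for (r in 1:200) {
    cfg <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 150,
                      chromosome_length_bp = 60e6, seed = 9000 + r)
    sim <- gene_drop(ped, simulate_founders(cfg, 2), cfg)
    fracs[r] <- true_autozygosity(sim)[["X"]]
  }
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.25), 4 * se)
})

test_that("autozygosity accumulates along a full-sib mating chain", {
  # closed full-sib line: expected F after t generations follows the
  # classic recurrence F_t = (1 + 2 F_{t-1} + F_{t-2}) / 4
  n_gen <- 5
  recs <- data.frame(id = c("M0", "F0"), sire = NA_character_,
                     dam = NA_character_, stringsAsFactors = FALSE)
  for (g in seq_len(n_gen)) {
    recs <- rbind(recs, data.frame(
      id = paste0(c("M", "F"), g),
      sire = paste0("M", g - 1), dam = paste0("F", g - 1)))
  }
  ped <- pedigree(recs)
  # F(gen 1) = 0 (founder offspring), F(gen 2) = 1/4, then
  # F_g = (1 + F_{g-2} + 2 F_{g-1}) / 4
  f_expect <- c(0, 0.25)
  for (g in 3:n_gen)
    f_expect[g] <- (1 + f_expect[g - 2] + 2 * f_expect[g - 1]) / 4
  f_ped <- ped_inbreeding(ped)
  expect_equal(unname(f_ped[paste0("M", 1:n_gen)]), f_expect,
               tolerance = 1e-12)
  # and simulated autozygous fractions track it within Monte-Carlo error
  means <- matrix(NA_real_, 60, n_gen)
  for (r in 1:60) {
    cfg <- sim_config(n_chromosomes = 4, n_snps_per_chrom = 100,
                      chromosome_length_bp = 50e6, seed = 7000 + r)
    sim <- gene_drop(ped, simulate_founders(cfg, 2), cfg)
    ta <- true_autozygosity(sim)
    means[r, ] <- ta[paste0("M", 1:n_gen)]
  }
  obs <- colMeans(means)
  expect_true(all(diff(obs) > 0))          # monotone increase
  expect_equal(obs, f_expect, tolerance = 0.15)
})

test_that("noise injection blanks and perturbs genotypes but not truth", {
  cfg0 <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 500,
                     chromosome_length_bp = 8e6, seed = 95)
  cfg1 <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 500,
                     chromosome_length_bp = 8e6, seed = 95,
                     missing_rate = 0.05, genotype_error_rate = 0.02)
  ped <- sim_pedigree(4, 2, 6, seed = 96)
  clean <- gene_drop(ped, simulate_founders(cfg0, 4), cfg0)
  noisy <- gene_drop(ped, simulate_founders(cfg1, 4), cfg1)
  expect_identical(clean$truth, noisy$truth)
  expect_equal(mean(is.na(noisy$genotypes$calls)), 0.05, tolerance = 0.25)
  both <- !is.na(noisy$genotypes$calls)
  expect_gt(mean(clean$genotypes$calls[both] != noisy$genotypes$calls[both]),
            0.005)
})

test_that("drift in a Wright-Fisher line matches the variance formula", {
  # Var(p_t) = p0 (1 - p0) (1 - (1 - 1/(2N))^t)
  N <- 25; t <- 15
  vars <- numeric(3)
  for (k in 1:3) {
    cfg <- sim_config(n_chromosomes = 30, n_snps_per_chrom = 80,
                      chromosome_length_bp = 60e6, freq_law = "fixed",
                      fixed_p = 0.5, seed = 600 + k)
    g <- wright_fisher(cfg, N, t, N)
    p_t <- colMeans(g$calls) / 2
    vars[k] <- mean((p_t - 0.5)^2)
  }
  expected <- 0.25 * (1 - (1 - 1 / (2 * N))^t)
  expect_equal(mean(vars), expected, tolerance = 0.15)
})

test_that("heterozygosity collapses in a two-individual population", {
  cfg <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 400,
                    chromosome_length_bp = 8e6, freq_law = "fixed",
                    fixed_p = 0.5, seed = 97)
  g <- wright_fisher(cfg, N_diploid = 2, n_generations = 40, sample_size = 2)
  expect_lt(mean(observed_het(g)$h_obs), 0.15)
})

test_that("emitted files round-trip genotypes and truth", {
  d <- withr::local_tempdir()
  cfg <- sim_config(n_chromosomes = 2, n_snps_per_chrom = 300,
                    chromosome_length_bp = 6e6, seed = 98)
  ped <- sim_pedigree(4, 3, 8, seed = 99)
  sim <- gene_drop(ped, simulate_founders(cfg, 4), cfg)
  emit_simulation(sim, file.path(d, "sim"))
  g2 <- read_plink(file.path(d, "sim"))
  expect_identical(unname(g2$calls), unname(sim$genotypes$calls))
  tr <- read.delim(file.path(d, "sim.truth.tsv"))
  expect_equal(nrow(tr), nrow(sim$truth))
  bed <- read_bed(file.path(d, "sim.truth.bed"))
  multi <- sim$truth[sim$truth$start_bp < sim$truth$end_bp, ]
  expect_equal(bed$start_bp, multi$start_bp)
  expect_equal(bed$end_bp, multi$end_bp)
  # per-sample truth segments stay disjoint in the export
  for (id in unique(bed$name)) {
    for (ch in unique(bed$chrom[bed$name == id])) {
      sub <- bed[bed$name == id & bed$chrom == ch, ]
      sub <- sub[order(sub$start_bp), ]
      if (nrow(sub) > 1)
        expect_true(all(sub$start_bp[-1] > sub$end_bp[-nrow(sub)]))
    }
  }
})
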