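test_that("hand-written ped/map fixture reads into the expected call matrix", {
  d <- withr::local_tempdir()
  writeLines(c("1\tsnp1\t0\t1000", "1\tsnp2\t0\t2000",
               "1\tsnp3\t0\t3000", "2\tsnp4\t0\t500"),
             file.path(d, "fix.map"))
  # alleles sorted per marker: allele_a = first, allele_b = second
  writeLines(c("s1 s1 0 0 0 -9 A A A C C C 0 0",
               "s2 s2 0 0 0 -9 A C C C A C G G",
               "s3 s3 0 0 0 -9 C C A A A A G T"),
             file.path(d, "fix.ped"))
  g <- read_plink(file.path(d, "fix"), dialect = "text")
  expect_equal(g$samples$sample_id, c("s1", "s2", "s3"))
  # markers sorted by (chrom, pos): snp1..3 then snp4
  expect_equal(g$map$id, c("snp1", "snp2", "snp3", "snp4"))
  expect_equal(unname(g$calls[, "snp1"]), c(0L, 1L, 2L))
  expect_equal(unname(g$calls[, "snp2"]), c(1L, 2L, 0L))
  expect_equal(unname(g$calls[, "snp3"]), c(2L, 1L, 0L))
  expect_equal(unname(g$calls[, "snp4"]), c(NA_integer_, 0L, 1L))
})

test_that("write/read round-trips calls, ids and positions in both dialects", {
  set.seed(41)
  n <- 50; m <- 200
  p <- runif(m, 0.2, 0.8)
  calls <- sapply(p, function(pp) rbinom(n, 2, pp))
  calls[sample(length(calls), 150)] <- NA
  g <- toy_genotypes(calls,
                     pos = sort(sample(1:5e6, m)),
                     chrom = rep(c("1", "2"), each = m / 2))
  d <- withr::local_tempdir()
  for (dialect in c("binary", "text")) {
    write_plink(g, file.path(d, dialect), dialect)
    g2 <- read_plink(file.path(d, dialect), dialect)
    expect_identical(unname(g2$calls), unname(g$calls), label = dialect)
    expect_equal(g2$map$pos_bp, g$map$pos_bp)
    expect_equal(g2$map$id, g$map$id)
    expect_equal(g2$samples$sample_id, g$samples$sample_id)
  }
})

test_that("binary dialect matches the PLINK 1 bit layout byte for byte", {
  d <- withr::local_tempdir()
  # 5 samples, 1 SNP: codes 0,1,2,NA,2 -> 2-bit values 0,2,3,1,3 ->
  # bytes 0b11 01 11 10 00... little-endian pairs: byte1 = 0 + 2*4 + 3*16
  # + 1*64 = 120, byte2 = 3
  writeLines("1\tsnpA\t0\t1000\tA\tB", file.path(d, "h.bim"))
  writeLines(sprintf("s%d s%d 0 0 0 -9", 1:5, 1:5), file.path(d, "h.fam"))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 120, 3)), file.path(d, "h.bed"))
  g <- read_plink(file.path(d, "h"), dialect = "binary")
  expect_equal(unname(g$calls[, 1]), c(0L, 1L, 2L, NA, 2L))
  # and writing it back reproduces the same payload
  write_plink(g, file.path(d, "h2"), "binary")
  expect_identical(readBin(file.path(d, "h2.bed"), "raw", 10),
                   as.raw(c(0x6c, 0x1b, 0x01, 120, 3)))
})

test_that("empty marker set writes valid, re-readable files", {
  g <- genotype_matrix(matrix(integer(), 2, 0),
                       data.frame(chrom = character(), id = character(),
                                  pos_bp = integer()),
                       c("a", "b"))
  d <- withr::local_tempdir()
  write_plink(g, file.path(d, "empty"), "binary")
  g2 <- read_plink(file.path(d, "empty"))
  expect_equal(dim(g2), c(2L, 0L))
})

test_that("heterozygote counts are invariant under allele relabeling", {
  set.seed(5)
  calls <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 6, 10)
  g <- toy_genotypes(calls)
  g_swapped <- toy_genotypes(2L - calls)
  expect_equal(observed_het(g)$n_het, observed_het(g_swapped)$n_het)
  expect_equal(observed_het(g)$h_obs, observed_het(g_swapped)$h_obs)
})

test_that("marker intersection keeps exactly the shared markers in order", {
  set.seed(6)
  mk <- function(pos) toy_genotypes(matrix(0L, 2, length(pos)), pos = pos)
  a <- mk(c(100, 200, 300, 400, 500, 600, 700, 800, 900, 1000))
  b <- mk(c(100, 250, 300, 400, 550, 600, 700, 800, 900, 1000))
  suppressMessages(res <- intersect_markers(a, b, key = "position"))
  shared <- c(100, 300, 400, 600, 700, 800, 900, 1000)
  expect_equal(res$a$map$pos_bp, shared)
  expect_equal(res$b$map$pos_bp, shared)
  suppressMessages(idn <- intersect_markers(a, a))
  expect_identical(idn$a$calls, a$calls)
  disjoint <- mk(c(123, 456))
  expect_error(suppressMessages(intersect_markers(a, disjoint)), "no shared")
})

test_that("BED export is 0-based half-open and re-import restores intervals", {
  d <- withr::local_tempdir()
  path <- file.path(d, "iv.bed")
  rec <- data.frame(chrom = c("23", "1", "1"),
                    start_bp = c(22117843, 1, 11),
                    end_bp = c(22706518, 10, 20),
                    name = c("island", "x", "y"))
  export_bed(rec, path)
  lines <- readLines(path)
  expect_equal(strsplit(lines[1], "\t")[[1]][2:3], c("22117842", "22706518"))
  # adjacent 1-based [1,10], [11,20] become non-overlapping (0,10), (10,20)
  expect_equal(strsplit(lines[2], "\t")[[1]][2:3], c("0", "10"))
  expect_equal(strsplit(lines[3], "\t")[[1]][2:3], c("10", "20"))
  back <- read_bed(path)
  expect_equal(back$start_bp, rec$start_bp)
  expect_equal(back$end_bp, rec$end_bp)
  export_bed(rec[0, ], path)
  expect_equal(file.size(path), 0)
  expect_equal(nrow(read_bed(path)), 0)
})

test_that("a sample metadata TSV supplies population and birth year", {
  d <- withr::local_tempdir()
  g <- toy_genotypes(matrix(0L, 3, 4))
  write_plink(g, file.path(d, "md"))
  writeLines(c("sample_id\tpopulation\tbirth_year",
               "s1\tICE\t2006", "s3\tEXM\t2001"),
             file.path(d, "meta.tsv"))
  g2 <- read_plink(file.path(d, "md"), metadata = file.path(d, "meta.tsv"))
  expect_equal(g2$samples$population, c("ICE", NA, "EXM"))
  expect_equal(g2$samples$birth_year, c(2006L, NA, 2001L))
})

test_that("non-autosomal markers are dropped and duplicates deduplicated", {
  map <- data.frame(chrom = c("1", "X", "1", "1"),
                    id = c("a", "b", "c", "c2"),
                    pos_bp = c(100, 200, 300, 300))
  expect_message(
    expect_warning(g <- genotype_matrix(matrix(0L, 1, 4), map, "s1"),
                   "duplicated"),
    "non-autosomal")
  expect_equal(g$map$id, c("a", "c"))
})
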