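#' Read PLINK genotype files
#'
#' Reads either the text (`.ped`/`.map`) or binary (`.bed`/`.bim`/`.fam`,
#' SNP-major PLINK 1 layout) dialect into a [genotype_matrix]. Sample order
#' follows the family file; markers are sorted by (chromosome, position) and
#' restricted to `autosomes`. Calls are counts of the second (`allele_b` /
#' bim A2) allele, so heterozygote coding is independent of allele
#' orientation.
#'
#' For the text dialect the two alleles of each marker are inferred from the
#' data (lexicographically sorted; a monomorphic marker's single allele is
#' taken as `allele_a`). The binary dialect is lossless because the `.bim`
#' file carries both alleles.
#'
#' An optional metadata TSV with columns `sample_id`, `population`,
#' `birth_year` supplements the family file.
#'
#' @param prefix path prefix of the fileset (no extension).
#' @param dialect `"auto"` (default; binary preferred when present),
#'   `"binary"` or `"text"`.
#' @param metadata optional path to a sample metadata TSV.
#' @param autosomes admissible chromosome labels (see [genotype_matrix]).
#' @return A [genotype_matrix].
#' @export
read_plink <- function(prefix, dialect = c("auto", "binary", "text"),
                       metadata = NULL, autosomes = horse_autosomes()) {
  dialect <- match.arg(dialect)
  has_bin <- file.exists(paste0(prefix, ".bed"))
  has_txt <- file.exists(paste0(prefix, ".ped"))
  if (dialect == "auto") dialect <- if (has_bin) "binary" else "text"
  g <- if (dialect == "binary") {
    if (!has_bin) stop("no .bed file at prefix ", prefix)
    read_plink_binary(prefix, autosomes)
  } else {
    if (!has_txt) stop("no .ped file at prefix ", prefix)
    read_plink_text(prefix, autosomes)
  }
  if (!is.null(metadata)) {
    md <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    stopifnot("sample_id" %in% names(md))
    idx <- match(g$samples$sample_id, as.character(md$sample_id))
    if (!is.null(md$population))
      g$samples$population <- as.character(md$population)[idx]
    if (!is.null(md$birth_year))
      g$samples$birth_year <- as.integer(md$birth_year)[idx]
  }
  g
}

# read.table that tolerates a zero-row file
read_table_safe <- function(path, col.names, colClasses) {
  if (file.size(path) == 0) {
    df <- as.data.frame(stats::setNames(
      lapply(colClasses, function(cl) vector(cl, 0)), col.names))
    return(df)
  }
  utils::read.table(path, stringsAsFactors = FALSE, col.names = col.names,
                    colClasses = colClasses)
}

read_plink_text <- function(prefix, autosomes) {
  map <- read_table_safe(paste0(prefix, ".map"),
                         col.names = c("chrom", "id", "cm", "pos_bp"),
                         colClasses = c("character", "character", "character",
                                        "integer"))
  ped <- utils::read.table(paste0(prefix, ".ped"), stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop("ped has ", ncol(ped), " columns; expected ", 6 + 2 * m,
         " for ", m, " markers")
  samples <- data.frame(sample_id = ped[[2]],
                        population = ifelse(ped[[1]] == ped[[2]], NA, ped[[1]]),
                        stringsAsFactors = FALSE)
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  n <- nrow(ped)
  calls <- matrix(NA_integer_, n, m)
  allele_a <- character(m); allele_b <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    ok <- x1 != "0" & x2 != "0"
    al <- sort(unique(c(x1[ok], x2[ok])))
    if (length(al) > 2)
      stop("marker ", map$id[j], " has more than two alleles")
    allele_a[j] <- if (length(al) >= 1) al[1] else "A"
    allele_b[j] <- if (length(al) == 2) al[2] else "B"
    calls[ok, j] <- (x1[ok] == allele_b[j]) + (x2[ok] == allele_b[j])
  }
  map2 <- data.frame(chrom = map$chrom, id = map$id, pos_bp = map$pos_bp,
                     allele_a = allele_a, allele_b = allele_b,
                     stringsAsFactors = FALSE)
  genotype_matrix(calls, map2, samples, autosomes)
}

# PLINK 1 .bed 2-bit codes (low bit first): 0 = hom A1, 1 = missing,
# 2 = het, 3 = hom A2. Internal call = count of A2 (allele_b).
.bed_decode <- c(0L, NA_integer_, 1L, 2L)

read_plink_binary <- function(prefix, autosomes) {
  bim <- read_table_safe(paste0(prefix, ".bim"),
                         col.names = c("chrom", "id", "cm", "pos_bp",
                                       "allele_a", "allele_b"),
                         colClasses = c("character", "character", "character",
                                        "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), stringsAsFactors = FALSE,
                           colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  bpl <- ceiling(n / 4)                      # bytes per SNP block
  raw <- readBin(paste0(prefix, ".bed"), "raw", n = 3 + bpl * m)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: bad magic number")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  if (length(raw) != 3 + bpl * m)
    stop(".bed payload size does not match .bim/.fam dimensions")
  bits <- matrix(as.integer(rawToBits(raw[-(1:3)])), nrow = 8 * bpl)
  vals <- bits[seq(1, 2 * n, by = 2), , drop = FALSE] +
    2L * bits[seq(2, 2 * n, by = 2), , drop = FALSE]
  calls <- matrix(.bed_decode[vals + 1L], nrow = n)
  samples <- data.frame(sample_id = fam[[2]],
                        population = ifelse(fam[[1]] == fam[[2]], NA, fam[[1]]),
                        stringsAsFactors = FALSE)
  map <- bim[, c("chrom", "id", "pos_bp", "allele_a", "allele_b")]
  genotype_matrix(calls, map, samples, autosomes)
}

#' Write PLINK genotype files
#'
#' Writes a [genotype_matrix] as a PLINK fileset readable by [read_plink];
#' lossless for calls, ids, positions and (in the binary dialect) alleles.
#'
#' @param g a [genotype_matrix].
#' @param prefix output path prefix.
#' @param dialect `"binary"` (default) or `"text"`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix, dialect = c("binary", "text")) {
  dialect <- match.arg(dialect)
  fid <- ifelse(is.na(g$samples$population), g$samples$sample_id,
                g$samples$population)
  zero <- rep(0, nrow(g$map))
  if (dialect == "binary") {
    utils::write.table(data.frame(g$map$chrom, g$map$id, zero, g$map$pos_bp,
                                  g$map$allele_a, g$map$allele_b),
                       paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(fid, g$samples$sample_id, 0, 0, 0, -9),
                       paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    n <- nrow(g$calls); m <- ncol(g$calls)
    enc <- c(0L, 2L, 3L)                     # call 0/1/2 -> 2-bit value
    con <- file(paste0(prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    pad <- 4 * ceiling(n / 4) - n
    for (j in seq_len(m)) {
      v <- g$calls[, j]
      v <- ifelse(is.na(v), 1L, enc[v + 1L])
      if (pad > 0) v <- c(v, integer(pad))
      bits <- rbind(v %% 2L, v %/% 2L)
      writeBin(packBits(as.logical(bits), "raw"), con)
    }
  } else {
    utils::write.table(data.frame(g$map$chrom, g$map$id, zero, g$map$pos_bp),
                       paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    n <- nrow(g$calls); m <- ncol(g$calls)
    al <- matrix("0", n, 2 * m)
    for (j in seq_len(m)) {
      v <- g$calls[, j]
      a <- g$map$allele_a[j]; b <- g$map$allele_b[j]
      al[, 2 * j - 1] <- ifelse(is.na(v), "0", ifelse(v >= 1, b, a))
      al[, 2 * j] <- ifelse(is.na(v), "0", ifelse(v == 2, b, a))
    }
    ped <- cbind(fid, g$samples$sample_id, "0", "0", "0", "-9", al)
    utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(prefix)
}

#' Intersect the marker sets of two genotype matrices
#'
#' Restricts both matrices to their shared markers (matched by map position
#' or by marker id) in a common order, as done when merging two array
#' datasets for a combined analysis.
#'
#' @param a,b [genotype_matrix] objects on the same genome build.
#' @param key `"position"` (match on chromosome + bp) or `"id"`.
#' @return A list with elements `a` and `b`, both restricted to the shared
#'   markers in identical order.
#' @export
intersect_markers <- function(a, b, key = c("position", "id")) {
  key <- match.arg(key)
  ka <- if (key == "position") paste(a$map$chrom, a$map$pos_bp) else a$map$id
  kb <- if (key == "position") paste(b$map$chrom, b$map$pos_bp) else b$map$id
  shared <- intersect(ka, kb)
  if (length(shared) == 0L) stop("no shared markers between the two datasets")
  ia <- match(shared, ka)
  ib <- match(shared, kb)
  message("marker intersection: ", length(ka), " and ", length(kb),
          " markers in; ", length(shared), " shared")
  list(a = a[, ia], b = b[, ib])
}

#' Export genomic intervals as a BED file
#'
#' Internal intervals are 1-based inclusive `[start_bp, end_bp]`; BED is
#' 0-based half-open, so the written line is `(start_bp - 1, end_bp)`.
#'
#' @param records data.frame with columns `chrom`, `start_bp`, `end_bp` and
#'   optional `name`, `score`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_bed <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(all(records$start_bp < records$end_bp))
  out <- data.frame(records$chrom,
                    as.integer(records$start_bp) - 1L,
                    as.integer(records$end_bp),
                    if (is.null(records$name)) "." else records$name,
                    if (is.null(records$score)) 0 else records$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file back into 1-based inclusive intervals
#'
#' Inverse of [export_bed].
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start_bp`, `end_bp`, `name`, `score`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), name = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(x[[1]]), start_bp = x[[2]] + 1L,
             end_bp = x[[3]],
             name = if (ncol(x) >= 4) as.character(x[[4]]) else ".",
             score = if (ncol(x) >= 5) x[[5]] else 0,
             stringsAsFactors = FALSE)
}
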