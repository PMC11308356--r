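#' Autosome labels of the horse genome
#'
#' EquCab3.0 has 31 autosomes; chromosome labels outside this set (X, MT,
#' unplaced scaffolds) are dropped when a [genotype_matrix] is built.
#'
#' @return Character vector `"1"` ... `"31"`.
#' @export
horse_autosomes <- function() as.character(1:31)

#' Construct a genotype matrix
#'
#' The central container of the package: biallelic genotype calls for a set
#' of samples on an ordered autosomal marker map. Calls are stored as counts
#' of `allele_b` (0 = homozygous `allele_a`, 1 = heterozygous, 2 = homozygous
#' `allele_b`, `NA` = missing), so every downstream statistic (heterozygosity,
#' allele frequency, homozygosity runs) is invariant to strand and to allele
#' relabeling.
#'
#' Markers are sorted by (chromosome, position) with chromosome order taken
#' from `autosomes`. Markers on chromosomes outside `autosomes` are dropped
#' with a message; duplicated (chromosome, position) pairs keep the first
#' occurrence with a warning. Positions are 1-based physical coordinates.
#'
#' @param calls integer matrix, samples x markers, values 0/1/2/`NA`.
#' @param map data.frame with columns `chrom`, `id`, `pos_bp` and optionally
#'   `allele_a`, `allele_b` (single characters; default `"A"`/`"B"`).
#' @param samples data.frame with column `sample_id` and optional
#'   `population`, `birth_year`; or a character vector of ids.
#' @param autosomes character vector of admissible chromosome labels, in
#'   karyotype order.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `map`, `samples` and attribute-like element `autosomes`.
#' @export
genotype_matrix <- function(calls, map, samples, autosomes = horse_autosomes()) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.character(samples)) samples <- data.frame(sample_id = samples)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% names(samples))
  samples$sample_id <- as.character(samples$sample_id)
  if (is.null(samples$population)) samples$population <- NA_character_
  if (is.null(samples$birth_year)) samples$birth_year <- NA_integer_

  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "id", "pos_bp") %in% names(map)))
  map$chrom <- as.character(map$chrom)
  map$id <- as.character(map$id)
  map$pos_bp <- as.integer(map$pos_bp)
  if (is.null(map$allele_a)) map$allele_a <- rep("A", nrow(map))
  if (is.null(map$allele_b)) map$allele_b <- rep("B", nrow(map))

  if (nrow(map) != ncol(calls))
    stop("map has ", nrow(map), " markers but calls has ", ncol(calls), " columns")
  if (nrow(samples) != nrow(calls))
    stop("sample registry has ", nrow(samples), " rows but calls has ",
         nrow(calls), " rows")
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("calls contain values other than 0/1/2/NA")

  keep <- map$chrom %in% autosomes
  if (any(!keep)) {
    message("dropping ", sum(!keep), " marker(s) on non-autosomal chromosome(s)")
    map <- map[keep, , drop = FALSE]
    calls <- calls[, keep, drop = FALSE]
  }
  if (nrow(map) > 0L) {
    ord <- order(match(map$chrom, autosomes), map$pos_bp)
    map <- map[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
    dup <- duplicated(map[, c("chrom", "pos_bp")])
    if (any(dup)) {
      warning("keeping first of ", sum(dup), " duplicated (chrom, position) marker(s)")
      map <- map[!dup, , drop = FALSE]
      calls <- calls[, !dup, drop = FALSE]
    }
  }
  rownames(map) <- NULL
  rownames(samples) <- NULL
  dimnames(calls) <- list(samples$sample_id, map$id)

  structure(list(calls = calls, map = map, samples = samples,
                 autosomes = autosomes),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "markers\n")
  if (ncol(x$calls) > 0L)
    cat("  chromosomes:", length(unique(x$map$chrom)),
        " missing rate:", signif(mean(is.na(x$calls)), 3), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix].
#' @param i sample index (logical/integer).
#' @param j marker index (logical/integer).
#' @param ... unused.
#' @return A `genotype_matrix` restricted to the selected samples/markers.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  genotype_matrix(x$calls[i, j, drop = FALSE],
                  x$map[j, , drop = FALSE],
                  x$samples[i, , drop = FALSE],
                  autosomes = x$autosomes)
}

# allele-b frequency per marker over non-missing calls; NA where no calls
allele_freq <- function(g) {
  nn <- colSums(!is.na(g$calls))
  s <- colSums(g$calls, na.rm = TRUE)
  ifelse(nn > 0L, s / (2 * nn), NA_real_)
}
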