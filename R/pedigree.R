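#' Construct a pedigree
#'
#' Validates and topologically orders a parent map. Unknown parents
#' (`NA`, `"0"` or `""`) are treated as founders; parents that appear only
#' as sire/dam are added as founder records. Cycles (an individual being
#' its own ancestor) are rejected with the offending ids named.
#'
#' @param df data.frame with columns `id`, `sire`, `dam` and optional
#'   `birth_year`.
#' @return A data.frame of class `pedigree` with character `id`/`sire`/`dam`
#'   (`NA` = unknown), ordered so parents precede offspring.
#' @export
pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "sire", "dam") %in% names(df)))
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "")] <- NA
    x
  }
  df$id <- as.character(df$id)
  df$sire <- clean(df$sire)
  df$dam <- clean(df$dam)
  if (is.null(df$birth_year)) df$birth_year <- NA_integer_
  if (anyDuplicated(df$id)) stop("duplicated individual ids in pedigree")
  extra <- setdiff(stats::na.omit(c(df$sire, df$dam)), df$id)
  if (length(extra))
    df <- rbind(df, data.frame(id = extra, sire = NA, dam = NA,
                               birth_year = NA_integer_,
                               stringsAsFactors = FALSE))
  # Kahn topological sort; leftovers indicate a cycle
  n <- nrow(df)
  idx <- stats::setNames(seq_len(n), df$id)
  ps <- idx[df$sire]; pd <- idx[df$dam]
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) for (p in c(ps[i], pd[i])) if (!is.na(p)) {
    indeg[i] <- indeg[i] + 1L
    kids[[p]] <- c(kids[[p]], i)
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order_out <- c(order_out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(order_out) < n)
    stop("pedigree contains a cycle involving: ",
         paste(df$id[setdiff(seq_len(n), order_out)], collapse = ", "))
  out <- df[order_out, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Read a pedigree file
#'
#' TSV/CSV with 3-4 columns: id, sire, dam and optionally birth year
#' (header optional; `0` or empty marks an unknown parent).
#'
#' @param path file path.
#' @param sep field separator (`"\t"` default; `","` for CSV).
#' @return A [pedigree].
#' @export
read_pedigree <- function(path, sep = "\t") {
  first <- readLines(path, n = 1)
  has_header <- grepl("id", strsplit(first, sep)[[1]][1], ignore.case = TRUE)
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!has_header)
    names(df) <- c("id", "sire", "dam", "birth_year")[seq_len(ncol(df))]
  if (!is.null(df$birth_year)) df$birth_year <- as.integer(df$birth_year)
  pedigree(df)
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat("pedigree:", nrow(x), "individuals (", founders, "founders )\n")
  invisible(x)
}

#' Generation equivalents
#'
#' Pedigree completeness per individual: the sum over all known ancestor
#' positions of `(1/2)^depth` (depth 1 = parents), computed by the
#' recursion `ge(i) = sum over known parents p of (1/2)(1 + ge(p))`.
#' Founders score 0; a fully known g-generation pedigree scores g.
#'
#' @param p a [pedigree].
#' @param ids individuals to report (default: all).
#' @return Named numeric vector of generation equivalents.
#' @export
generation_equivalents <- function(p, ids = p$id) {
  stopifnot(inherits(p, "pedigree"))
  idx <- stats::setNames(seq_len(nrow(p)), p$id)
  ge <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {       # parents precede offspring
    for (par in c(p$sire[i], p$dam[i])) {
      if (!is.na(par)) ge[i] <- ge[i] + 0.5 * (1 + ge[idx[[par]]])
    }
  }
  stats::setNames(ge[idx[ids]], ids)
}

#' Additive kinship matrix
#'
#' Tabular-method kinship (coancestry) for a set of individuals:
#' `phi(i,i) = (1 + F_i)/2` with `F_i` the kinship of i's parents, and
#' `phi(i,j) = (phi(sire_i, j) + phi(dam_i, j))/2` for j processed before
#' i; unknown parents contribute zero (founder assumption). Computed over
#' the whole pedigree, returned for `ids`.
#'
#' @param p a [pedigree].
#' @param ids individuals to return (default: all).
#' @return Symmetric kinship matrix with dimnames `ids`.
#' @export
kinship_matrix <- function(p, ids = p$id) {
  stopifnot(inherits(p, "pedigree"))
  n <- nrow(p)
  idx <- stats::setNames(seq_len(n), p$id)
  ps <- idx[p$sire]; pd <- idx[p$dam]   # NA for unknown (parents precede)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ps[i]; d <- pd[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + K[s, j]
      if (!is.na(d)) row <- row + K[d, j]
      K[i, j] <- K[j, i] <- row / 2
    }
    fi <- if (!is.na(s) && !is.na(d)) K[s, d] else 0
    K[i, i] <- 0.5 * (1 + fi)
  }
  K <- K[idx[ids], idx[ids], drop = FALSE]
  dimnames(K) <- list(ids, ids)
  K
}

#' Pedigree inbreeding coefficients
#'
#' Wright's F via the tabular relationship recursion:
#' `F_i = kinship(sire_i, dam_i)`; individuals with an unknown parent get
#' zero (founder assumption).
#'
#' @param p a [pedigree].
#' @param ids individuals to report (default: all).
#' @return Named numeric vector of F_PED values.
#' @export
ped_inbreeding <- function(p, ids = p$id) {
  K <- kinship_matrix(p)
  idx <- stats::setNames(seq_len(nrow(p)), p$id)
  f <- ifelse(is.na(p$sire) | is.na(p$dam), 0,
              K[cbind(idx[p$sire], idx[p$dam])])
  stats::setNames(f, p$id)[ids]
}

#' Coancestry-rate effective population size
#'
#' For every pair (j, k) in the reference cohort the individual rate of
#' increase in coancestry is
#' `dc_jk = 1 - (1 - c_jk)^(1 / ((ge_j + ge_k)/2))`, with `c_jk` the
#' pairwise kinship and `ge` the generation equivalents; the realized
#' effective size is `Ne = 1 / (2 * mean(dc))`. A cohort of mutually
#' unrelated individuals has zero mean rate and `Ne = Inf` (flagged).
#'
#' @param p a [pedigree].
#' @param cohort ids of the reference cohort (>= 2 individuals); default
#'   all non-founders.
#' @return A list of class `ne_coancestry`: `ne`, `mean_delta_c`,
#'   `n_pairs`, `cohort_size`.
#' @export
ne_coancestry <- function(p, cohort = NULL) {
  stopifnot(inherits(p, "pedigree"))
  if (is.null(cohort)) cohort <- p$id[!(is.na(p$sire) & is.na(p$dam))]
  if (length(cohort) < 2) stop("cohort must contain at least 2 individuals")
  K <- kinship_matrix(p, cohort)
  ge <- generation_equivalents(p, cohort)
  iu <- which(upper.tri(K), arr.ind = TRUE)
  c_jk <- K[iu]
  g_jk <- (ge[iu[, 1]] + ge[iu[, 2]]) / 2
  dc <- ifelse(c_jk == 0, 0,
               ifelse(g_jk > 0, 1 - (1 - c_jk)^(1 / g_jk), NA_real_))
  if (anyNA(dc)) {
    warning(sum(is.na(dc)), " related pair(s) with zero generation ",
            "equivalents excluded")
    dc <- dc[!is.na(dc)]
  }
  mdc <- mean(dc)
  structure(list(ne = if (mdc > 0) 1 / (2 * mdc) else Inf,
                 mean_delta_c = mdc, n_pairs = length(dc),
                 cohort_size = length(cohort)),
            class = "ne_coancestry")
}

#' @export
print.ne_coancestry <- function(x, ...) {
  cat(sprintf(
    "coancestry-rate Ne: %s (mean rate %.5g over %d pairs, cohort %d)\n",
    if (is.finite(x$ne)) sprintf("%.1f", x$ne) else "Inf (unrelated cohort)",
    x$mean_delta_c, x$n_pairs, x$cohort_size))
  invisible(x)
}

#' Summarize a pedigree
#'
#' Per-individual F_PED and generation equivalents plus cohort means —
#' the standard pedigree-quality report.
#'
#' @param p a [pedigree].
#' @param cohort optional reference cohort for [ne_coancestry].
#' @return list: `by_individual` (data.frame `id`, `f_ped`, `ge`,
#'   `birth_year`), `mean_f_ped`, `mean_ge`, `ne` (coancestry Ne object or
#'   `NULL` when the cohort has < 2 members).
#' @export
pedigree_summary <- function(p, cohort = NULL) {
  f <- ped_inbreeding(p)
  ge <- generation_equivalents(p)
  by_ind <- data.frame(id = p$id, f_ped = unname(f), ge = unname(ge),
                       birth_year = p$birth_year, stringsAsFactors = FALSE)
  ne <- tryCatch(ne_coancestry(p, cohort), error = function(e) NULL)
  list(by_individual = by_ind, mean_f_ped = mean(f), mean_ge = mean(ge),
       ne = ne)
}
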