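#' Full-analysis run configuration
#'
#' One declarative object for the whole pipeline: per-population input
#' prefixes, QC thresholds, ROH scan parameters, Ne settings, optional
#' pedigree, island threshold and output directory. Round-trips losslessly
#' through YAML ([write_run_config] / [read_run_config]).
#'
#' @param populations named list; each element a list with `prefix` (PLINK
#'   fileset prefix) and optional `metadata` (sample TSV path).
#' @param out_dir output directory (created if absent).
#' @param qc_roh,qc_diversity [qc_config] objects for the two profiles.
#' @param roh a [roh_params].
#' @param ne an [ne_config], or `NULL` to skip the Ne stage.
#' @param pedigree_path optional pedigree file for the pedigree stage.
#' @param pedigree_cohort optional `c(from, to)` birth-year interval
#'   selecting the coancestry-Ne reference cohort.
#' @param island_threshold ROH-island incidence threshold.
#' @param L_auto optional autosomal-length override (bp) for F_ROH.
#' @param seed seed for any capped subsampling.
#' @return A list of class `run_config`.
#' @export
run_config <- function(populations, out_dir,
                       qc_roh = qc_config(profile = "roh"),
                       qc_diversity = qc_config(profile = "diversity"),
                       roh = roh_params(), ne = ne_config(),
                       pedigree_path = NULL, pedigree_cohort = NULL,
                       island_threshold = 0.70, L_auto = NULL, seed = 1L) {
  stopifnot(length(populations) >= 1, !is.null(names(populations)))
  structure(list(populations = populations, out_dir = out_dir,
                 qc_roh = qc_roh, qc_diversity = qc_diversity, roh = roh,
                 ne = ne, pedigree_path = pedigree_path,
                 pedigree_cohort = pedigree_cohort,
                 island_threshold = island_threshold, L_auto = L_auto,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  plain <- rapply(unclass(cfg), identity, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  as_cfg <- function(lst, maker) do.call(maker, lst[names(lst) %in%
                                                      names(formals(maker))])
  run_config(populations = x$populations, out_dir = x$out_dir,
             qc_roh = as_cfg(x$qc_roh, qc_config),
             qc_diversity = as_cfg(x$qc_diversity, qc_config),
             roh = as_cfg(x$roh, roh_params),
             ne = if (is.null(x$ne)) NULL else as_cfg(x$ne, ne_config),
             pedigree_path = x$pedigree_path,
             pedigree_cohort = x$pedigree_cohort,
             island_threshold = x$island_threshold,
             L_auto = x$L_auto, seed = x$seed)
}

write_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full diversity analysis
#'
#' Executes every stage for every configured population — QC (both
#' profiles), heterozygosity, ROH detection, F_ROH, descriptive table,
#' incidence and islands, LD-based Ne, coverage validation — plus the
#' pedigree stage and the cross-population island overlap when applicable,
#' and writes a deterministic TSV bundle with a machine-readable manifest
#' (inputs, parameters, package version, output hashes). A stage failure
#' aborts with the stage name; outputs written so far are retained next to
#' a `FAILED` marker file.
#'
#' @param cfg a [run_config].
#' @return Invisibly, a named list of written file paths.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  for (pop in cfg$populations)
    if (!file.exists(paste0(pop$prefix, ".bed")) &&
        !file.exists(paste0(pop$prefix, ".ped")))
      stop("no PLINK fileset at prefix ", pop$prefix)
  if (!is.null(cfg$pedigree_path) && !file.exists(cfg$pedigree_path))
    stop("pedigree file not found: ", cfg$pedigree_path)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  stage <- "setup"
  on.exit(if (!identical(stage, "done")) {
    writeLines(paste("failed at stage:", stage),
               file.path(cfg$out_dir, "FAILED"))
  })

  qc_rows <- list(); het_rows <- list(); roh_sets <- list()
  froh_rows <- list(); desc_rows <- list(); island_sets <- list()
  inc_rows <- list(); ne_rows <- list(); cov_lines <- character()

  for (pname in names(cfg$populations)) {
    pop <- cfg$populations[[pname]]
    stage <- paste0("read:", pname)
    g <- read_plink(pop$prefix, metadata = pop$metadata)
    if (all(is.na(g$samples$population))) g$samples$population <- pname

    stage <- paste0("qc:", pname)
    qr <- apply_qc(g, cfg$qc_roh)
    qd <- apply_qc(g, cfg$qc_diversity)
    qc_rows[[pname]] <- cbind(population = pname,
                              rbind(cbind(profile = "roh", qc_report_df(qr)),
                                    cbind(profile = "diversity",
                                          qc_report_df(qd))))

    stage <- paste0("het:", pname)
    het <- observed_het(qd$genotypes)
    ch <- expected_het(qd$genotypes)
    het_rows[[pname]] <- cbind(population = pname, het,
                               mean_h_exp = ch$mean_h_exp)

    stage <- paste0("roh:", pname)
    runs <- detect_roh(qr$genotypes, cfg$roh)
    roh_sets[[pname]] <- cbind(population = pname, as.data.frame(runs))
    lens <- genome_lengths(qr$genotypes$map, L_auto = cfg$L_auto)
    fr <- froh(runs, lengths = lens)
    froh_rows[[pname]] <- cbind(population = pname, fr$by_sample)
    desc_rows[[pname]] <- descriptive_table(runs)
    cov_lines <- c(cov_lines, sprintf(
      "%s\tdetectable_fraction\t%.6f", pname,
      coverage_validation(qr$genotypes$map, cfg$roh, lens)))

    stage <- paste0("islands:", pname)
    inc <- island_incidence(runs, qr$genotypes)
    inc_rows[[pname]] <- cbind(population = pname, as.data.frame(inc))
    island_sets[[pname]] <- call_islands(inc, cfg$island_threshold)

    if (!is.null(cfg$ne)) {
      stage <- paste0("ne:", pname)
      tr <- tryCatch(estimate_ne(qd$genotypes, cfg$ne),
                     error = function(e) NULL)
      if (!is.null(tr))
        ne_rows[[pname]] <- cbind(population = pname, as.data.frame(tr))
    }
  }

  stage <- "write"
  out$qc_report <- write_tsv(do.call(rbind, qc_rows), cfg$out_dir,
                             "qc_report.tsv")
  out$het <- write_tsv(do.call(rbind, het_rows), cfg$out_dir, "het.tsv")
  out$roh <- write_tsv(do.call(rbind, roh_sets), cfg$out_dir, "roh.tsv")
  out$froh <- write_tsv(do.call(rbind, froh_rows), cfg$out_dir, "froh.tsv")
  out$descriptive <- write_tsv(do.call(rbind, desc_rows), cfg$out_dir,
                               "descriptive_table.tsv")
  out$incidence <- write_tsv(do.call(rbind, inc_rows), cfg$out_dir,
                             "incidence.tsv")
  isl <- do.call(rbind, lapply(names(island_sets), function(p)
    if (nrow(island_sets[[p]])) cbind(population = p, island_sets[[p]])))
  if (is.null(isl))
    isl <- data.frame(population = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer())
  out$islands <- write_tsv(isl, cfg$out_dir, "islands.tsv")
  if (nrow(isl) > 0)
    out$islands_bed <- export_bed(
      data.frame(chrom = isl$chrom, start_bp = isl$start_bp,
                 end_bp = isl$end_bp, name = isl$population,
                 score = isl$peak_incidence),
      file.path(cfg$out_dir, "islands.bed"))
  if (length(island_sets) >= 2) {
    ov <- overlap_islands(island_sets[[1]], island_sets[[2]])
    out$islands_shared <- write_tsv(ov, cfg$out_dir, "islands_shared.tsv")
  }
  if (length(ne_rows))
    out$ne <- write_tsv(do.call(rbind, ne_rows), cfg$out_dir, "ne.tsv")
  writeLines(cov_lines, file.path(cfg$out_dir, "coverage_check.txt"))
  out$coverage <- file.path(cfg$out_dir, "coverage_check.txt")

  if (!is.null(cfg$pedigree_path)) {
    stage <- "pedigree"
    ped <- read_pedigree(cfg$pedigree_path)
    cohort <- NULL
    if (!is.null(cfg$pedigree_cohort)) {
      by <- ped$birth_year
      cohort <- ped$id[!is.na(by) & by >= cfg$pedigree_cohort[1] &
                         by <= cfg$pedigree_cohort[2]]
    }
    ps <- pedigree_summary(ped, cohort)
    out$pedigree <- write_tsv(ps$by_individual, cfg$out_dir, "pedigree.tsv")
    writeLines(c(sprintf("mean_f_ped\t%.6f", ps$mean_f_ped),
                 sprintf("mean_ge\t%.4f", ps$mean_ge),
                 sprintf("ne_coancestry\t%s",
                         if (is.null(ps$ne)) "NA" else
                           format(ps$ne$ne, digits = 6))),
               file.path(cfg$out_dir, "pedigree_summary.txt"))
    out$pedigree_summary <- file.path(cfg$out_dir, "pedigree_summary.txt")
  }

  stage <- "manifest"
  files <- unlist(out)
  manifest <- list(
    package = "equidiv",
    version = as.character(utils::packageVersion("equidiv")),
    inputs = lapply(cfg$populations, function(p) p$prefix),
    parameters = rapply(unclass(cfg[c("qc_roh", "qc_diversity", "roh", "ne",
                                      "island_threshold", "seed")]),
                        identity, how = "replace"),
    outputs = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  out$manifest <- file.path(cfg$out_dir, "manifest.yaml")
  stage <- "done"
  invisible(out)
}
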