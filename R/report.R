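#' Cohort-level summary report
#'
#' Assembles the cohort statistics into one machine-readable structure:
#' demographics, overlapping age-group sizes, the combined
#' forensic/molecular diagnostic-yield table, and (when death timestamps
#' are present) the temporal histograms with the clock-window fraction.
#' All thresholds used are echoed into the report for provenance.
#'
#' @param cases case table from [read_case_table()] or
#'   [generate_cases()].
#' @param window_start,window_end clock window passed to
#'   [temporal_histograms()].
#' @return a list of class `cohort_report`.
#' @export
cohort_report <- function(cases, window_start = 8, window_end = 20) {
  yt <- yield_table(cases)
  ag <- age_groups(cases)
  dem <- demographics(cases)
  tmp <- temporal_histograms(cases, window_start, window_end)
  structure(list(
    schema_version = "1.0",
    n_cases = yt$n,
    demographics = dem,
    age_groups = list(infants = nrow(ag$infants),
                      minors = nrow(ag$minors),
                      full = nrow(ag$full)),
    yield = list(counts = yt$counts, percent = yt$percent,
                 ma_positive = yt$ma_positive,
                 ma_positive_pct = 100 * yt$ma_positive / yt$n,
                 fa_positive = yt$fa_positive,
                 fa_positive_pct = 100 * yt$fa_positive / yt$n),
    temporal = tmp,
    parameters = list(infant_max_months = 12, minor_max_years = 18,
                      window_start = window_start,
                      window_end = window_end)),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Molecular-autopsy cohort report (n =", x$n_cases, ")\n")
  cat(sprintf("  MA positive: %d (%.0f%%); FA positive: %d (%.0f%%)\n",
              x$yield$ma_positive, x$yield$ma_positive_pct,
              x$yield$fa_positive, x$yield$fa_positive_pct))
  cat("  Yield table (MA rows x FA columns):\n")
  print(x$yield$counts)
  cat(sprintf("  Sex: %d female / %d male; infants: %d; minors: %d\n",
              x$demographics$sex[["female"]], x$demographics$sex[["male"]],
              x$age_groups$infants, x$age_groups$minors))
  invisible(x)
}

#' Write a report as JSON
#'
#' @param report any report list (e.g. [cohort_report()]).
#' @param path output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       force = TRUE)
  invisible(path)
}

#' Write synthetic cases in the case-table dialect
#'
#' @param cases case table.
#' @param path output TSV.
#' @export
write_case_table <- function(cases, path) {
  out <- data.frame(
    case_id = cases$case_id,
    age = ifelse(cases$age_months <= 12,
                 paste(cases$age_months, "months"),
                 format(cases$age_months / 12, trim = TRUE)),
    sex = paste0(toupper(substr(cases$sex, 1, 1)),
                 substr(cases$sex, 2, nchar(cases$sex))),
    race = ifelse(is.na(cases$race), "NA", cases$race),
    fa_status = ifelse(cases$fa_status == "positive", "Positive",
                       "Negative"),
    fa_summary = ifelse(is.na(cases$fa_summary), "-", cases$fa_summary),
    ma_status = ifelse(cases$ma_status == "positive", "Positive",
                       "Negative"),
    death_time = ifelse(is.na(cases$death_time), "NA",
                        format(cases$death_time, "%Y-%m-%dT%H:%M:%S",
                               tz = "UTC")),
    site_label = cases$site_label,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

usage_text <- function() {
  paste(
    "usage: ma <subcommand> [--flag value ...]",
    "subcommands:",
    "  simulate       --out DIR [--n-cases N] [--seed S]",
    "  filter         --variants FILE [--dialect tsv|vcf]",
    "                 [--internal-maf 0.05] [--kg-maf 0.01]",
    "                 [--out filtered.tsv] [--report report.json]",
    "  panel-compare  --variants FILE --panel FILE [--min-likely 0]",
    "                 [--out genes.tsv]",
    "  cooccur        --variants FILE [--out sharing.tsv]",
    "  fingerprint    --variants FILE [--categories 1,2,3]",
    "                 [--z-threshold 3] [--out fp.json]",
    "  mtdna          --variants FILE [--pedigree FILE] [--hf-low 0.2]",
    "                 [--hf-high 0.95] [--maf 0.05] [--out mtdna.tsv]",
    "  cohort-report  --cases FILE [--out report.json]",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    if (i == length(args))
      stop("flag ", a, " needs a value", call. = FALSE)
    flags[[substring(a, 3)]] <- args[i + 1]
    i <- i + 2
  }
  flags
}

flag_or <- function(flags, name, default) {
  if (is.null(flags[[name]])) default else flags[[name]]
}

need_flag <- function(flags, name) {
  if (is.null(flags[[name]]))
    stop("missing required flag --", name, call. = FALSE)
  flags[[name]]
}

#' Command-line entry point
#'
#' Dispatcher behind the `ma` command (`inst/cli/ma.R`): thin wrappers
#' over the exported analysis functions, one subcommand per pipeline
#' stage. Outputs are tab-separated tables plus a machine-readable JSON
#' report; every threshold used is echoed into the report.
#'
#' @param argv character vector of command-line arguments.
#' @return exit code, invisibly: 0 success, 1 analysis error,
#'   2 usage error.
#' @export
ma_run <- function(argv = character()) {
  if (length(argv) == 0) {
    message(usage_text())
    return(invisible(2L))
  }
  sub <- argv[1]
  known <- c("simulate", "filter", "panel-compare", "cooccur",
             "fingerprint", "mtdna", "cohort-report")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub, "\n", usage_text())
    return(invisible(2L))
  }
  flags <- tryCatch(parse_flags(argv[-1]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags), "\n", usage_text())
    return(invisible(2L))
  }
  res <- tryCatch({
    switch(sub,
           "simulate" = cli_simulate(flags),
           "filter" = cli_filter(flags),
           "panel-compare" = cli_panel_compare(flags),
           "cooccur" = cli_cooccur(flags),
           "fingerprint" = cli_fingerprint(flags),
           "mtdna" = cli_mtdna(flags),
           "cohort-report" = cli_cohort_report(flags))
    0L
  }, error = function(e) {
    message("ma ", sub, ": ", conditionMessage(e))
    1L
  })
  invisible(res)
}

cli_simulate <- function(flags) {
  out_dir <- need_flag(flags, "out")
  cfg <- generator_config(
    n_cases = as.integer(flag_or(flags, "n-cases", 50)),
    seed = as.integer(flag_or(flags, "seed", 1)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cases <- generate_cases(cfg)
  variants <- generate_variants(cases, cfg)
  ped <- generate_pedigree(cases)
  mt <- generate_mtdna(cases, ped, cfg)
  write_case_table(cases, file.path(out_dir, "cases.tsv"))
  write_variant_table(variants, file.path(out_dir, "variants.tsv"))
  write_variant_table(mt, file.path(out_dir, "mtdna.tsv"))
  utils::write.table(ped, file.path(out_dir, "pedigree.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  writeLines(cfg$genes$gene[cfg$genes$in_panel],
             file.path(out_dir, "panel.txt"))
  invisible(NULL)
}

cli_filter <- function(flags) {
  v <- read_variant_table(need_flag(flags, "variants"),
                          dialect = flag_or(flags, "dialect", "tsv"))
  res <- cascade_cohort(
    v, internal_maf_cut = as.numeric(flag_or(flags, "internal-maf", 0.05)),
    kg_maf_cut = as.numeric(flag_or(flags, "kg-maf", 0.01)))
  write_variant_table(res$variants, flag_or(flags, "out", "filtered.tsv"))
  report <- list(schema_version = "1.0",
                 parameters = list(
                   internal_maf_cut = as.numeric(flag_or(flags,
                                                         "internal-maf",
                                                         0.05)),
                   kg_maf_cut = as.numeric(flag_or(flags, "kg-maf", 0.01))),
                 per_sample = res$report)
  write_report_json(report, flag_or(flags, "report", "report.json"))
  invisible(NULL)
}

cli_panel_compare <- function(flags) {
  v <- read_variant_table(need_flag(flags, "variants"))
  panel <- read_panel(need_flag(flags, "panel"))
  ga <- gene_abundance(restrict_to_panel(v, panel),
                       min_likely = as.numeric(flag_or(flags,
                                                       "min-likely", 0)))
  utils::write.table(ga, flag_or(flags, "out", "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

cli_cooccur <- function(flags) {
  v <- read_variant_table(need_flag(flags, "variants"))
  prof <- build_sharing_profiles(v)
  utils::write.table(prof, flag_or(flags, "out", "sharing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

cli_fingerprint <- function(flags) {
  v <- read_variant_table(need_flag(flags, "variants"))
  cats <- as.integer(strsplit(flag_or(flags, "categories", "1,2,3"),
                              ",")[[1]])
  fp <- fingerprint(v, categories = cats,
                    z_threshold = as.numeric(flag_or(flags, "z-threshold",
                                                     3)))
  out <- flag_or(flags, "out", "fp.json")
  write_report_json(list(schema_version = "1.0",
                         parameters = list(categories = cats),
                         sample_ids = fp$sample_ids,
                         top_pairs = fp$top_pairs), out)
  base <- sub("\\.json$", "", out)
  utils::write.table(fp$jaccard, paste0(base, "_jaccard.tsv"), sep = "\t",
                     quote = FALSE)
  utils::write.table(fp$zscores, paste0(base, "_zscores.tsv"), sep = "\t",
                     quote = FALSE)
  invisible(NULL)
}

cli_mtdna <- function(flags) {
  v <- read_variant_table(need_flag(flags, "variants"))
  hf_low <- as.numeric(flag_or(flags, "hf-low", 0.2))
  hf_high <- as.numeric(flag_or(flags, "hf-high", 0.95))
  maf <- as.numeric(flag_or(flags, "maf", 0.05))
  profiles <- lapply(split(v, v$sample_id), filter_heteroplasmic,
                     hf_low = hf_low, hf_high = hf_high, maf_cut = maf)
  if (!is.null(flags[["pedigree"]])) {
    ped <- read_pedigree(flags[["pedigree"]])
    for (i in seq_len(nrow(ped))) {
      pid <- ped$proband_sample[i]
      if (!pid %in% names(profiles)) next
      get_profile <- function(id)
        if (!is.na(id) && id %in% names(profiles)) profiles[[id]] else NULL
      profiles[[pid]] <- maternal_sharing(
        profiles[[pid]],
        mother = get_profile(ped$mother_sample[i]),
        father = get_profile(ped$father_sample[i]))
    }
  }
  utils::write.table(profiles_to_df(profiles),
                     flag_or(flags, "out", "mtdna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(NULL)
}

cli_cohort_report <- function(flags) {
  cases <- read_case_table(need_flag(flags, "cases"))
  rep <- cohort_report(cases)
  write_report_json(rep, flag_or(flags, "out", "report.json"))
  invisible(NULL)
}
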