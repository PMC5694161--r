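#' @keywords internal
"_PACKAGE"

## Controlled vocabularies shared across the pipeline.

#' Effect classes recognised by the pipeline
#'
#' Functional consequence classes a variant record may carry. Records read
#' from annotated input with an unrecognised class are mapped to `"other"`
#' with a warning.
#'
#' @export
EFFECT_CLASSES <- c("missense", "nonsense", "frameshift", "splice",
                    "synonymous", "noncoding", "other")

#' @rdname EFFECT_CLASSES
#' @export
ZYGOSITY_LEVELS <- c("het", "hom", "hemi")

## Contig names accepted as the mitochondrial genome.
MT_CONTIGS <- c("MT", "chrM", "chrMT", "M", "mt")

is_mt_contig <- function(chrom) chrom %in% MT_CONTIGS

#' Construct a variant table
#'
#' Builds the canonical per-sample annotated variant table used throughout
#' the package: one row per called alternate allele in one sample, carrying
#' the gene symbol, functional effect class, QC flag, internal-cohort and
#' 1000 Genomes allele frequencies, pathogenicity category (1--5) and, for
#' mitochondrial records, reference/alternate allelic depths.
#'
#' @param sample_id,chrom,pos,ref,alt required record identity fields;
#'   `pos` is 1-based.
#' @param gene gene symbol or `NA` for unassigned loci.
#' @param effect one of [EFFECT_CLASSES].
#' @param qc_pass logical QC flag.
#' @param af_internal,af_1kg allele frequencies in `[0, 1]`; `NA` means
#'   unobserved (treated as rare by the frequency filters).
#' @param category pathogenicity category 1--5 or `NA`.
#' @param zygosity one of [ZYGOSITY_LEVELS].
#' @param depth_ref,depth_alt non-negative allelic read depths or `NA`.
#' @return a `data.frame` with one row per variant call.
#' @export
variant_table <- function(sample_id, chrom, pos, ref, alt,
                          gene = NA_character_, effect = "other",
                          qc_pass = TRUE,
                          af_internal = NA_real_, af_1kg = NA_real_,
                          category = NA_integer_, zygosity = "het",
                          depth_ref = NA_integer_, depth_alt = NA_integer_) {
  n <- length(pos)
  df <- data.frame(
    sample_id = rep_len(as.character(sample_id), n),
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(pos),
    ref = rep_len(as.character(ref), n),
    alt = rep_len(as.character(alt), n),
    gene = rep_len(as.character(gene), n),
    effect = rep_len(as.character(effect), n),
    qc_pass = rep_len(as.logical(qc_pass), n),
    af_internal = rep_len(as.numeric(af_internal), n),
    af_1kg = rep_len(as.numeric(af_1kg), n),
    category = rep_len(as.integer(category), n),
    zygosity = rep_len(as.character(zygosity), n),
    depth_ref = rep_len(as.integer(depth_ref), n),
    depth_alt = rep_len(as.integer(depth_alt), n),
    stringsAsFactors = FALSE
  )
  df
}

VARIANT_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt", "gene",
                     "effect", "qc_pass", "af_internal", "af_1kg",
                     "category", "zygosity", "depth_ref", "depth_alt")

#' Validate a variant table
#'
#' Applies the record invariants (positive 1-based position, distinct
#' non-empty alleles, frequencies in `[0, 1]`, category in 1--5,
#' non-negative depths, recognised effect class). Invalid rows are dropped
#' with a warning naming the offending rows; they are never silently lost.
#'
#' @param variants a variant table.
#' @param warn emit a warning describing dropped rows (default `TRUE`).
#' @return the table restricted to valid rows, with an attribute
#'   `n_dropped` giving the number removed.
#' @export
validate_variant_table <- function(variants, warn = TRUE) {
  missing_cols <- setdiff(VARIANT_COLUMNS, names(variants))
  if (length(missing_cols) > 0)
    stop("variant table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  ok <- !is.na(variants$pos) & variants$pos >= 1L &
    !is.na(variants$ref) & !is.na(variants$alt) &
    nzchar(variants$ref) & nzchar(variants$alt) &
    variants$ref != variants$alt &
    (is.na(variants$af_internal) |
       (variants$af_internal >= 0 & variants$af_internal <= 1)) &
    (is.na(variants$af_1kg) |
       (variants$af_1kg >= 0 & variants$af_1kg <= 1)) &
    (is.na(variants$category) | variants$category %in% 1:5) &
    (is.na(variants$depth_ref) | variants$depth_ref >= 0L) &
    (is.na(variants$depth_alt) | variants$depth_alt >= 0L) &
    variants$effect %in% EFFECT_CLASSES &
    variants$zygosity %in% ZYGOSITY_LEVELS
  ok[is.na(ok)] <- FALSE
  n_bad <- sum(!ok)
  if (n_bad > 0 && warn)
    warning(n_bad, " variant record(s) failed validation and were excluded",
            " (rows: ", paste(utils::head(which(!ok), 10), collapse = ", "),
            if (n_bad > 10) ", ..." else "", ")")
  out <- variants[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_bad
  out
}

#' Read an annotated variant table
#'
#' Reads per-sample annotated variant calls from either a tab-delimited
#' table (one column per [variant_table] field) or a VCF 4.x file carrying
#' the annotation dialect `GENE`, `EFFECT`, `AF_INT`, `AF_1KG`, `CAT` in
#' the INFO column and allelic depths `AD` in the genotype column.
#' Multi-allelic VCF rows are split into one record per alternate allele.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param info_keys named character vector rebinding the VCF INFO keys, with
#'   names `gene`, `effect`, `af_internal`, `af_1kg`, `category`.
#' @return a validated variant table (invalid rows warned about and
#'   excluded).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               info_keys = c(gene = "GENE", effect = "EFFECT",
                                             af_internal = "AF_INT",
                                             af_1kg = "AF_1KG",
                                             category = "CAT")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read variant file: ", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    mandatory <- c("sample_id", "chrom", "pos", "ref", "alt")
    miss <- setdiff(mandatory, names(df))
    if (length(miss) > 0)
      stop("variant TSV lacks mandatory column(s): ",
           paste(miss, collapse = ", "))
    for (col in setdiff(VARIANT_COLUMNS, names(df)))
      df[[col]] <- switch(col,
                          qc_pass = TRUE, effect = "other", zygosity = "het",
                          category = NA_integer_,
                          depth_ref = NA_integer_, depth_alt = NA_integer_,
                          NA)
    out <- variant_table(df$sample_id, df$chrom, df$pos, df$ref, df$alt,
                         gene = df$gene, effect = df$effect,
                         qc_pass = df$qc_pass,
                         af_internal = df$af_internal, af_1kg = df$af_1kg,
                         category = df$category, zygosity = df$zygosity,
                         depth_ref = df$depth_ref, depth_alt = df$depth_alt)
  } else {
    out <- read_vcf_variants(path, info_keys)
  }
  validate_variant_table(out)
}

## VCF reading via vcfR; record building and multi-allelic splitting are
## handled here because the annotation dialect is package-specific.
read_vcf_variants <- function(path, info_keys) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) return(variant_table(character(0), character(0), integer(0),
                                   character(0), character(0)))
  info_get <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  gene <- info_get(info_keys[["gene"]])
  effect <- info_get(info_keys[["effect"]])
  af_int <- info_get(info_keys[["af_internal"]])
  af_1kg <- info_get(info_keys[["af_1kg"]])
  cat_raw <- info_get(info_keys[["category"]])
  filter_pass <- fix[, "FILTER"] %in% c("PASS", ".", NA)

  gt <- if (ncol(vcf@gt) > 1) vcf@gt else NULL
  samples <- if (is.null(gt)) "sample" else colnames(gt)[-1]
  ad <- if (!is.null(gt)) vcfR::extract.gt(vcf, element = "AD") else NULL

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    per_allele <- function(x) {
      parts <- if (is.na(x)) NA_character_ else
        strsplit(x, ",", fixed = TRUE)[[1]]
      if (length(parts) == n_alt) parts else rep(parts[1], n_alt)
    }
    for (s in samples) {
      ad_s <- if (!is.null(ad)) ad[i, s] else NA_character_
      ad_parts <- if (is.na(ad_s)) NULL else
        suppressWarnings(as.integer(strsplit(ad_s, ",", fixed = TRUE)[[1]]))
      for (a in seq_len(n_alt)) {
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = s, chrom = fix[i, "CHROM"],
          pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alts[a],
          gene = per_allele(gene[i])[a],
          effect = per_allele(effect[i])[a],
          qc_pass = filter_pass[i],
          af_internal = suppressWarnings(as.numeric(per_allele(af_int[i])[a])),
          af_1kg = suppressWarnings(as.numeric(per_allele(af_1kg[i])[a])),
          category = suppressWarnings(as.integer(per_allele(cat_raw[i])[a])),
          zygosity = "het",
          depth_ref = if (is.null(ad_parts)) NA_integer_ else ad_parts[1],
          depth_alt = if (is.null(ad_parts) || length(ad_parts) < a + 1)
            NA_integer_ else ad_parts[a + 1],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  out$effect[is.na(out$effect) | !(out$effect %in% EFFECT_CLASSES)] <- "other"
  rownames(out) <- NULL
  out
}

#' Write a variant table as TSV
#'
#' Inverse of the `"tsv"` dialect of [read_variant_table()]; a written
#' table re-reads to the identical records.
#'
#' @param variants a variant table.
#' @param path output file.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants[, VARIANT_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Normalise an age to months
#'
#' @param value numeric age value.
#' @param unit `"months"` or `"years"`.
#' @return age in months.
#' @export
age_in_months <- function(value, unit = c("years", "months")) {
  unit <- match.arg(unit)
  if (any(value < 0, na.rm = TRUE)) stop("negative age")
  if (unit == "months") value else value * 12
}

parse_age_months <- function(x) {
  x <- trimws(x)
  if (grepl("month", x, ignore.case = TRUE)) {
    v <- suppressWarnings(as.numeric(sub("\\s*months?$", "", x,
                                         ignore.case = TRUE)))
    if (is.na(v)) return(NA_real_)
    return(age_in_months(v, "months"))
  }
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) return(NA_real_)
  age_in_months(v, "years")
}

#' Read a case-metadata table
#'
#' Parses the cohort case table: one row per case with demographic fields,
#' forensic-autopsy (FA) and molecular-autopsy (MA) statuses, and an age
#' written either as `"3 months"` or as a bare number of years (the mixed
#' dialect of the source table). A sibling-pair row writes its two probands
#' with `/`-separated values (e.g. age `"17/24"`, FA `"Positive/Negative"`);
#' it expands to a single case whose *analysis proband* is the
#' forensic-autopsy-negative sibling, the cohort inclusion rule for the
#' one sibling-pair case. The analysis age of such a case is the younger
#' sibling's, which is what the cohort age-group counts use.
#'
#' @param path tab-delimited file with columns `case_id`, `age`, `sex`,
#'   `race`, `fa_status`, `fa_summary`, `ma_status` and optionally
#'   `death_time` (ISO 8601) and `site_label`.
#' @return a `data.frame` of cases with ages normalised to months
#'   (`age_months`), all proband ages kept in `ages_months_all`
#'   (`;`-separated), statuses lower-cased, and one analysis proband per
#'   case (`proband_id`).
#' @export
read_case_table <- function(path) {
  if (!file.exists(path)) stop("cannot read case file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                           na.strings = "NA", quote = "")
  mandatory <- c("case_id", "age", "sex", "fa_status", "ma_status")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss) > 0)
    stop("case table lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(raw$case_id))
    stop("duplicate case_id: ",
         paste(unique(raw$case_id[duplicated(raw$case_id)]), collapse = ", "))

  parse_row <- function(i) {
    row <- raw[i, ]
    age_parts <- strsplit(as.character(row$age), "/", fixed = TRUE)[[1]]
    fa_parts <- tolower(strsplit(as.character(row$fa_status), "/",
                                 fixed = TRUE)[[1]])
    ma_parts <- tolower(strsplit(as.character(row$ma_status), "/",
                                 fixed = TRUE)[[1]])
    n_prob <- max(length(age_parts), length(fa_parts))
    ages <- vapply(age_parts, parse_age_months, numeric(1))
    if (any(is.na(ages)))
      stop("unparseable age '", row$age, "' in case ", row$case_id)
    fa_parts <- rep_len(fa_parts, n_prob)
    ma_parts <- rep_len(ma_parts, n_prob)
    # analysis proband: the forensic-autopsy-negative sibling when the pair
    # differs, otherwise the first listed proband
    idx <- if (n_prob > 1 && any(fa_parts == "negative"))
      which(fa_parts == "negative")[1] else 1L
    proband_ids <- if (n_prob > 1)
      paste0(row$case_id, "-", sprintf("%02dP", seq_len(n_prob)))
    else row$case_id
    data.frame(
      case_id = row$case_id,
      proband_id = proband_ids[idx],
      n_probands = n_prob,
      age_months = min(ages),
      ages_months_all = paste(ages, collapse = ";"),
      sex = tolower(sub("s$", "", as.character(row$sex))),
      race = if ("race" %in% names(raw)) as.character(row$race)
             else NA_character_,
      fa_status = fa_parts[idx],
      fa_summary = if ("fa_summary" %in% names(raw))
        as.character(row$fa_summary) else NA_character_,
      ma_status = ma_parts[idx],
      death_time = if ("death_time" %in% names(raw))
        as.character(row$death_time) else NA_character_,
      site_label = if ("site_label" %in% names(raw))
        as.character(row$site_label) else substr(row$case_id, 1, 4),
      include_in_cohort = TRUE,
      stringsAsFactors = FALSE
    )
  }
  cases <- do.call(rbind, lapply(seq_len(nrow(raw)), parse_row))
  bad_sex <- !cases$sex %in% c("male", "female")
  if (any(bad_sex))
    stop("unrecognised sex value(s): ",
         paste(unique(cases$sex[bad_sex]), collapse = ", "))
  bad_status <- !cases$fa_status %in% c("positive", "negative") |
    !cases$ma_status %in% c("positive", "negative")
  if (any(bad_status))
    stop("unrecognised autopsy status in case(s): ",
         paste(cases$case_id[bad_status], collapse = ", "))
  cases$death_time <- as.POSIXct(cases$death_time, tz = "UTC",
                                 tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                "%Y-%m-%d %H:%M:%S",
                                                "%Y-%m-%d"))
  rownames(cases) <- NULL
  cases
}

#' Read a gene-panel definition
#'
#' Plain-text gene list, one symbol per line; `#` starts a comment.
#' Symbols are upper-cased and de-duplicated.
#'
#' @param path file of gene symbols.
#' @param name panel name (defaults to the file name).
#' @return an object of class `panel_definition` with elements `name`
#'   and `genes`.
#' @export
read_panel <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("cannot read panel file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  genes <- toupper(trimws(lines))
  genes <- unique(genes[nzchar(genes)])
  if (length(genes) == 0) stop("panel file contains no gene symbols: ", path)
  panel_definition(name, genes)
}

#' @rdname read_panel
#' @param genes character vector of gene symbols.
#' @export
panel_definition <- function(name, genes) {
  genes <- unique(toupper(trimws(as.character(genes))))
  genes <- genes[nzchar(genes) & !is.na(genes)]
  if (length(genes) == 0) stop("empty panel definition")
  structure(list(name = name, genes = sort(genes)),
            class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat("Gene panel '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read a pedigree table
#'
#' Tab-delimited table linking each proband to its sequenced relatives.
#'
#' @param path file with columns `case_id`, `proband_sample`,
#'   `mother_sample`, `father_sample` and optional `other_relatives`
#'   (`;`-separated).
#' @return a `data.frame` with one row per case.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("cannot read pedigree file: ", path)
  ped <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  miss <- setdiff(c("case_id", "proband_sample"), names(ped))
  if (length(miss) > 0)
    stop("pedigree lacks mandatory column(s): ", paste(miss, collapse = ", "))
  for (col in c("mother_sample", "father_sample", "other_relatives"))
    if (!col %in% names(ped)) ped[[col]] <- NA_character_
  for (i in seq_len(nrow(ped))) {
    ids <- stats::na.omit(unlist(ped[i, c("proband_sample", "mother_sample",
                                          "father_sample")]))
    if (anyDuplicated(ids))
      stop("pedigree row ", i, ": duplicated sample ids")
  }
  ped
}

#' Path to a packaged fixture
#'
#' @param name fixture name, `"table1_cases"` or `"table3_mtdna"`.
#' @return absolute path to the packaged tab-delimited file.
#' @export
fixture_path <- function(name = c("table1_cases", "table3_mtdna")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "mautopsy")
  if (!nzchar(path)) stop("fixture not found: ", name)
  path
}

#' Load a packaged cohort fixture
#'
#' The package ships two verbatim transcriptions of the published cohort
#' tables: `table1_cases`, the 50-case demographic and autopsy summary,
#' and `table3_mtdna`, the eight cases carrying >= 10 mitochondrial
#' heteroplasmic variants with per-case all/D-loop counts and the counts
#' shared with each sequenced parent.
#'
#' @param name `"table1_cases"` or `"table3_mtdna"`.
#' @return the fixture as a `data.frame`, transcribed verbatim.
#' @export
load_fixture <- function(name = c("table1_cases", "table3_mtdna")) {
  name <- match.arg(name)
  utils::read.delim(fixture_path(name), stringsAsFactors = FALSE,
                    na.strings = "NA", quote = "", fill = TRUE)
}
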