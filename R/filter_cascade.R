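#' Apply the rare-variant filter cascade to one sample
#'
#' The four-stage reduction applied to every sample's raw variant calls:
#' \enumerate{
#'   \item raw calls (`n_raw`);
#'   \item quality control -- keep `qc_pass` (`n_qc`);
#'   \item internal-database frequency -- discard common variants with
#'     internal-cohort MAF `>=` `internal_maf_cut` (`n_internal`);
#'   \item population frequency -- keep only variants with 1000 Genomes
#'     MAF `<` `kg_maf_cut` (`n_final`).
#' }
#' The boundary semantics are deliberately asymmetric (`>=` at stage 3,
#' strict `<` at stage 4), matching the thresholds as published. A missing
#' frequency passes both frequency filters: unobserved variants are by
#' construction rare, and novel variants are the analysis target
#' (`strict_missing = TRUE` flips this to the conservative drop).
#'
#' @param variants variant table for a single sample.
#' @param internal_maf_cut internal-database MAF removal threshold
#'   (default 0.05; a variant at exactly the cut is removed).
#' @param kg_maf_cut 1000 Genomes MAF retention threshold (default 0.01;
#'   a variant at exactly the cut is removed).
#' @param strict_missing drop records with missing frequencies instead of
#'   passing them (default `FALSE`).
#' @return a list with `variants` (the survivors, input order preserved)
#'   and `report`, a one-row `data.frame` of class `cascade_report` with
#'   the per-stage counts and `retained_fraction` (`n_final / n_raw`,
#'   defined as 0 for empty input).
#' @export
apply_cascade <- function(variants, internal_maf_cut = 0.05,
                          kg_maf_cut = 0.01, strict_missing = FALSE) {
  ids <- unique(variants$sample_id)
  if (length(ids) > 1)
    stop("apply_cascade expects variants from a single sample; got ",
         length(ids), " sample ids")
  sample_id <- if (length(ids) == 1) ids else NA_character_

  n_raw <- nrow(variants)
  keep_qc <- variants$qc_pass %in% TRUE
  v_qc <- variants[keep_qc, , drop = FALSE]

  pass_internal <- if (strict_missing)
    !is.na(v_qc$af_internal) & v_qc$af_internal < internal_maf_cut
  else is.na(v_qc$af_internal) | v_qc$af_internal < internal_maf_cut
  v_int <- v_qc[pass_internal, , drop = FALSE]

  pass_kg <- if (strict_missing)
    !is.na(v_int$af_1kg) & v_int$af_1kg < kg_maf_cut
  else is.na(v_int$af_1kg) | v_int$af_1kg < kg_maf_cut
  v_final <- v_int[pass_kg, , drop = FALSE]
  rownames(v_final) <- NULL

  report <- data.frame(
    sample_id = sample_id,
    n_raw = n_raw, n_qc = nrow(v_qc), n_internal = nrow(v_int),
    n_final = nrow(v_final),
    retained_fraction = if (n_raw == 0) 0 else nrow(v_final) / n_raw,
    stringsAsFactors = FALSE
  )
  class(report) <- c("cascade_report", class(report))
  list(variants = v_final, report = report)
}

#' Apply the filter cascade to a whole cohort
#'
#' Splits a cohort variant table by sample, runs [apply_cascade()] on each
#' sample independently, and binds the survivors and per-sample reports.
#'
#' @inheritParams apply_cascade
#' @param variants cohort-wide variant table (any number of samples).
#' @return a list with `variants` (all survivors) and `report` (one row
#'   per sample).
#' @export
cascade_cohort <- function(variants, internal_maf_cut = 0.05,
                           kg_maf_cut = 0.01, strict_missing = FALSE) {
  pieces <- split(variants, variants$sample_id)
  res <- lapply(pieces, apply_cascade, internal_maf_cut = internal_maf_cut,
                kg_maf_cut = kg_maf_cut, strict_missing = strict_missing)
  out_v <- do.call(rbind, lapply(res, `[[`, "variants"))
  rownames(out_v) <- NULL
  report <- do.call(rbind, lapply(res, `[[`, "report"))
  rownames(report) <- NULL
  list(variants = out_v, report = report)
}

#' Default category-assignment rules
#'
#' A simplified, configurable stand-in for an external annotation engine,
#' used only for records that arrive without a pathogenicity category.
#' Categories follow the ordinal convention: 1 = previously reported,
#' recognised cause; 2 = unreported but of a type expected to be causal
#' (protein-truncating); 3 = unreported, may or may not be causal
#' (missense); 4--5 = lower tiers (synonymous / non-coding).
#'
#' @param known_pathogenic `data.frame` with columns `gene`, `ref`, `alt`,
#'   `pos` identifying previously reported causal alleles (category 1).
#' @param effect_defaults named integer vector mapping each effect class
#'   to the category assigned to unreported variants of that class.
#' @param fallback category for unrecognised effect classes.
#' @return a list of class `category_rules`.
#' @export
category_rules <- function(known_pathogenic = NULL,
                           effect_defaults = c(missense = 3L, nonsense = 2L,
                                               frameshift = 2L, splice = 2L,
                                               synonymous = 4L,
                                               noncoding = 5L, other = 5L),
                           fallback = 5L) {
  structure(list(known_pathogenic = known_pathogenic,
                 effect_defaults = effect_defaults,
                 fallback = as.integer(fallback)),
            class = "category_rules")
}

#' Assign pathogenicity categories
#'
#' Fills in the `category` column for records lacking one, using
#' [category_rules()]: known-pathogenic lookup hits become category 1,
#' otherwise the per-effect default applies. Records that already carry a
#' category are never overridden.
#'
#' @param variants variant table.
#' @param rules a [category_rules()] object.
#' @return the variant table with `category` completed.
#' @export
assign_category <- function(variants, rules = category_rules()) {
  need <- is.na(variants$category)
  if (!any(need)) return(variants)
  cat_new <- rules$effect_defaults[variants$effect[need]]
  unknown <- is.na(cat_new)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unrecognised effect class; ",
            "assigned fallback category ", rules$fallback)
    cat_new[unknown] <- rules$fallback
  }
  kp <- rules$known_pathogenic
  if (!is.null(kp) && nrow(kp) > 0) {
    key_v <- paste(toupper(variants$gene[need]), variants$pos[need],
                   variants$ref[need], variants$alt[need])
    key_k <- paste(toupper(kp$gene), kp$pos, kp$ref, kp$alt)
    cat_new[key_v %in% key_k] <- 1L
  }
  variants$category[need] <- as.integer(cat_new)
  variants
}

#' Assign the causal-interpretation tier
#'
#' Maps each categorised variant to one of the three interpretation tiers
#' used to call a molecular-autopsy report:
#' \itemize{
#'   \item `likely` -- category 1 or 2 (reported cause, or unreported but
#'     of an expected-causal type) in a sudden-cardiac-death gene;
#'   \item `plausible` -- category 3 (unknown significance) in an SCD gene;
#'   \item `speculative` -- category 1--3 outside the SCD list but
#'     previously implicated in another disorder;
#'   \item `none` -- everything else.
#' }
#'
#' @param variants categorised variant table.
#' @param scd_genes a [panel_definition()] of sudden-death genes.
#' @param other_disease_genes optional [panel_definition()] of genes
#'   implicated in other disorders (for the speculative tier).
#' @return character vector of tiers, one per record.
#' @export
assign_tier <- function(variants, scd_genes, other_disease_genes = NULL) {
  if (any(is.na(variants$category)))
    stop("assign_tier requires a category on every record; ",
         "run assign_category() first")
  gene <- toupper(ifelse(is.na(variants$gene), "", variants$gene))
  in_scd <- gene %in% scd_genes$genes
  in_other <- if (is.null(other_disease_genes)) rep(FALSE, length(gene))
    else gene %in% other_disease_genes$genes
  tier <- rep("none", nrow(variants))
  tier[variants$category %in% c(1L, 2L, 3L) & !in_scd & in_other] <-
    "speculative"
  tier[variants$category == 3L & in_scd] <- "plausible"
  tier[variants$category %in% c(1L, 2L) & in_scd] <- "likely"
  tier
}

#' Classify a molecular-autopsy report
#'
#' A report is *positive* when at least one of the sample's cascade
#' survivors is tiered `likely` (a likely cause of sudden death),
#' *negative* otherwise.
#'
#' @inheritParams assign_tier
#' @return `"positive"` or `"negative"`.
#' @export
classify_report <- function(variants, scd_genes, other_disease_genes = NULL) {
  if (nrow(variants) == 0) return("negative")
  tiers <- assign_tier(variants, scd_genes, other_disease_genes)
  if (any(tiers == "likely")) "positive" else "negative"
}

#' Five-number summary with interquartile range
#'
#' Median, quartiles and range as used for the per-stage variant counts.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7, the R default); the convention is stated
#' here because published count summaries rarely name one.
#'
#' @param values non-empty numeric vector.
#' @return named list with `median`, `q1`, `q3`, `min`, `max`.
#' @export
summarize_counts <- function(values) {
  if (length(values) == 0) stop("summarize_counts: empty input")
  if (any(is.na(values))) stop("summarize_counts: NA in input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3],
       min = min(values), max = max(values))
}
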