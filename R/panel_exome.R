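#' Restrict variants to a gene panel
#'
#' Keeps exactly the records whose (case-normalised) gene symbol belongs
#' to the panel; order is preserved. Matching is by symbol, mirroring the
#' way panel restriction is applied to exome-derived calls.
#'
#' @param variants variant table.
#' @param panel a [panel_definition()].
#' @return the restricted variant table.
#' @export
restrict_to_panel <- function(variants, panel) {
  keep <- !is.na(variants$gene) & toupper(variants$gene) %in% panel$genes
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

is_likely_pathogenic <- function(variants) variants$category %in% c(1L, 2L)

#' Per-gene variant abundance
#'
#' Pools cascade survivors across the cohort and counts, per gene, the
#' total number of variants and the number that are likely pathogenic
#' (category 1--2), plus their ratio -- the per-gene pathogenic fraction
#' used to gauge mutation tolerance. Records without a gene symbol are
#' excluded from per-gene rows and reported in the `n_unassigned`
#' attribute.
#'
#' @param variants cohort-wide variant table of cascade survivors.
#' @param min_likely keep only genes with at least this many likely
#'   pathogenic variants (0 keeps all genes).
#' @param exclude_regex optional regular expression; genes matching it are
#'   dropped (off by default; useful for recurrently artefactual loci such
#'   as the protocadherin gamma cluster).
#' @return a `data.frame` with columns `gene`, `n_total`, `n_likely`,
#'   `ratio`, sorted by `n_total` descending with alphabetical
#'   tie-breaking; attribute `n_unassigned` counts gene-less records.
#' @export
gene_abundance <- function(variants, min_likely = 0, exclude_regex = NULL) {
  has_gene <- !is.na(variants$gene) & nzchar(variants$gene)
  n_unassigned <- sum(!has_gene)
  v <- variants[has_gene, , drop = FALSE]
  v$gene <- toupper(v$gene)
  if (!is.null(exclude_regex))
    v <- v[!grepl(exclude_regex, v$gene), , drop = FALSE]
  if (nrow(v) == 0) {
    out <- data.frame(gene = character(0), n_total = integer(0),
                      n_likely = integer(0), ratio = numeric(0))
    attr(out, "n_unassigned") <- n_unassigned
    return(out)
  }
  n_total <- table(v$gene)
  n_likely <- table(factor(v$gene[is_likely_pathogenic(v)],
                           levels = names(n_total)))
  out <- data.frame(gene = names(n_total),
                    n_total = as.integer(n_total),
                    n_likely = as.integer(n_likely),
                    stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$n_total > 0, out$n_likely / out$n_total, NA_real_)
  out <- out[out$n_likely >= min_likely, , drop = FALSE]
  out <- out[order(-out$n_total, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Per-sample likely-pathogenic counts
#'
#' Counts, for every sample in the cohort, the number of likely
#' pathogenic variants (category 1--2) at exome scope or restricted to a
#' panel. Samples with zero such variants are retained in the result --
#' the zero bin is the panel's diagnostic ceiling.
#'
#' @param variants cohort-wide variant table of cascade survivors.
#' @param scope `"exome"` (no restriction) or `"panel"`.
#' @param panel a [panel_definition()]; required when `scope = "panel"`.
#' @param samples optional character vector fixing the sample universe
#'   (defaults to the samples present in `variants`).
#' @return named integer vector, one count per sample.
#' @export
per_sample_likely_counts <- function(variants,
                                     scope = c("exome", "panel"),
                                     panel = NULL, samples = NULL) {
  scope <- match.arg(scope)
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  v <- variants
  if (scope == "panel") {
    if (is.null(panel)) stop("panel scope requires a panel definition")
    v <- restrict_to_panel(v, panel)
  }
  v <- v[is_likely_pathogenic(v), , drop = FALSE]
  counts <- table(factor(v$sample_id, levels = samples))
  out <- as.integer(counts)
  names(out) <- samples
  out
}

#' Tally effect classes among likely pathogenic variants
#'
#' @param variants cohort-wide variant table.
#' @param likely_only restrict the tally to category 1--2 records
#'   (default `TRUE`, the published convention).
#' @return named integer vector over all of [EFFECT_CLASSES] (zero
#'   classes included).
#' @export
effect_class_tally <- function(variants, likely_only = TRUE) {
  v <- if (likely_only)
    variants[is_likely_pathogenic(variants), , drop = FALSE] else variants
  counts <- table(factor(v$effect, levels = EFFECT_CLASSES))
  out <- as.integer(counts)
  names(out) <- EFFECT_CLASSES
  out
}
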