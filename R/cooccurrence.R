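#' Build per-sample gene-sharing profiles
#'
#' For every sample, collects the set of genes carrying at least one
#' likely pathogenic (category 1--2) variant, then computes `max_shared`:
#' the largest number of those genes also present in some *single* other
#' sample's set. This is the cross-sample co-occurrence profile.
#'
#' @param variants cohort-wide variant table (>= 2 samples).
#' @param samples optional sample universe (samples with no likely
#'   pathogenic variants get empty sets).
#' @return a `data.frame` with columns `sample_id`, `n_genes_likely`,
#'   `max_shared`; the gene sets themselves are in the `gene_sets`
#'   attribute (a named list).
#' @export
build_sharing_profiles <- function(variants, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  if (length(samples) < 2)
    stop("sharing profiles require at least 2 samples")
  v <- variants[is_likely_pathogenic(variants) & !is.na(variants$gene), ,
                drop = FALSE]
  sets <- lapply(samples, function(s)
    sort(unique(toupper(v$gene[v$sample_id == s]))))
  names(sets) <- samples
  n <- length(samples)
  max_shared <- integer(n)
  for (i in seq_len(n)) {
    best <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      best <- max(best, length(intersect(sets[[i]], sets[[j]])))
    }
    max_shared[i] <- best
  }
  out <- data.frame(sample_id = samples,
                    n_genes_likely = lengths(sets),
                    max_shared = max_shared,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "gene_sets") <- sets
  out
}

#' Gene-sharing histogram
#'
#' Percentage of samples whose `max_shared` reaches each sharing level
#' `k = 1..k_max`. The default mode is cumulative (`>= k`, "shared up to
#' k genes with at least another sample"); `mode = "exact"` reports the
#' exact-`k` distribution instead.
#'
#' @param profiles output of [build_sharing_profiles()].
#' @param k_max largest sharing level reported (default 3).
#' @param mode `"cumulative"` (default) or `"exact"`.
#' @return named numeric vector of percentages, names `"1".."k_max"`.
#' @export
sharing_histogram <- function(profiles, k_max = 3,
                              mode = c("cumulative", "exact")) {
  mode <- match.arg(mode)
  if (nrow(profiles) == 0) stop("empty profiles")
  n <- nrow(profiles)
  ks <- seq_len(k_max)
  pct <- vapply(ks, function(k) {
    hit <- if (mode == "cumulative") profiles$max_shared >= k
           else profiles$max_shared == k
    100 * sum(hit) / n
  }, numeric(1))
  names(pct) <- as.character(ks)
  pct
}

#' Per-gene distinct-sample sharing counts
#'
#' For each gene, the number of distinct samples carrying at least one
#' likely pathogenic variant in it (a sample with two such variants in
#' one gene counts once). Genes with no likely pathogenic variants are
#' absent from the result.
#'
#' @param variants cohort-wide variant table.
#' @return named integer vector, sorted by count descending then gene.
#' @export
gene_sharing_counts <- function(variants) {
  v <- variants[is_likely_pathogenic(variants) & !is.na(variants$gene), ,
                drop = FALSE]
  if (nrow(v) == 0) return(stats::setNames(integer(0), character(0)))
  pairs <- unique(data.frame(gene = toupper(v$gene),
                             sample_id = v$sample_id,
                             stringsAsFactors = FALSE))
  counts <- table(pairs$gene)
  counts <- counts[order(-as.integer(counts), names(counts))]
  stats::setNames(as.integer(counts), names(counts))
}
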