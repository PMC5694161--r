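#' Collapse variants to per-sample gene sets
#'
#' The genetic fingerprint of a sample is the set of distinct genes
#' carrying at least one variant in the selected pathogenicity categories
#' (default 1--3: reported causes, expected-causal types, and unknown
#' significance -- the band wide enough to make pairwise overlaps
#' informative).
#'
#' @param variants cohort-wide variant table with categories assigned.
#' @param categories integer categories collapsed per gene (default `1:3`).
#' @param samples optional sample universe; samples with no qualifying
#'   variant keep an empty set.
#' @return named list mapping sample id to a sorted character vector of
#'   gene symbols.
#' @export
collapse_gene_sets <- function(variants, categories = 1:3, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  v <- variants[variants$category %in% categories & !is.na(variants$gene), ,
                drop = FALSE]
  sets <- lapply(samples, function(s)
    sort(unique(toupper(v$gene[v$sample_id == s]))))
  names(sets) <- samples
  sets
}

jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)  # two empty sets: similarity 0 by convention
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard similarity matrix
#'
#' Intersection-over-union similarity between every pair of per-sample
#' gene sets. The diagonal is 1 for non-empty sets and 0 for an empty set
#' (the empty/empty union is empty; 0 by the documented convention).
#'
#' @param gene_sets named list of gene sets, as from
#'   [collapse_gene_sets()] (>= 2 samples).
#' @return symmetric numeric matrix in `[0, 1]` with sample ids as
#'   dimnames.
#' @export
jaccard_matrix <- function(gene_sets) {
  n <- length(gene_sets)
  if (n < 2) stop("jaccard_matrix requires at least 2 samples")
  ids <- names(gene_sets)
  J <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      J[i, j] <- J[j, i] <- jaccard_index(gene_sets[[i]], gene_sets[[j]])
    }
  }
  J
}

#' Z-score standardisation of a similarity matrix
#'
#' Standardises the pairwise similarities against the distribution of
#' *all* distinct unordered pairs (the diagonal is excluded): each
#' off-diagonal entry becomes `(J_ij - mean) / sd`. A single global pair
#' population is used because the analysis reports one scalar Z per pair
#' and counts pairs above a global threshold. The diagonal of the result
#' is `NA` (undefined).
#'
#' @param jaccard symmetric similarity matrix.
#' @param sd_convention `"sample"` (divisor `n_pairs - 1`, default) or
#'   `"population"` (divisor `n_pairs`).
#' @return symmetric matrix of Z-scores with `NA` diagonal.
#' @export
standardize_zscores <- function(jaccard,
                                sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  n <- nrow(jaccard)
  if (n < 3) stop("Z-score standardisation requires >= 3 samples")
  vals <- jaccard[upper.tri(jaccard)]
  mu <- mean(vals)
  sdev <- if (sd_convention == "sample") stats::sd(vals)
          else sqrt(mean((vals - mu)^2))
  if (!is.finite(sdev) || sdev == 0)
    stop("degenerate similarity matrix: all pairwise values identical, ",
         "standard deviation is zero")
  Z <- (jaccard - mu) / sdev
  diag(Z) <- NA_real_
  Z
}

#' Rank high-similarity sample pairs
#'
#' Lists pairs whose Z-score exceeds a report threshold, sorted by Z
#' descending (ties broken by sample-id order), with the intersection and
#' union gene lists that produced each similarity.
#'
#' @param zscores matrix from [standardize_zscores()].
#' @param gene_sets the gene sets the similarity was computed from.
#' @param z_threshold report pairs with `Z > z_threshold` (default 3).
#' @return a `data.frame` with columns `sample_a`, `sample_b`, `zscore`,
#'   `n_intersection`, `n_union`, `intersection_genes` (`;`-separated,
#'   alphabetical).
#' @export
rank_pairs <- function(zscores, gene_sets, z_threshold = 3.0) {
  ids <- rownames(zscores)
  idx <- which(upper.tri(zscores) & zscores > z_threshold, arr.ind = TRUE)
  out <- data.frame(sample_a = character(0), sample_b = character(0),
                    zscore = numeric(0), n_intersection = integer(0),
                    n_union = integer(0),
                    intersection_genes = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(idx) > 0) {
    rows <- lapply(seq_len(nrow(idx)), function(k) {
      i <- idx[k, 1]; j <- idx[k, 2]
      inter <- sort(intersect(gene_sets[[ids[i]]], gene_sets[[ids[j]]]))
      uni <- union(gene_sets[[ids[i]]], gene_sets[[ids[j]]])
      data.frame(sample_a = ids[i], sample_b = ids[j],
                 zscore = zscores[i, j],
                 n_intersection = length(inter), n_union = length(uni),
                 intersection_genes = paste(inter, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$zscore, out$sample_a, out$sample_b), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Hierarchically cluster samples by similarity profile
#'
#' Agglomerative clustering of the (symmetric) similarity matrix, as
#' applied to a standardised heatmap: by default, complete linkage on
#' Euclidean distances between matrix rows -- the default behaviour of a
#' standard R heatmap. Alternatively `distance = "one_minus_jaccard"`
#' treats the input as a Jaccard matrix and clusters on `1 - J` directly.
#' An `NA` diagonal (masked self-similarity) is replaced by 0 before row
#' distances are taken; any other non-finite entry is an error.
#'
#' @param mat symmetric similarity matrix (Z-scores or Jaccard).
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#' @param distance `"euclidean_rows"` (default) or `"one_minus_jaccard"`.
#' @return an object of class `hclust` (`n - 1` merges).
#' @export
cluster_samples <- function(mat,
                            linkage = c("complete", "average", "single"),
                            distance = c("euclidean_rows",
                                         "one_minus_jaccard")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  m <- as.matrix(mat)
  diag(m)[is.na(diag(m))] <- 0
  if (any(!is.finite(m)))
    stop("cluster_samples: non-finite entries in similarity matrix")
  d <- if (distance == "euclidean_rows") stats::dist(m)
       else stats::as.dist(1 - m)
  stats::hclust(d, method = linkage)
}

#' Run the full genetic-fingerprint analysis
#'
#' Convenience wrapper chaining [collapse_gene_sets()],
#' [jaccard_matrix()], [standardize_zscores()], [rank_pairs()] and
#' [cluster_samples()].
#'
#' @inheritParams collapse_gene_sets
#' @inheritParams rank_pairs
#' @inheritParams cluster_samples
#' @param sd_convention passed to [standardize_zscores()].
#' @return a list of class `fingerprint_result` with elements
#'   `sample_ids`, `gene_sets`, `jaccard`, `zscores`, `tree`, `top_pairs`.
#' @export
fingerprint <- function(variants, categories = 1:3, z_threshold = 3.0,
                        linkage = "complete", distance = "euclidean_rows",
                        sd_convention = "sample", samples = NULL) {
  sets <- collapse_gene_sets(variants, categories, samples)
  J <- jaccard_matrix(sets)
  Z <- standardize_zscores(J, sd_convention)
  structure(list(sample_ids = names(sets), gene_sets = sets,
                 jaccard = J, zscores = Z,
                 tree = cluster_samples(Z, linkage, distance),
                 top_pairs = rank_pairs(Z, sets, z_threshold)),
            class = "fingerprint_result")
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat("Genetic fingerprint:", length(x$sample_ids), "samples;",
      nrow(x$top_pairs), "pair(s) above the Z threshold\n")
  invisible(x)
}
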