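#' Default mitochondrial locus map
#'
#' Minimal locus map on the revised Cambridge Reference Sequence (rCRS,
#' 16,569 bp): the displacement-loop control region (MT-DLOOP) spans two
#' intervals, 16024--16569 and 1--576 (1-based inclusive); every other
#' position maps to `"MT-OTHER"`. A custom map may add named loci.
#'
#' @param extra optional `data.frame` with columns `locus`, `start`,
#'   `end` appended to the default map.
#' @return a `data.frame` of class `mt_locus_map`.
#' @export
mt_locus_map <- function(extra = NULL) {
  map <- data.frame(locus = c("MT-DLOOP", "MT-DLOOP"),
                    start = c(16024L, 1L), end = c(16569L, 576L),
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) map <- rbind(map, extra[, c("locus", "start", "end")])
  if (any(map$start < 1L | map$end > 16569L | map$start > map$end))
    stop("locus intervals must lie within [1, 16569]")
  class(map) <- c("mt_locus_map", class(map))
  map
}

#' Assign mitochondrial loci by position
#'
#' @param pos integer positions on the mitochondrial reference.
#' @param map a [mt_locus_map()].
#' @return character vector of locus names (`"MT-OTHER"` outside the map).
#' @export
mt_locus_of <- function(pos, map = mt_locus_map()) {
  out <- rep("MT-OTHER", length(pos))
  for (i in seq_len(nrow(map))) {
    hit <- pos >= map$start[i] & pos <= map$end[i]
    out[hit] <- map$locus[i]
  }
  out
}

#' Heteroplasmic fraction from allelic depths
#'
#' The alternate-allele share of reads at a mitochondrial site:
#' `depth_alt / (depth_ref + depth_alt)`.
#'
#' @param depth_ref,depth_alt non-negative read depths; total must be > 0.
#' @return fraction in `[0, 1]`.
#' @export
heteroplasmic_fraction <- function(depth_ref, depth_alt) {
  total <- depth_ref + depth_alt
  if (any(is.na(total)) || any(total <= 0))
    stop("heteroplasmic_fraction: zero or missing total depth")
  if (any(depth_ref < 0) || any(depth_alt < 0))
    stop("heteroplasmic_fraction: negative depth")
  depth_alt / total
}

#' Filter mitochondrial variants to the heteroplasmic band
#'
#' Computes the heteroplasmic fraction (HF) from allelic depths and keeps
#' variants with `hf_low < HF < hf_high` and population MAF
#' `< maf_cut` (missing MAF passes, as for the nuclear cascade). The
#' strict lower bound reproduces the published `HF > 0.2` rule; the upper
#' bound separates heteroplasmy from effective homoplasmy and is
#' configurable because only the lower bound is published. The result
#' carries per-sample burden (`n_total`), D-loop burden (`n_dloop`), and
#' the high-burden flag (`n_total >= 10`).
#'
#' @param variants variant table, all records on the mitochondrial contig
#'   with depths present.
#' @param hf_low,hf_high open HF band (defaults 0.2 and 0.95).
#' @param maf_cut population-MAF threshold (default 0.05, strict `<`).
#' @param locus_map a [mt_locus_map()].
#' @param high_burden_min burden defining the high-burden flag
#'   (default 10).
#' @return an object of class `heteroplasmy_profile`: list with
#'   `sample_id`, `variants` (pos/ref/alt/hf/locus), `n_total`,
#'   `n_dloop`, `high_burden`, `shared_with_mother`, `shared_with_father`
#'   (the latter two `NA` until [maternal_sharing()] is run).
#' @export
filter_heteroplasmic <- function(variants, hf_low = 0.2, hf_high = 0.95,
                                 maf_cut = 0.05, locus_map = mt_locus_map(),
                                 high_burden_min = 10L) {
  if (nrow(variants) > 0 && !all(is_mt_contig(variants$chrom)))
    stop("filter_heteroplasmic: non-mitochondrial records present")
  ids <- unique(variants$sample_id)
  if (length(ids) > 1)
    stop("filter_heteroplasmic expects a single sample")
  sample_id <- if (length(ids) == 1) ids else NA_character_
  if (nrow(variants) > 0) {
    if (any(is.na(variants$depth_ref) | is.na(variants$depth_alt)))
      stop("filter_heteroplasmic: allelic depths required on all records")
    hf <- heteroplasmic_fraction(variants$depth_ref, variants$depth_alt)
    keep <- hf > hf_low & hf < hf_high &
      (is.na(variants$af_1kg) | variants$af_1kg < maf_cut)
    v <- variants[keep, , drop = FALSE]
    hf <- hf[keep]
  } else {
    v <- variants
    hf <- numeric(0)
  }
  vt <- data.frame(pos = v$pos, ref = v$ref, alt = v$alt, hf = hf,
                   locus = mt_locus_of(v$pos, locus_map),
                   stringsAsFactors = FALSE)
  vt <- vt[order(vt$pos, vt$alt), , drop = FALSE]
  rownames(vt) <- NULL
  structure(list(sample_id = sample_id, variants = vt,
                 n_total = nrow(vt),
                 n_dloop = sum(vt$locus == "MT-DLOOP"),
                 high_burden = nrow(vt) >= high_burden_min,
                 shared_with_mother = NA_integer_,
                 shared_with_father = NA_integer_),
            class = "heteroplasmy_profile")
}

#' @export
print.heteroplasmy_profile <- function(x, ...) {
  cat("mtDNA heteroplasmy profile for", x$sample_id, "--", x$n_total,
      "variant(s),", x$n_dloop, "in MT-DLOOP",
      if (x$high_burden) "[high burden]" else "", "\n")
  invisible(x)
}

variant_keys <- function(profile) {
  with(profile$variants, paste(pos, ref, alt))
}

#' Parental sharing of heteroplasmic variants
#'
#' Counts how many of the proband's heteroplasmic variants (exact
#' position/ref/alt identity) are also present in each sequenced parent's
#' profile, recording mother and father independently. Maternal sharing
#' of the full burden is the signature of transmitted (non-de-novo)
#' heteroplasmy.
#'
#' @param proband,mother,father [filter_heteroplasmic()] profiles from
#'   one pedigree; `mother`/`father` may be `NULL` if unsequenced.
#' @return the proband profile with `shared_with_mother` /
#'   `shared_with_father` filled in (`NA` for an unsequenced parent).
#' @export
maternal_sharing <- function(proband, mother = NULL, father = NULL) {
  keys <- variant_keys(proband)
  if (!is.null(mother))
    proband$shared_with_mother <-
      as.integer(sum(keys %in% variant_keys(mother)))
  if (!is.null(father))
    proband$shared_with_father <-
      as.integer(sum(keys %in% variant_keys(father)))
  proband
}

profiles_to_df <- function(profiles) {
  if (is.data.frame(profiles)) return(profiles)
  do.call(rbind, lapply(profiles, function(p)
    data.frame(sample_id = p$sample_id, n_total = p$n_total,
               n_dloop = p$n_dloop, high_burden = p$high_burden,
               shared_with_mother = p$shared_with_mother,
               shared_with_father = p$shared_with_father,
               stringsAsFactors = FALSE)))
}

#' Heteroplasmy burden versus age
#'
#' Joins per-sample heteroplasmy burdens to case metadata, yielding the
#' age-versus-burden table and the count of infants (under 12 months)
#' among high-burden samples -- the signal that flagged half of the
#' infant group.
#'
#' @param profiles list of `heteroplasmy_profile` objects, or a
#'   `data.frame` with columns `sample_id`, `n_total`, `n_dloop`,
#'   `high_burden`.
#' @param cases case table from [read_case_table()].
#' @param high_burden_min burden defining high burden when `profiles`
#'   lacks the flag (default 10).
#' @return a list with `table` (`sample_id`, `age_months`, `n_total`,
#'   `n_dloop`, `fa_status`, `high_burden`, `infant`),
#'   `n_high_burden` and `n_infant_high_burden`; unjoinable samples are
#'   dropped with a warning.
#' @export
burden_vs_age <- function(profiles, cases, high_burden_min = 10L) {
  pdf <- profiles_to_df(profiles)
  if (!"high_burden" %in% names(pdf))
    pdf$high_burden <- pdf$n_total >= high_burden_min
  key <- match(pdf$sample_id, cases$case_id)
  alt <- match(pdf$sample_id, cases$proband_id)
  key[is.na(key)] <- alt[is.na(key)]
  if (any(is.na(key))) {
    warning("unjoinable sample(s) excluded: ",
            paste(pdf$sample_id[is.na(key)], collapse = ", "))
    pdf <- pdf[!is.na(key), , drop = FALSE]
    key <- key[!is.na(key)]
  }
  tab <- data.frame(sample_id = pdf$sample_id,
                    age_months = cases$age_months[key],
                    n_total = pdf$n_total, n_dloop = pdf$n_dloop,
                    fa_status = cases$fa_status[key],
                    high_burden = pdf$high_burden,
                    stringsAsFactors = FALSE)
  tab$infant <- tab$age_months < 12
  rownames(tab) <- NULL
  list(table = tab,
       n_high_burden = sum(tab$high_burden),
       n_infant_high_burden = sum(tab$high_burden & tab$infant))
}
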