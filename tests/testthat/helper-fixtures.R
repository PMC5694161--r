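# Small in-code builders shared across the test files.

# A hand-traceable six-variant sample: one QC failure, one internally
# common variant (af_internal = 0.07), one population-common variant
# (af_1kg = 0.02) and three rare survivors.
toy_cascade_sample <- function(sample_id = "S1") {
  variant_table(
    sample_id = sample_id, chrom = "chr1", pos = 1:6,
    ref = "A", alt = "G",
    gene = c("TTN", "RYR2", "MYH7", "PKP2", "SCN5A", "KCNQ1"),
    effect = "missense",
    qc_pass = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    af_internal = c(NA, 0.07, 0.001, NA, 0.002, 0.003),
    af_1kg = c(NA, NA, 0.02, NA, 0.001, 0.0005),
    category = 3L)
}

# Cohort with known likely-pathogenic gene sets per sample.
toy_cohort_variants <- function(sets, category = 1L) {
  rows <- lapply(names(sets), function(s) {
    genes <- sets[[s]]
    if (length(genes) == 0)
      return(variant_table(character(0), character(0), integer(0),
                           character(0), character(0)))
    variant_table(sample_id = s, chrom = "chr1",
                  pos = seq_along(genes), ref = "A", alt = "G",
                  gene = genes, effect = "missense", category = category)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Mitochondrial variant rows with depths encoding the given HFs.
toy_mt_variants <- function(sample_id, pos, hf, total = 100L,
                            ref = "A", alt = "G", af_1kg = NA_real_) {
  depth_alt <- as.integer(round(hf * total))
  variant_table(sample_id = sample_id, chrom = "MT", pos = pos,
                ref = ref, alt = alt, qc_pass = TRUE, af_1kg = af_1kg,
                depth_ref = total - depth_alt, depth_alt = depth_alt)
}

# Random variant table for property-style checks.
random_variant_table <- function(n, sample_id = "R1") {
  variant_table(
    sample_id = sample_id, chrom = "chr1",
    pos = sample.int(1e6, n, replace = TRUE), ref = "A", alt = "G",
    gene = sample(sprintf("G%02d", 1:20), n, replace = TRUE),
    effect = sample(EFFECT_CLASSES, n, replace = TRUE),
    qc_pass = runif(n) < 0.9,
    af_internal = ifelse(runif(n) < 0.2, NA, runif(n, 0, 0.2)),
    af_1kg = ifelse(runif(n) < 0.2, NA, runif(n, 0, 0.05)),
    category = sample(1:5, n, replace = TRUE))
}
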