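test_that("the four-stage cascade reproduces a hand-traced reduction", {
  v <- toy_cascade_sample()
  res <- apply_cascade(v)
  expect_equal(res$report$n_raw, 6)
  expect_equal(res$report$n_qc, 5)        # one QC failure out
  expect_equal(res$report$n_internal, 4)  # af_internal 0.07 out
  expect_equal(res$report$n_final, 3)     # af_1kg 0.02 out
  expect_equal(res$report$retained_fraction, 0.5)
  expect_equal(res$variants$pos, c(4L, 5L, 6L))  # order preserved
})

test_that("frequency boundaries are asymmetric as published", {
  at_cut <- variant_table("S1", "chr1", 1:2, "A", "G",
                          af_internal = c(0.05, 0.01),
                          af_1kg = c(0.001, 0.01))
  res <- apply_cascade(at_cut)
  # internal MAF exactly at the cut is removed (>= 5%)
  expect_equal(res$report$n_internal, 1)
  # 1000G MAF exactly at the cut is removed (keep < 1%)
  expect_equal(res$report$n_final, 0)
})

test_that("empty input and missing frequencies follow the documented rules", {
  empty <- toy_cascade_sample()[0, ]
  res <- apply_cascade(empty)
  expect_equal(res$report$n_raw, 0)
  expect_equal(res$report$retained_fraction, 0)

  novel <- variant_table("S1", "chr1", 1, "A", "G",
                         af_internal = NA_real_, af_1kg = NA_real_)
  expect_equal(apply_cascade(novel)$report$n_final, 1)
  expect_equal(apply_cascade(novel, strict_missing = TRUE)$report$n_final, 0)
})

test_that("cascade refuses mixed samples and is idempotent/monotone", {
  mixed <- rbind(toy_cascade_sample("A"), toy_cascade_sample("B"))
  expect_error(apply_cascade(mixed), "single sample")

  set.seed(42)
  for (i in 1:20) {
    v <- random_variant_table(50)
    res <- apply_cascade(v)
    r <- res$report
    # stage counts monotone non-increasing
    expect_true(r$n_raw >= r$n_qc && r$n_qc >= r$n_internal &&
                  r$n_internal >= r$n_final)
    # idempotence: the survivors survive unchanged
    again <- apply_cascade(res$variants)
    expect_equal(again$variants, res$variants, ignore_attr = TRUE)
    expect_equal(again$report$n_raw, again$report$n_final)
    # removing the internal-MAF stage can never reduce the final yield
    no_int <- apply_cascade(v, internal_maf_cut = 1.1)
    expect_gte(no_int$report$n_final, r$n_final)
  }
})

test_that("category assignment follows the rule set and never overrides", {
  lookup <- data.frame(gene = "PKP2", pos = 1132L, ref = "C", alt = "T")
  rules <- category_rules(known_pathogenic = lookup)
  v <- variant_table("S1", "chr1", c(1132L, 5L, 9L, 7L), ref = "C",
                     alt = "T",
                     gene = c("PKP2", "NEW1", "NEW2", "NEW3"),
                     effect = c("missense", "nonsense", "missense",
                                "synonymous"),
                     category = NA_integer_)
  out <- assign_category(v, rules)
  expect_equal(out$category, c(1L, 2L, 3L, 4L))

  v$category <- c(5L, NA, NA, NA)
  out2 <- assign_category(v, rules)
  expect_equal(out2$category[1], 5L)  # pre-annotated category kept
})

test_that("tier assignment and report classification follow the tier rules", {
  scd <- panel_definition("scd", c("RYR2", "PKP2"))
  other <- panel_definition("other", "TTR")
  v <- variant_table("S1", "chr1", 1:4, "A", "G",
                     gene = c("RYR2", "PKP2", "TTR", "ZZZ9"),
                     category = c(1L, 3L, 1L, 2L))
  tiers <- assign_tier(v, scd, other)
  expect_equal(tiers, c("likely", "plausible", "speculative", "none"))
  expect_equal(classify_report(v, scd, other), "positive")

  v_no <- v[v$category != 1L | !(v$gene %in% scd$genes), ]
  expect_equal(classify_report(v_no, scd, other), "negative")

  # monotone: adding a likely variant never flips positive -> negative
  added <- rbind(v_no, v[1, ])
  expect_equal(classify_report(added, scd, other), "positive")

  v$category <- NA_integer_
  expect_error(assign_tier(v, scd), "category")
})

test_that("count summaries use the documented quartile convention", {
  s <- summarize_counts(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)
  expect_equal(summarize_counts(c(2, 4))$median, 3)
  expect_error(summarize_counts(numeric(0)), "empty")

  # brute-force sort-and-interpolate oracle (h = (n - 1) p + 1)
  oracle_q <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  set.seed(7)
  for (i in 1:10) {
    x <- sample.int(1000, sample(4:30, 1))
    s <- summarize_counts(x)
    expect_equal(s$q1, oracle_q(x, 0.25))
    expect_equal(s$median, oracle_q(x, 0.5))
    expect_equal(s$q3, oracle_q(x, 0.75))
  }
})
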