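test_that("TSV variant tables parse and round-trip exactly", {
  v <- toy_cascade_sample()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, path)
  back <- read_variant_table(path, dialect = "tsv")
  expect_equal(nrow(back), 6)
  expect_equal(back, v, ignore_attr = TRUE)

  # writing the re-read table reproduces it field by field
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(back, path2)
  expect_equal(read_variant_table(path2), back, ignore_attr = TRUE)
})

test_that("rows violating record invariants are warned about and excluded", {
  v <- toy_cascade_sample()
  v$af_1kg[2] <- 1.3
  expect_warning(kept <- validate_variant_table(v), "excluded")
  expect_equal(nrow(kept), 5)
  expect_false(2 %in% which(kept$pos == 2))
})

test_that("missing mandatory TSV columns are fatal and name the column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tchrom\tpos\tref", path)
  expect_error(read_variant_table(path), "alt")
})

test_that("VCF parsing splits multi-allelic rows and maps AD per allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene">',
    '##INFO=<ID=EFFECT,Number=1,Type=String,Description="Effect">',
    '##INFO=<ID=AF_INT,Number=A,Type=Float,Description="Internal AF">',
    '##INFO=<ID=AF_1KG,Number=A,Type=Float,Description="1KG AF">',
    '##INFO=<ID=CAT,Number=1,Type=Integer,Description="Category">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    paste("chr7", "150", ".", "A", "G,T", ".", "PASS",
          "GENE=KCNH2;EFFECT=missense;AF_INT=0.001,0.002;AF_1KG=0.003,0.004;CAT=3",
          "GT:AD", "1/2:10,5,3", sep = "\t"),
    paste("MT", "310", ".", "T", "C", ".", "PASS",
          "GENE=.;EFFECT=noncoding;AF_INT=.;AF_1KG=0.01;CAT=5",
          "GT:AD", "0/1:80,20", sep = "\t")),
    path)
  v <- read_variant_table(path, dialect = "vcf")
  expect_equal(nrow(v), 3)
  two <- v[v$pos == 150, ]
  expect_equal(two$ref, c("A", "A"))
  expect_equal(two$alt, c("G", "T"))
  expect_equal(two$af_internal, c(0.001, 0.002))
  expect_equal(two$depth_ref, c(10L, 10L))
  expect_equal(two$depth_alt, c(5L, 3L))
  mt <- v[v$pos == 310, ]
  expect_equal(mt$depth_alt, 20L)
  expect_equal(mt$af_1kg, 0.01)
})

test_that("panel reading deduplicates, case-folds and rejects empty lists", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# cardiac panel", "TTN", "ttn", "RYR2", ""), path)
  p <- read_panel(path)
  expect_s3_class(p, "panel_definition")
  expect_setequal(p$genes, c("TTN", "RYR2"))

  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# only", "# comments"), empty)
  expect_error(read_panel(empty), "no gene symbols")
})

test_that("ages normalise to months consistently", {
  expect_equal(age_in_months(2, "months"), 2)
  expect_equal(age_in_months(44, "years"), 528)
  expect_error(age_in_months(-1, "years"), "negative")
  # unit consistency: x years is 12x the months of x
  for (x in c(0.5, 1, 17, 44))
    expect_equal(age_in_months(x, "years"), 12 * age_in_months(x, "months"))
})

test_that("the packaged case table parses to the 50-case cohort", {
  cases <- read_case_table(fixture_path("table1_cases"))
  expect_equal(nrow(cases), 50)
  expect_equal(sum(cases$ma_status == "positive"), 14)
  expect_equal(sum(cases$fa_status == "positive"), 26)
  # mixed age dialect
  expect_equal(cases$age_months[cases$case_id == "MA00072"], 2)
  expect_equal(cases$age_months[cases$case_id == "MA00001"], 528)
})

test_that("the sibling-pair row collapses to one analysis proband", {
  cases <- read_case_table(fixture_path("table1_cases"))
  sib <- cases[cases$case_id == "MA00024", ]
  expect_equal(nrow(sib), 1)
  expect_equal(sib$n_probands, 2L)
  # the autopsy-negative sibling is the analysis proband
  expect_equal(sib$fa_status, "negative")
  expect_equal(sib$ma_status, "negative")
  # analysis age is the younger proband's; both ages retained
  expect_equal(sib$age_months, 17 * 12)
  expect_equal(sib$ages_months_all, "204;288")
})

test_that("duplicate case ids and unparseable ages are fatal", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tage\tsex\tfa_status\tma_status",
               "C1\t3 months\tMale\tNegative\tNegative",
               "C1\t4\tMale\tNegative\tNegative"), path)
  expect_error(read_case_table(path), "duplicate")
  writeLines(c("case_id\tage\tsex\tfa_status\tma_status",
               "C1\telderly\tMale\tNegative\tNegative"), path)
  expect_error(read_case_table(path), "age")
})

test_that("packaged mtDNA high-burden fixture matches the printed rows", {
  t3 <- load_fixture("table3_mtdna")
  expect_equal(nrow(t3), 8)
  expect_equal(t3$all[t3$case_id == "MA02010"], 17)
  expect_equal(t3$dloop[t3$case_id == "MA02010"], 5)
  m56 <- t3[t3$case_id == "MA00056", ]
  expect_equal(m56$mother_all, 15)
  expect_equal(m56$mother_shared, 15)
  expect_equal(m56$father_all, 6)
  expect_true(all(t3$dloop <= t3$all))
})
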