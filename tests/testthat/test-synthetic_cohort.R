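test_that("the generator is deterministic under a fixed seed", {
  cfg <- generator_config(n_cases = 40, seed = 7, raw_mean = 200)
  c1 <- generate_cases(cfg); c2 <- generate_cases(cfg)
  expect_identical(c1, c2)
  v1 <- generate_variants(c1, cfg); v2 <- generate_variants(c2, cfg)
  expect_identical(v1, v2)
  ped <- generate_pedigree(c1)
  m1 <- generate_mtdna(c1, ped, cfg); m2 <- generate_mtdna(c1, ped, cfg)
  expect_identical(m1, m2)
  # a different seed changes the draw
  expect_false(identical(generate_cases(generator_config(n_cases = 40,
                                                         seed = 8)), c1))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(generator_config(sex_male_prob = 1.4), "probabilities")
  expect_error(generator_config(weekday_weights = rep(0, 7)),
               "weekday_weights")
  expect_error(generator_config(hour_profile = c(-1, rep(1, 23))),
               "hour_profile")
  bad_genes <- gene_catalog(n_background = 5)
  bad_genes$length[1] <- 0
  expect_error(generator_config(genes = bad_genes), "length")
  expect_error(generator_config(ma_likely_rate = 0.8,
                                panel_likely_probs = c(0.5, 0.3, 0.15,
                                                       0.05)),
               "ma_likely_rate")
})

test_that("case-level parameters are recovered at moderate cohort size", {
  cfg <- generator_config(n_cases = 5000, seed = 11)
  cases <- generate_cases(cfg)
  # sex ratio within 3 binomial SEs of 0.62
  se_sex <- sqrt(0.62 * 0.38 / 5000)
  expect_lt(abs(mean(cases$sex == "male") - 0.62), 3 * se_sex)
  # infant fraction within 3 binomial SEs of 0.16
  se_inf <- sqrt(0.16 * 0.84 / 5000)
  expect_lt(abs(mean(cases$age_months < 12) - 0.16), 3 * se_inf)
  # ages lie in the supported range
  expect_true(all(cases$age_months >= 1 & cases$age_months <= 528))
  # forensic positivity increases with age (logistic model)
  expect_gt(mean(cases$fa_status[cases$age_months > 240] == "positive"),
            mean(cases$fa_status[cases$age_months < 12] == "positive"))
})

test_that("weekday weights drive the death-day distribution", {
  cfg <- generator_config(n_cases = 400, seed = 3,
                          weekday_weights = c(0, 0, 1, 1, 0, 0, 0))
  cases <- generate_cases(cfg)
  th <- temporal_histograms(cases)
  expect_equal(sum(th$by_weekday[c("Wed", "Thu")]), 400)
})

test_that("per-gene variant counts scale with locus footprint", {
  genes <- data.frame(gene = c("BIGGY", "SMALLY"),
                      length = c(10000, 1000),
                      in_panel = FALSE, causal = FALSE)
  cfg <- generator_config(n_cases = 30, seed = 5, raw_mean = 2000,
                          exome_likely_mean = 0,
                          panel_likely_probs = c(1, 0, 0, 0),
                          ma_likely_rate = 0, genes = genes)
  v <- generate_variants(generate_cases(cfg), cfg)
  counts <- table(v$gene)
  ratio <- counts[["BIGGY"]] / counts[["SMALLY"]]
  # 10x the footprint gives ~10x the variants
  expect_lt(abs(ratio - 10) / 10, 0.15)
})

test_that("generated tables pass the readers' validation with no warnings", {
  cfg <- generator_config(n_cases = 25, seed = 2, raw_mean = 300)
  cases <- generate_cases(cfg)
  v <- generate_variants(cases, cfg)
  expect_no_warning(validate_variant_table(v))
  ped <- generate_pedigree(cases)
  mt <- generate_mtdna(cases, ped, cfg)
  expect_no_warning(validate_variant_table(mt))

  dir <- withr::local_tempdir()
  write_case_table(cases, file.path(dir, "cases.tsv"))
  back <- read_case_table(file.path(dir, "cases.tsv"))
  expect_equal(nrow(back), 25)
  expect_equal(back$ma_status, cases$ma_status)
  expect_equal(back$age_months, cases$age_months)
  expect_equal(format(back$death_time), format(cases$death_time))

  write_variant_table(v, file.path(dir, "variants.tsv"))
  expect_no_warning(vback <- read_variant_table(file.path(dir,
                                                          "variants.tsv")))
  expect_equal(nrow(vback), nrow(v))
})

test_that("planted mtDNA structure follows the pedigree", {
  cfg <- generator_config(n_cases = 60, seed = 9)
  cases <- generate_cases(cfg)
  ped <- generate_pedigree(cases, parents_for = "all")
  mt <- generate_mtdna(cases, ped, cfg)
  # full maternal transmission: shared equals the proband burden
  for (i in seq_len(20)) {
    pid <- ped$proband_sample[i]
    prof_p <- filter_heteroplasmic(mt[mt$sample_id == pid, ])
    prof_m <- filter_heteroplasmic(mt[mt$sample_id ==
                                        ped$mother_sample[i], ])
    res <- maternal_sharing(prof_p, prof_m)
    expect_equal(res$shared_with_mother, res$n_total)
  }

  # zero transmission: sharing collapses to (vanishingly rare) collisions
  cfg0 <- generator_config(n_cases = 60, seed = 9,
                           mtdna = list(maternal_transmission_prob = 0))
  mt0 <- generate_mtdna(cases, ped, cfg0)
  shared0 <- vapply(seq_len(nrow(ped)), function(i) {
    p <- filter_heteroplasmic(mt0[mt0$sample_id ==
                                    ped$proband_sample[i], ])
    m <- filter_heteroplasmic(mt0[mt0$sample_id ==
                                    ped$mother_sample[i], ])
    maternal_sharing(p, m)$shared_with_mother
  }, integer(1))
  expect_true(all(shared0 == 0L))
})

test_that("minors get sequenced parents in the synthetic pedigree", {
  cfg <- generator_config(n_cases = 80, seed = 21)
  cases <- generate_cases(cfg)
  ped <- generate_pedigree(cases)
  minor <- cases$age_months <= 18 * 12
  expect_true(all(!is.na(ped$mother_sample[minor])))
  expect_true(all(is.na(ped$mother_sample[!minor])))
})
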