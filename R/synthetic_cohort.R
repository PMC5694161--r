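#' Default synthetic gene catalog
#'
#' Builds the gene universe the variant generator draws from: a set of
#' named cardiac-disease panel anchors (with a designated causal sublist
#' of recognised sudden-death genes), a few large recurrently mutated
#' non-panel loci, and a long-tailed synthetic background. Per-gene
#' variant yield is proportional to the `length` column (locus footprint,
#' arbitrary units), so large loci accumulate more variants. Default
#' footprints put the panel at roughly 2% of the total, matching the
#' observed panel share of cascade survivors.
#'
#' @param n_background number of synthetic background genes.
#' @param bg_meanlog,bg_sdlog log-normal parameters of background
#'   footprints.
#' @param seed seed for the footprint draw.
#' @return `data.frame` with columns `gene`, `length`, `in_panel`,
#'   `causal`.
#' @export
gene_catalog <- function(n_background = 400, bg_meanlog = 10.8,
                         bg_sdlog = 1, seed = 99L) {
  panel_genes <- c("TTN", "MYH7", "MYH6", "MYBPC3", "TNNT2", "TNNI3",
                   "TPM1", "ACTC1", "MYL2", "MYL3", "PKP2", "DSP", "DSG2",
                   "DSC2", "JUP", "RYR2", "SCN5A", "SCN10A", "KCNQ1",
                   "KCNH2", "KCNE1", "KCNE2", "KCNJ2", "CASQ2", "CALM1",
                   "CALM2", "CALM3", "ANK2", "CACNA1C", "CACNB2", "HCN4",
                   "TRPM4", "LMNA", "DES", "PLN", "AKAP9", "TMEM43",
                   "LDB3", "CSRP3", "TNNC1", "GLA", "PRKAG2", "TTR",
                   "NOTCH1", "LTBP2", "LAMA2")
  causal_genes <- c("RYR2", "SCN5A", "KCNQ1", "KCNH2", "MYH7", "MYBPC3",
                    "PKP2", "DSP", "TRPM4", "HCN4", "SCN10A", "AKAP9",
                    "MYH6", "TTR", "CALM1")
  big_nonpanel <- data.frame(
    gene = c("MUC16", "SSPO", "OBSCN", "SYNE1", "NEB"),
    length = c(132000, 58000, 150000, 147000, 100000),
    stringsAsFactors = FALSE)
  panel <- data.frame(
    gene = panel_genes,
    length = c(305000, rep(8000, length(panel_genes) - 1)),
    stringsAsFactors = FALSE)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  bg <- data.frame(
    gene = sprintf("GENE%03d", seq_len(n_background)),
    length = round(stats::rlnorm(n_background, bg_meanlog, bg_sdlog)),
    stringsAsFactors = FALSE)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  cat_df <- rbind(panel, big_nonpanel, bg)
  cat_df$in_panel <- cat_df$gene %in% panel_genes
  cat_df$causal <- cat_df$gene %in% causal_genes
  rownames(cat_df) <- NULL
  cat_df
}

#' Synthetic cohort generator configuration
#'
#' Parameters of the seeded cohort generator. Defaults are the study
#' conditions of the 50-case cohort the analyses were designed around:
#' a bimodal age distribution with an infant peak (weight 8/50) and an
#' exponential rise towards 44 years, a 1:2 female:male ratio, forensic
#' autopsy positivity increasing with age, per-gene variant counts scaled
#' by locus footprint, per-stage cascade survival reproducing ~0.4%
#' retention (the ratios of the published per-stage medians), the
#' published per-sample panel likely-count distribution (46/36/12/6% for
#' 0--3) coupled to a 28% causal-positive rate, and maternally
#' transmitted mtDNA heteroplasmy with a high-burden infant subgroup
#' (probability 0.5).
#'
#' @param n_cases cohort size.
#' @param seed integer seed; all generator draws derive from it.
#' @param infant_weight probability a case is an infant (under
#'   12 months).
#' @param adult_age_scale exponential scale (months) of the adult age
#'   distribution, which rises towards 528 months (44 years).
#' @param sex_male_prob probability of male sex.
#' @param fa_logistic intercept/slope (per month of age) of the logistic
#'   forensic-autopsy positivity model.
#' @param panel_likely_probs probabilities of 0--3 likely pathogenic
#'   panel variants per sample.
#' @param ma_likely_rate planted causal-positive rate; conditional on at
#'   least one panel likely variant, one of them is made a recognised
#'   cause (category 1 in a causal gene) with probability
#'   `ma_likely_rate / P(count >= 1)`.
#' @param raw_mean mean raw variant calls per sample. The study scale is
#'   ~98,667; simulations in this package default to a scaled-down 4,000
#'   so whole cohorts fit in memory and seconds -- the cascade acts
#'   per-variant, so retention statistics are scale-free.
#' @param stage_survival per-stage survival probabilities
#'   (`qc`, `internal`, `kg`); defaults 80445/98667, 4684/80445,
#'   354.5/4684.
#' @param exome_likely_mean mean planted likely pathogenic variants per
#'   sample outside the panel (exome-only signal).
#' @param likely_effect_probs effect mixture of likely pathogenic
#'   variants (missense/nonsense/frameshift).
#' @param background_effect_probs effect mixture of background variants
#'   (missense/synonymous/noncoding), which map to categories 3/4/5.
#' @param weekday_weights 7 non-negative weights (Monday first) for the
#'   day of death.
#' @param hour_profile 24 non-negative weights for the hour of death.
#' @param date_range study window the death dates are drawn from.
#' @param genes gene catalog, see [gene_catalog()].
#' @param mtdna list of mitochondrial generator parameters:
#'   `burden_mean` (baseline heteroplasmic variants per sample, capped
#'   below the high-burden threshold), `high_burden_infant_prob`,
#'   `high_burden_other_prob`, `high_burden_min`, `high_burden_extra_mean`,
#'   `dloop_prob`, `hf_range`, `depth_mean`,
#'   `maternal_transmission_prob`, `hf_jitter`, `father_burden_mean`.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_cases = 50, seed = 1L,
                             infant_weight = 8 / 50,
                             adult_age_scale = 150,
                             sex_male_prob = 31 / 50,
                             fa_logistic = c(intercept = -2.5,
                                             slope = 0.009),
                             panel_likely_probs = c(0.46, 0.36, 0.12, 0.06),
                             ma_likely_rate = 0.28,
                             raw_mean = 4000,
                             stage_survival = c(qc = 80445 / 98667,
                                                internal = 4684 / 80445,
                                                kg = 354.5 / 4684),
                             exome_likely_mean = 10.5,
                             likely_effect_probs = c(missense = 0.757,
                                                     nonsense = 0.097,
                                                     frameshift = 0.146),
                             background_effect_probs = c(missense = 0.55,
                                                         synonymous = 0.25,
                                                         noncoding = 0.20),
                             weekday_weights = rep(1, 7),
                             hour_profile = c(rep(1, 8), rep(2, 12),
                                              rep(1, 4)),
                             date_range = c("2014-08-01", "2017-03-31"),
                             genes = gene_catalog(),
                             mtdna = list()) {
  mt_defaults <- list(burden_mean = 4, high_burden_infant_prob = 0.5,
                      high_burden_other_prob = 0.095,
                      high_burden_min = 10L, high_burden_extra_mean = 3,
                      dloop_prob = 0.45, hf_range = c(0.25, 0.9),
                      depth_mean = 500,
                      maternal_transmission_prob = 1.0, hf_jitter = 0.05,
                      father_burden_mean = 1)
  mtdna <- utils::modifyList(mt_defaults, mtdna)
  cfg <- list(n_cases = n_cases, seed = as.integer(seed),
              infant_weight = infant_weight,
              adult_age_scale = adult_age_scale,
              sex_male_prob = sex_male_prob, fa_logistic = fa_logistic,
              panel_likely_probs = panel_likely_probs,
              ma_likely_rate = ma_likely_rate, raw_mean = raw_mean,
              stage_survival = stage_survival,
              exome_likely_mean = exome_likely_mean,
              likely_effect_probs = likely_effect_probs,
              background_effect_probs = background_effect_probs,
              weekday_weights = weekday_weights,
              hour_profile = hour_profile, date_range = date_range,
              genes = genes, mtdna = mtdna)
  probs <- c(cfg$infant_weight, cfg$sex_male_prob, cfg$panel_likely_probs,
             cfg$ma_likely_rate, cfg$stage_survival,
             cfg$likely_effect_probs, cfg$background_effect_probs,
             unlist(cfg$mtdna[c("high_burden_infant_prob",
                                "high_burden_other_prob", "dloop_prob",
                                "maternal_transmission_prob")]))
  if (any(probs < 0 | probs > 1))
    stop("generator_config: probabilities must lie in [0, 1]")
  if (any(cfg$weekday_weights < 0) || all(cfg$weekday_weights == 0))
    stop("generator_config: invalid weekday_weights")
  if (any(cfg$hour_profile < 0) || all(cfg$hour_profile == 0))
    stop("generator_config: invalid hour_profile")
  if (any(cfg$genes$length <= 0))
    stop("generator_config: gene lengths must be positive")
  if (cfg$ma_likely_rate > 1 - cfg$panel_likely_probs[1] + 1e-12)
    stop("generator_config: ma_likely_rate cannot exceed the probability ",
         "of carrying at least one panel likely variant")
  structure(cfg, class = "generator_config")
}

sample_probs <- function(x) x / sum(x)

#' Generate synthetic cases
#'
#' Draws a cohort of case records under a [generator_config()]:
#' bimodal ages, sex ratio, age-dependent forensic-autopsy status, death
#' timestamps with configurable weekday and hour profiles, and the
#' hidden planted truth used by [generate_variants()] --
#' `panel_likely_count` (number of likely pathogenic panel variants to
#' plant) and `causal_planted` (whether one of them is a recognised
#' cause, which determines `ma_status`).
#'
#' @param config a [generator_config()].
#' @return a case table compatible with [read_case_table()] output, plus
#'   the planted-truth columns.
#' @export
generate_cases <- function(config = generator_config()) {
  set.seed(config$seed)
  n <- config$n_cases
  infant <- stats::runif(n) < config$infant_weight
  age <- numeric(n)
  age[infant] <- sample(1:11, sum(infant), replace = TRUE)
  n_adult <- sum(!infant)
  if (n_adult > 0) {
    draw <- function(m) {
      out <- numeric(0)
      while (length(out) < m) {
        e <- stats::rexp(m, rate = 1 / config$adult_age_scale)
        ok <- 528 - e >= 13
        out <- c(out, (528 - e)[ok])
      }
      out[seq_len(m)]
    }
    age[!infant] <- round(draw(n_adult))
  }
  sex <- ifelse(stats::runif(n) < config$sex_male_prob, "male", "female")
  p_fa <- stats::plogis(config$fa_logistic[["intercept"]] +
                          config$fa_logistic[["slope"]] * age)
  fa_status <- ifelse(stats::runif(n) < p_fa, "positive", "negative")

  k <- sample(0:3, n, replace = TRUE,
              prob = sample_probs(config$panel_likely_probs))
  p_any <- 1 - sample_probs(config$panel_likely_probs)[1]
  causal <- k >= 1 & stats::runif(n) < config$ma_likely_rate / p_any

  d0 <- as.Date(config$date_range[1])
  d1 <- as.Date(config$date_range[2])
  base_date <- d0 + sample.int(as.integer(d1 - d0) + 1L, n,
                               replace = TRUE) - 1L
  target_wd <- sample.int(7L, n, replace = TRUE,
                          prob = sample_probs(config$weekday_weights))
  # shift each date within its ISO week to the drawn weekday
  cur_wd <- as.integer(format(base_date, "%u"))
  date <- base_date + (target_wd - cur_wd)
  hour <- sample(0:23, n, replace = TRUE,
                 prob = sample_probs(config$hour_profile))
  minute <- sample(0:59, n, replace = TRUE)
  death_time <- as.POSIXct(paste0(format(date), sprintf(" %02d:%02d:00",
                                                        hour, minute)),
                           tz = "UTC")
  case_id <- sprintf("SYN%05d", seq_len(n))
  data.frame(case_id = case_id, proband_id = case_id, n_probands = 1L,
             age_months = age,
             ages_months_all = as.character(age),
             sex = sex, race = NA_character_, fa_status = fa_status,
             fa_summary = NA_character_,
             ma_status = ifelse(causal, "positive", "negative"),
             death_time = death_time, site_label = "SYN",
             include_in_cohort = TRUE,
             panel_likely_count = k, causal_planted = causal,
             stringsAsFactors = FALSE)
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

#' Generate a synthetic cohort variant table
#'
#' Draws, per sample, raw background variant calls whose per-gene counts
#' scale with locus footprint and whose QC flags and allele frequencies
#' reproduce the configured per-stage cascade survival, then plants the
#' likely pathogenic signal: exome-level likely variants in non-panel
#' genes, the per-sample panel likely-count distribution, and -- for
#' cases with `causal_planted` -- one recognised-causal (category 1)
#' variant in a causal gene. Background variants carry categories 3--5 by
#' effect class so that only planted variants are likely pathogenic.
#'
#' @param cases output of [generate_cases()].
#' @param config the same [generator_config()].
#' @return a validated variant table for the whole cohort.
#' @export
generate_variants <- function(cases, config = generator_config()) {
  set.seed(config$seed + 1L)
  genes <- config$genes
  gp <- sample_probs(genes$length)
  s <- config$stage_survival
  bg_eff <- names(config$background_effect_probs)
  bg_cat <- c(missense = 3L, synonymous = 4L, noncoding = 5L)
  lk_eff <- names(config$likely_effect_probs)

  per_sample <- function(i) {
    sid <- cases$proband_id[i]
    n_raw <- stats::rpois(1, config$raw_mean)
    gi <- sample.int(nrow(genes), n_raw, replace = TRUE, prob = gp)
    al <- random_alleles(n_raw)
    qc <- stats::runif(n_raw) < s[["qc"]]
    rare_int <- stats::runif(n_raw) < s[["internal"]]
    af_int <- ifelse(rare_int, stats::runif(n_raw, 0, 0.05),
                     stats::runif(n_raw, 0.05, 0.6))
    rare_kg <- stats::runif(n_raw) < s[["kg"]]
    af_kg <- ifelse(rare_int,
                    ifelse(rare_kg, stats::runif(n_raw, 0, 0.01),
                           stats::runif(n_raw, 0.01, 0.5)),
                    pmin(1, af_int * stats::runif(n_raw, 0.5, 1.5)))
    eff <- sample(bg_eff, n_raw, replace = TRUE,
                  prob = sample_probs(config$background_effect_probs))
    bg <- variant_table(
      sample_id = sid, chrom = paste0("chr", sample.int(22L, n_raw,
                                                        replace = TRUE)),
      pos = sample.int(2.4e8, n_raw, replace = TRUE),
      ref = al$ref, alt = al$alt, gene = genes$gene[gi], effect = eff,
      qc_pass = qc, af_internal = af_int, af_1kg = af_kg,
      category = bg_cat[eff])

    plant <- function(m, gene_pool) {
      if (m == 0) return(NULL)
      gsel <- sample(gene_pool, m, replace = TRUE)
      al2 <- random_alleles(m)
      eff2 <- sample(lk_eff, m, replace = TRUE,
                     prob = sample_probs(config$likely_effect_probs))
      variant_table(
        sample_id = sid,
        chrom = paste0("chr", sample.int(22L, m, replace = TRUE)),
        pos = sample.int(2.4e8, m, replace = TRUE),
        ref = al2$ref, alt = al2$alt, gene = gsel, effect = eff2,
        qc_pass = TRUE, af_internal = NA_real_, af_1kg = NA_real_,
        category = ifelse(eff2 == "missense", 1L, 2L))
    }
    n_exome <- stats::rpois(1, config$exome_likely_mean)
    exome_plant <- plant(n_exome, genes$gene[!genes$in_panel])
    k <- cases$panel_likely_count[i]
    causal <- cases$causal_planted[i]
    causal_plant <- if (causal) plant(1L, genes$gene[genes$causal])
      else NULL
    noncausal_pool <- genes$gene[genes$in_panel & !genes$causal]
    panel_plant <- plant(k - as.integer(causal), noncausal_pool)
    out <- rbind(bg, exome_plant, causal_plant, panel_plant)
    rownames(out) <- NULL
    out
  }
  out <- do.call(rbind, lapply(seq_len(nrow(cases)), per_sample))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic pedigree
#'
#' Minor cases (age <= 18 years) get sequenced parents, mirroring the
#' trio-sequencing policy for probands under 18.
#'
#' @param cases output of [generate_cases()].
#' @param parents_for `"minors"` (default) or `"all"`.
#' @return a pedigree `data.frame` (`case_id`, `proband_sample`,
#'   `mother_sample`, `father_sample`).
#' @export
generate_pedigree <- function(cases, parents_for = c("minors", "all")) {
  parents_for <- match.arg(parents_for)
  has_parents <- if (parents_for == "all") rep(TRUE, nrow(cases))
    else cases$age_months <= 18 * 12
  data.frame(case_id = cases$case_id,
             proband_sample = cases$proband_id,
             mother_sample = ifelse(has_parents,
                                    paste0(cases$case_id, "-M"),
                                    NA_character_),
             father_sample = ifelse(has_parents,
                                    paste0(cases$case_id, "-F"),
                                    NA_character_),
             stringsAsFactors = FALSE)
}

mt_positions <- function(m, dloop_prob) {
  dloop_pool <- c(16024:16569, 1:576)
  other_pool <- 577:16023
  in_dloop <- stats::runif(m) < dloop_prob
  pos <- integer(m)
  pos[in_dloop] <- sample(dloop_pool, sum(in_dloop))
  pos[!in_dloop] <- sample(other_pool, sum(!in_dloop))
  pos
}

mt_variant_rows <- function(sid, pos, hf, depth_mean) {
  m <- length(pos)
  al <- random_alleles(m)
  total <- pmax(20L, stats::rpois(m, depth_mean))
  depth_alt <- pmax(1L, pmin(total - 1L, as.integer(round(hf * total))))
  variant_table(sample_id = sid, chrom = "MT", pos = pos,
                ref = al$ref, alt = al$alt, gene = NA_character_,
                effect = "other", qc_pass = TRUE,
                af_internal = NA_real_, af_1kg = NA_real_,
                category = NA_integer_, zygosity = "het",
                depth_ref = total - depth_alt, depth_alt = depth_alt)
}

#' Generate synthetic mitochondrial heteroplasmy data
#'
#' Per proband, draws heteroplasmic mtDNA variants (allelic depths
#' encode the heteroplasmic fraction) with D-loop enrichment. Infants
#' are high-burden (at least `high_burden_min` variants) with
#' probability `high_burden_infant_prob`; other cases with
#' `high_burden_other_prob`; baseline burdens are capped below the
#' high-burden threshold so the planted high-burden fraction is exact.
#' Each proband variant is copied into the mother's table with
#' probability `maternal_transmission_prob`, its heteroplasmic fraction
#' jittered within the band; fathers receive independent background
#' variants.
#'
#' @param cases output of [generate_cases()].
#' @param pedigree output of [generate_pedigree()].
#' @param config the [generator_config()].
#' @return a single variant table containing proband, mother and father
#'   mitochondrial records (sample ids as in the pedigree).
#' @export
generate_mtdna <- function(cases, pedigree,
                           config = generator_config()) {
  set.seed(config$seed + 2L)
  mt <- config$mtdna
  ped <- pedigree[match(cases$case_id, pedigree$case_id), , drop = FALSE]
  out <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    infant <- cases$age_months[i] < 12
    p_high <- if (infant) mt$high_burden_infant_prob
      else mt$high_burden_other_prob
    high <- stats::runif(1) < p_high
    m <- if (high)
      mt$high_burden_min + stats::rpois(1, mt$high_burden_extra_mean)
    else min(stats::rpois(1, mt$burden_mean), mt$high_burden_min - 1L)
    pos <- mt_positions(m, mt$dloop_prob)
    hf <- stats::runif(m, mt$hf_range[1], mt$hf_range[2])
    proband <- mt_variant_rows(cases$proband_id[i], pos, hf,
                               mt$depth_mean)
    rows <- list(proband)
    mother_id <- ped$mother_sample[i]
    if (!is.na(mother_id) && m >= 0) {
      transmitted <- stats::runif(m) < mt$maternal_transmission_prob
      if (any(transmitted)) {
        hf_m <- pmin(mt$hf_range[2],
                     pmax(mt$hf_range[1],
                          hf[transmitted] +
                            stats::runif(sum(transmitted), -mt$hf_jitter,
                                         mt$hf_jitter)))
        mrow <- mt_variant_rows(mother_id, pos[transmitted], hf_m,
                                mt$depth_mean)
        # identical variant identity (pos, ref, alt) to the proband's
        mrow$ref <- proband$ref[transmitted]
        mrow$alt <- proband$alt[transmitted]
        rows <- c(rows, list(mrow))
      }
    }
    father_id <- ped$father_sample[i]
    if (!is.na(father_id)) {
      fm <- stats::rpois(1, mt$father_burden_mean)
      if (fm > 0) {
        fpos <- mt_positions(fm, mt$dloop_prob)
        fhf <- stats::runif(fm, mt$hf_range[1], mt$hf_range[2])
        rows <- c(rows, list(mt_variant_rows(father_id, fpos, fhf,
                                             mt$depth_mean)))
      }
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
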