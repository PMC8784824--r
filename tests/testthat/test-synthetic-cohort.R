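test_that("cohort generation is deterministic under a fixed config", {
  cfg <- small_cfg(n = 500L, seed = 42L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$weights_bmi, b$weights_bmi)
  cfg2 <- small_cfg(n = 500L, seed = 43L)
  expect_false(identical(simulate_cohort(cfg2)$data$admissions,
                         a$data$admissions))
})

test_that("genotype dosages follow the binomial model", {
  cfg <- sim_config(n_participants = 50000L, n_snps_bmi = 4L, n_snps_whr = 0L,
                    maf_range = c(0.5, 0.5), seed = 1L)
  d <- generate_genotypes(cfg)
  # mean dosage 1.0 by symmetry; MC SE of a mean of Bin(2, .5)/n draws
  mc_se <- sqrt(0.5 / 50000)
  expect_true(all(abs(colMeans(d) - 1) < 3 * mc_se))

  cfg2 <- sim_config(n_participants = 100000L, n_snps_bmi = 3L,
                     n_snps_whr = 0L, maf_range = c(0.2, 0.2), seed = 2L)
  d2 <- generate_genotypes(cfg2)
  v <- apply(d2, 2, var)
  # binomial variance 2 p (1-p) = 0.32; MC SE of the sample variance
  mc_se_v <- sqrt(2 / 100000) * 0.32
  expect_true(all(abs(v - 0.32) < 3 * mc_se_v))
  expect_error(generate_genotypes(
    small_cfg(n = 10L, n_snps_bmi = 0L, n_snps_whr = 0L)), "no instruments")
})

test_that("exposure generation hits the variance-explained target", {
  cfg <- sim_config(n_participants = 100000L, n_snps_bmi = 30L,
                    n_snps_whr = 5L, grs_r2_bmi = 0.017, seed = 3L)
  co <- simulate_cohort(cfg)
  fs <- fit_first_stage(co$data$bmi,
                        compute_grs(co$dosages, true_weight_table(co)))
  expect_gt(fs$r_squared, 0.014)
  expect_lt(fs$r_squared, 0.020)
  expect_gt(sd(co$data$bmi), 4.6)
  expect_lt(sd(co$data$bmi), 4.9)

  cfg0 <- small_cfg(n = 5000L, grs_r2_bmi = 0, grs_r2_whr = 0, seed = 4L)
  co0 <- simulate_cohort(cfg0)
  r2 <- summary(lm(co0$data$bmi ~ co0$dosages))$r.squared
  expect_lt(r2, 0.01) # pure noise fit at p/n
  expect_error(sim_config(grs_r2_bmi = 1), "grs_r2")
})

test_that("follow-up respects the entry/censoring/death model", {
  cfg <- small_cfg(n = 5000L, death_hazard = 0, seed = 5L)
  f <- generate_followup(cfg)
  expect_true(all(f$died == 0))
  expect_true(all(f$person_years > cfg$max_followup_years -
                    cfg$recruit_window_years - 1e-12))
  expect_true(all(f$person_years <= cfg$max_followup_years))

  cfg2 <- sim_config(n_participants = 50000L, n_snps_bmi = 2L,
                     n_snps_whr = 0L, seed = 6L)
  f2 <- generate_followup(cfg2)
  expect_gt(mean(f2$person_years), 5.9)
  expect_lt(mean(f2$person_years), 6.2)
  expect_gt(mean(f2$died), 0.015)
  expect_lt(mean(f2$died), 0.025)
  expect_error(sim_config(max_followup_years = -1), "follow-up|horizon")
})

test_that("admission counts are equidispersed without frailty and scale with t", {
  cfg <- small_cfg(n = 20000L, frailty_variance = 0,
                   rate_ratio_per_sd_bmi = 1, rate_ratio_per_sd_whr = 1,
                   confounder_log_rate = 0, seed = 7L)
  co <- simulate_cohort(cfg)
  y <- co$data$admissions
  expect_gt(var(y) / mean(y), 0.9)
  expect_lt(var(y) / mean(y), 1.1)

  doubled <- co$data
  doubled$person_years <- 2 * doubled$person_years
  y2 <- generate_admissions(doubled, cfg)
  mc_se <- sqrt(var(y2) / length(y2) + 4 * var(y) / length(y))
  expect_lt(abs(mean(y2) - 2 * mean(y)), 3 * mc_se)
  expect_error(sim_config(frailty_variance = -1), "frailty")
})

test_that("pleiotropy injection matches the requested mode", {
  expect_identical(inject_pleiotropy(small_cfg(), 10L), rep(0, 10))
  J <- 400L
  s <- 0.02
  cfg_b <- small_cfg(pleiotropy = "balanced", pleiotropy_sd = s, seed = 8L)
  a_b <- inject_pleiotropy(cfg_b, J)
  expect_lt(abs(mean(a_b)), 3 * s / sqrt(J))
  cfg_d <- small_cfg(pleiotropy = "directional", pleiotropy_mean = 0.05,
                     pleiotropy_sd = s, seed = 9L)
  a_d <- inject_pleiotropy(cfg_d, J)
  expect_lt(abs(mean(a_d) - 0.05), 3 * s / sqrt(J))
  cfg_bad <- small_cfg()
  cfg_bad$pleiotropy <- "weird"
  expect_error(inject_pleiotropy(cfg_bad, 5L), "unknown pleiotropy mode")
})

test_that("two-sample split is disjoint, exhaustive and reproducible", {
  co <- simulate_cohort(small_cfg(n = 100L, seed = 10L))
  sp <- split_two_sample(co, 0.5, seed = 1L)
  expect_equal(nrow(sp$a$data), 50)
  expect_equal(nrow(sp$b$data), 50)
  expect_length(intersect(sp$a$data$id, sp$b$data$id), 0)
  expect_setequal(c(sp$a$data$id, sp$b$data$id), co$data$id)
  sp2 <- split_two_sample(co, 0.5, seed = 1L)
  expect_identical(sp$a$data$id, sp2$a$data$id)
  for (s in c(2L, 3L, 4L)) {
    spx <- split_two_sample(co, 0.3, seed = s)
    expect_length(intersect(spx$a$data$id, spx$b$data$id), 0)
  }
  expect_error(split_two_sample(co, 1.2), "fraction")
})

test_that("per-SNP exposure summary statistics recover the true weights", {
  cfg <- sim_config(n_participants = 20000L, n_snps_bmi = 40L,
                    n_snps_whr = 3L, seed = 11L)
  co <- simulate_cohort(cfg)
  ss <- generate_summary_stats(co, "exposure", exposure = "bmi",
                               snps = names(co$weights_bmi))
  hits <- abs(ss$beta - co$weights_bmi[ss$variant_id]) < 3 * ss$se
  expect_gte(mean(hits), 0.95)
  expect_true(all(ss$se > 0))
  expect_true(all(ss$eaf >= 0 & ss$eaf <= 1))
})

test_that("null SNP associations have calibrated type-I error", {
  # WHR SNPs have no effect on BMI, so their BMI associations are null
  # (the shared confounder does not touch genotypes)
  cfg <- sim_config(n_participants = 5000L, n_snps_bmi = 5L,
                    n_snps_whr = 200L, seed = 12L)
  co <- simulate_cohort(cfg)
  ss <- generate_summary_stats(co, "exposure", exposure = "bmi",
                               snps = names(co$weights_whr))
  rej <- mean(abs(ss$beta / ss$se) > 1.96)
  mc_se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rej - 0.05), 3 * mc_se)
})

test_that("constant dosage columns are omitted with a warning", {
  co <- simulate_cohort(small_cfg(n = 300L, seed = 13L))
  co$dosages[, 2] <- 1L
  expect_warning(ss <- generate_summary_stats(co, "exposure"),
                 "constant dosage")
  expect_false(colnames(co$dosages)[2] %in% ss$variant_id)
})

test_that("outcome summary statistics are per-SNP quasi-Poisson fits", {
  co <- simulate_cohort(small_cfg(n = 3000L, seed = 14L))
  ss <- generate_summary_stats(co, "outcome", snps = colnames(co$dosages)[1:3])
  # oracle: direct quasi-Poisson fit for one SNP
  d <- co$data
  fit <- fit_quasipoisson(d$admissions,
                          data.frame(snp = co$dosages[, 1]),
                          d$person_years)
  expect_equal(ss$beta[1], unname(fit$coefficients["snp"]), tolerance = 1e-6)
  expect_equal(ss$se[1], unname(fit$se["snp"]), tolerance = 1e-4)
})
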