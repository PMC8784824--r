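mk_stats <- function(id, ea, oa, beta, se, eaf, pval = 0.001, n = 1000) {
  out <- data.frame(variant_id = id, effect_allele = ea, other_allele = oa,
                    beta = beta, se = se, pval = pval, eaf = eaf, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats_table", "data.frame")
  out
}

test_that("harmonization aligns allele codings", {
  ex <- mk_stats(c("rs1", "rs2", "rs3", "rs4"),
                 c("A", "A", "A", "A"), c("G", "G", "T", "G"),
                 beta = c(0.1, 0.2, 0.15, 0.1), se = 0.01,
                 eaf = c(0.3, 0.3, 0.50, 0.3))
  ou <- mk_stats(c("rs1", "rs2", "rs3", "rs4"),
                 c("A", "G", "A", "A"), c("G", "A", "T", "C"),
                 beta = c(0.02, 0.03, 0.01, 0.02), se = 0.005,
                 eaf = c(0.31, 0.69, 0.5, 0.3))
  h <- harmonize(ex, ou)
  aud <- attr(h, "audit")
  # identical coding: unchanged
  expect_equal(h$beta_y[h$variant_id == "rs1"], 0.02)
  # swapped alleles: outcome beta negated
  expect_equal(h$beta_y[h$variant_id == "rs2"], -0.03)
  expect_equal(aud$action[aud$variant_id == "rs2"], "flipped")
  # palindromic A/T at eaf 0.5: dropped
  expect_false("rs3" %in% h$variant_id)
  expect_match(aud$reason[aud$variant_id == "rs3"], "palindromic")
  # incompatible allele pair: dropped with reason
  expect_false("rs4" %in% h$variant_id)
  expect_match(aud$reason[aud$variant_id == "rs4"], "incompatible")
})

test_that("harmonization resolves strand flips and unambiguous palindromes", {
  ex <- mk_stats(c("rs1", "rs2"), c("A", "A"), c("G", "T"),
                 beta = c(0.1, 0.1), se = 0.01, eaf = c(0.3, 0.2))
  ou <- mk_stats(c("rs1", "rs2"), c("T", "A"), c("C", "T"),
                 beta = c(0.02, 0.05), se = 0.005, eaf = c(0.3, 0.81))
  h <- harmonize(ex, ou)
  # rs1: T/C is the strand complement of A/G, same orientation
  expect_equal(h$beta_y[h$variant_id == "rs1"], 0.02)
  # rs2: palindromic with eaf 0.2 vs 0.81 -> frequencies disagree, flip
  expect_equal(h$beta_y[h$variant_id == "rs2"], -0.05)
})

test_that("LD pruning retains no correlated pair", {
  ids <- sprintf("s%d", 1:6)
  r2_0 <- diag(6) * 0
  dimnames(r2_0) <- list(ids, ids)
  expect_setequal(ld_prune(ids, runif(6), r2_0), ids)

  # a duplicated SNP keeps only the smaller-p copy
  r2_dup <- r2_0
  r2_dup["s1", "s2"] <- r2_dup["s2", "s1"] <- 1
  kept <- ld_prune(ids, c(0.5, 0.001, rep(0.01, 4)), r2_dup)
  expect_true("s2" %in% kept)
  expect_false("s1" %in% kept)

  # brute-force property on random matrices
  set.seed(50)
  for (i in 1:20) {
    J <- 15
    M <- matrix(runif(J * J, 0, 0.01), J)
    r2 <- (M + t(M)) / 2
    diag(r2) <- 1
    idx <- sprintf("v%d", 1:J)
    dimnames(r2) <- list(idx, idx)
    kept <- ld_prune(idx, runif(J), r2, r2_threshold = 0.005)
    sub <- r2[kept, kept, drop = FALSE]
    diag(sub) <- 0
    expect_lt(max(sub), 0.005)
  }
})

test_that("Wald ratios follow the first- and second-order formulas", {
  st <- random_stats(5, seed = 51)
  st$beta_x <- c(0.1, 0.2, -0.1, 0.15, 0)
  st$beta_y <- c(0.02, 0, 0.01, 0.03, 0.01)
  st$se_y <- rep(0.01, 5)
  expect_warning(wr <- wald_ratios(st), "zero exposure beta")
  expect_equal(nrow(wr), 4)
  expect_equal(wr$ratio[1], 0.2)
  expect_equal(wr$se[1], 0.1)
  expect_equal(wr$ratio[2], 0)
  # joint negation leaves the ratio unchanged
  st2 <- st[1:4, ]
  st2$beta_x <- -st2$beta_x
  st2$beta_y <- -st2$beta_y
  expect_equal(wald_ratios(st2)$ratio, wr$ratio)
  # second-order SE adds the exposure-noise term
  wr2 <- wald_ratios(st[1, ], second_order = TRUE)
  expect_equal(wr2$se,
               sqrt(0.01^2 / 0.1^2 + 0.02^2 * st$se_x[1]^2 / 0.1^4),
               tolerance = 1e-12)
})

test_that("exact-weights IVW reduces to the closed form and the WLS oracle", {
  # equal-weight two-SNP mean
  st <- random_stats(2, seed = 52)
  st$beta_x <- c(1, 1); st$se_x <- c(0, 0)
  st$beta_y <- c(0.1, 0.3); st$se_y <- c(1, 1)
  expect_equal(ivw_exact(st)$estimate, 0.2, tolerance = 1e-12)

  set.seed(53)
  for (i in 1:50) {
    st <- random_stats(sample(5:40, 1), seed = 530 + i)
    st$se_x <- rep(0, nrow(st))
    est <- ivw_exact(st)$estimate
    oracle <- coef(lm(beta_y ~ 0 + beta_x, data = st,
                      weights = 1 / st$se_y^2))[[1]]
    expect_lt(abs(est - oracle), 1e-10)
    # continuity as the exposure SEs vanish
    st$se_x <- rep(1e-8, nrow(st))
    expect_lt(abs(ivw_exact(st)$estimate - oracle), 1e-6)
  }
  expect_error(ivw_exact(random_stats(1, 1)), "at least 2")
})

test_that("exact weights undo regression-dilution bias from exposure noise", {
  # with noisy exposure betas the closed form is attenuated; the exact-
  # weights optimum recovers the slope on average
  set.seed(54)
  R <- 100
  J <- 30
  b <- 0.4
  cf <- ex <- numeric(R)
  for (r in 1:R) {
    w <- runif(J, 0.05, 0.3)
    sx <- 0.05
    st <- data.frame(variant_id = seq_len(J), beta_x = w + rnorm(J, 0, sx),
                     se_x = sx, beta_y = b * w + rnorm(J, 0, 0.02),
                     se_y = 0.02)
    cf[r] <- sum(st$beta_x * st$beta_y / st$se_y^2) /
      sum(st$beta_x^2 / st$se_y^2)
    ex[r] <- ivw_exact(st)$estimate
  }
  expect_lt(mean(cf), b - 3 * sd(cf) / sqrt(R)) # closed form is diluted
  expect_lt(abs(mean(ex) - b), 3 * sd(ex) / sqrt(R)) # exact weights are not
})

test_that("MR-Egger fits the intercept model and is orientation-invariant", {
  st <- random_stats(6, seed = 55)
  st$beta_x <- abs(st$beta_x)
  st$beta_y <- 0.05 + 0.2 * st$beta_x # exact linear construction
  e <- mr_egger(st)
  expect_equal(e$intercept, 0.05, tolerance = 1e-10)
  expect_equal(e$estimate, 0.2, tolerance = 1e-10)
  expect_equal(e$Q_R, 0, tolerance = 1e-16)

  st2 <- random_stats(10, seed = 56)
  e1 <- mr_egger(st2)
  flipped <- st2
  flipped$beta_x[3] <- -flipped$beta_x[3]
  flipped$beta_y[3] <- -flipped$beta_y[3]
  e2 <- mr_egger(flipped)
  expect_equal(e2$estimate, e1$estimate, tolerance = 1e-12)
  expect_equal(e2$intercept, e1$intercept, tolerance = 1e-12)

  st3 <- st2
  st3$beta_x <- rep(0.2, 10)
  expect_error(mr_egger(st3), "not separable")
  expect_error(mr_egger(st2[1:2, ]), "at least 3")
})

test_that("weighted median interpolates at cumulative weight one half", {
  st <- random_stats(7, seed = 57)
  st$beta_y <- 0.25 * st$beta_x # all ratios equal
  pm <- penalized_weighted_median(st, n_boot = 50, seed = 1)
  expect_equal(pm$estimate, 0.25, tolerance = 1e-10)

  # odd J, equal weights, homogeneous enough that no penalty triggers:
  # close to the simple median
  st2 <- random_stats(5, seed = 58)
  st2$beta_x <- rep(0.2, 5)
  st2$se_y <- rep(0.05, 5)
  st2$beta_y <- c(0.039, 0.040, 0.041, 0.042, 0.043)
  pm2 <- penalized_weighted_median(st2, n_boot = 50, seed = 1)
  expect_equal(pm2$estimate, median(st2$beta_y / st2$beta_x),
               tolerance = 0.01)
})

test_that("the penalized median resists a minority of invalid SNPs", {
  set.seed(59)
  R <- 60
  b <- 0.3
  est_med <- est_ivw <- numeric(R)
  for (r in 1:R) {
    st <- sim_summary_mr(J = 30, b = b, se_x = 0.005, se_y = 0.01,
                         pleiotropy = "directional", pleiotropy_mean = 0.05,
                         pleiotropy_sd = 0.005, prop_invalid = 0.3,
                         seed = 590 + r)
    est_med[r] <- penalized_weighted_median(st, n_boot = 50,
                                            seed = r)$estimate
    est_ivw[r] <- ivw_exact(st)$estimate
  }
  expect_lt(abs(mean(est_med) - b), 3 * sd(est_med) / sqrt(R))
  expect_gt(mean(est_ivw), b + 3 * sd(est_ivw) / sqrt(R)) # IVW is pushed up
})

test_that("the weighted mode finds the dominant cluster", {
  st <- random_stats(9, seed = 60)
  st$beta_y <- 0.15 * st$beta_x
  wm <- weighted_mode(st, n_boot = 50, seed = 1)
  expect_equal(wm$estimate, 0.15, tolerance = 1e-6)

  set.seed(61)
  J <- 20
  w <- runif(J, 0.1, 0.3)
  ratios <- c(rep(0.2, 12), runif(8, 0.6, 2.4)) # 60% cluster at 0.2
  st2 <- data.frame(variant_id = sprintf("m%d", 1:J),
                    beta_x = w, se_x = 0.001,
                    beta_y = ratios * w + rnorm(J, 0, 0.001), se_y = 0.01)
  wm2 <- weighted_mode(st2, n_boot = 50, seed = 2)
  expect_lt(abs(wm2$estimate - 0.2), wm2$bandwidth / 2)
  # permutation invariance
  perm <- st2[sample(J), ]
  wm3 <- weighted_mode(perm, n_boot = 50, seed = 2)
  expect_equal(wm3$estimate, wm2$estimate, tolerance = 1e-12)
})

test_that("multivariable IVW reduces to univariable and solves exact systems", {
  st <- random_stats(12, seed = 62)
  mv <- mvmr_ivw_twosample(matrix(st$beta_x, ncol = 1), st$beta_y, st$se_y)
  closed <- sum(st$beta_x * st$beta_y / st$se_y^2) /
    sum(st$beta_x^2 / st$se_y^2)
  expect_equal(mv[[1]]$estimate, closed, tolerance = 1e-12)

  set.seed(63)
  X <- cbind(x1 = runif(15, 0.05, 0.3), x2 = runif(15, 0.05, 0.3))
  by <- 0.1 * X[, 1] + 0.3 * X[, 2]
  mv2 <- mvmr_ivw_twosample(X, by, rep(0.01, 15))
  expect_equal(mv2$x1$estimate, 0.1, tolerance = 1e-10)
  expect_equal(mv2$x2$estimate, 0.3, tolerance = 1e-10)
  expect_equal(mv2$x1$Q, 0, tolerance = 1e-16)
  expect_error(mvmr_ivw_twosample(cbind(X[, 1], 2 * X[, 1]), by,
                                  rep(0.01, 15)), "collinear")
})

test_that("two-sample separation mirrors a single causal exposure", {
  set.seed(64)
  R <- 60
  hit1 <- hit2 <- logical(R)
  for (r in 1:R) {
    J <- 40
    X <- cbind(bmi = runif(J, 0.02, 0.2), whr = runif(J, 0.02, 0.2))
    se_y <- rep(0.01, J)
    by <- 0.25 * X[, 2] + rnorm(J, 0, 0.01) # only exposure 2 causal
    mv <- mvmr_ivw_twosample(X, by, se_y)
    hit1[r] <- mv$bmi$ci_low < 1 && mv$bmi$ci_high > 1 # covers null rate
    hit2[r] <- mv$whr$ci_low > 1
  }
  expect_gte(mean(hit1), 0.9)
  expect_gte(mean(hit2), 0.9)
})
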