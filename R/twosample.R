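COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) unname(COMPLEMENT[a1]) == a2

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins two GWAS-style tables on variant id and aligns the outcome
#' rows to the exposure's effect-allele convention: where the outcome's
#' effect allele equals the exposure's other allele, the outcome beta is
#' negated and its frequency complemented; strand (complement) flips are
#' attempted before declaring a pair incompatible. Strand-ambiguous (A/T,
#' C/G) variants are dropped when the exposure effect-allele frequency lies
#' within the ambiguity window, and aligned by frequency otherwise.
#'
#' @param exposure_stats,outcome_stats `summary_stats_table` data.frames
#'   (columns `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   and optionally `pval`, `eaf`, `n`).
#' @param eaf_window Frequency window inside which palindromic SNPs are
#'   considered unresolvable (default `c(0.42, 0.58)`).
#' @return A data.frame of class `harmonized_stats` with columns
#'   `variant_id`, `effect_allele`, `other_allele`, `beta_x`, `se_x`,
#'   `pval_x`, `beta_y`, `se_y`, `eaf`, and attribute `audit` recording the
#'   action taken per variant (kept, flipped, dropped + reason).
#' @export
harmonize <- function(exposure_stats, outcome_stats,
                      eaf_window = c(0.42, 0.58)) {
  ex <- as.data.frame(exposure_stats)
  ou <- as.data.frame(outcome_stats)
  shared <- intersect(ex$variant_id, ou$variant_id)
  ex <- ex[match(shared, ex$variant_id), ]
  ou <- ou[match(shared, ou$variant_id), ]
  n <- length(shared)
  action <- character(n)
  reason <- character(n)
  beta_y <- ou$beta
  eaf_y <- ou$eaf %||% rep(NA_real_, n)

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    pal <- is_palindromic(ea_x, oa_x)
    if (pal) {
      fx <- ex$eaf[i]
      if (!is.null(ex$eaf) && !is.na(fx) &&
          fx >= eaf_window[1] && fx <= eaf_window[2]) {
        action[i] <- "dropped"; reason[i] <- "palindromic, ambiguous frequency"
        next
      }
      # palindromic but resolvable: align by frequency
      same <- identical(ea_y, ea_x) && identical(oa_y, oa_x)
      swapped <- identical(ea_y, oa_x) && identical(oa_y, ea_x)
      if (!same && !swapped) {
        action[i] <- "dropped"; reason[i] <- "incompatible alleles"
        next
      }
      fy <- eaf_y[i]
      flip <- if (!is.na(fy) && !is.na(fx))
        (fx - 0.5) * (fy - 0.5) < 0 else swapped
      if (flip) {
        beta_y[i] <- -beta_y[i]
        eaf_y[i] <- 1 - eaf_y[i]
        action[i] <- "flipped"; reason[i] <- "palindromic, frequency-aligned"
      } else action[i] <- "kept"
      next
    }
    match_type <- if (identical(ea_y, ea_x) && identical(oa_y, oa_x)) "same"
    else if (identical(ea_y, oa_x) && identical(oa_y, ea_x)) "swapped"
    else {
      cea <- unname(COMPLEMENT[ea_y]); coa <- unname(COMPLEMENT[oa_y])
      if (identical(cea, ea_x) && identical(coa, oa_x)) "same"
      else if (identical(cea, oa_x) && identical(coa, ea_x)) "swapped"
      else "incompatible"
    }
    if (match_type == "incompatible") {
      action[i] <- "dropped"; reason[i] <- "incompatible alleles"
    } else if (match_type == "swapped") {
      beta_y[i] <- -beta_y[i]
      eaf_y[i] <- 1 - eaf_y[i]
      action[i] <- "flipped"; reason[i] <- "effect/other alleles swapped"
    } else action[i] <- "kept"
  }

  keep <- action != "dropped"
  out <- data.frame(
    variant_id = shared[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_x = ex$beta[keep], se_x = ex$se[keep],
    pval_x = (ex$pval %||% rep(NA_real_, n))[keep],
    beta_y = beta_y[keep], se_y = ou$se[keep],
    eaf = (ex$eaf %||% rep(NA_real_, n))[keep],
    stringsAsFactors = FALSE)
  class(out) <- c("harmonized_stats", "data.frame")
  attr(out, "audit") <- data.frame(variant_id = shared, action = action,
                                   reason = reason, stringsAsFactors = FALSE)
  out
}

#' Pairwise r-squared between dosage columns
#'
#' @param dosages Dosage matrix.
#' @return Symmetric matrix of squared Pearson correlations.
#' @export
ld_matrix <- function(dosages) stats::cor(dosages)^2

#' Greedy LD pruning at an r-squared threshold
#'
#' SNPs are visited in ascending order of exposure p-value; a SNP is kept
#' iff its squared correlation with every already-kept SNP is below the
#' threshold. No retained pair can violate the threshold.
#'
#' @param ids Variant ids.
#' @param pvals Exposure p-values (ordering key).
#' @param r2 Symmetric r-squared matrix with ids as dimnames (or in the
#'   same order as `ids`).
#' @param r2_threshold Retention threshold (default 0.001).
#' @return Character vector of retained ids (in original order).
#' @export
ld_prune <- function(ids, pvals, r2, r2_threshold = 0.001) {
  stopifnot(length(ids) == length(pvals))
  if (!is.null(rownames(r2))) r2 <- r2[ids, ids, drop = FALSE]
  if (anyNA(r2)) stop_mr("missing r-squared entries")
  ord <- order(pvals)
  kept <- integer(0)
  for (i in ord) {
    if (all(r2[i, kept] < r2_threshold)) kept <- c(kept, i)
  }
  ids[sort(kept)]
}

#' Per-SNP Wald ratios from harmonized summary statistics
#'
#' Ratio `beta_y / beta_x` with first-order standard error
#' `se_y / |beta_x|`; optionally the second-order expansion adding
#' `beta_y^2 se_x^2 / beta_x^4` under the square root. SNPs with a zero
#' exposure beta are excluded with a warning.
#'
#' @param stats A `harmonized_stats` data.frame.
#' @param second_order Use the second-order SE (default FALSE).
#' @return A data.frame of class `wald_ratio_set` with columns
#'   `variant_id`, `ratio`, `se`, `weight` (`se^-2`).
#' @export
wald_ratios <- function(stats, second_order = FALSE) {
  zero <- stats$beta_x == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " SNP(s) with zero exposure beta",
            call. = FALSE)
    stats <- stats[!zero, ]
  }
  ratio <- stats$beta_y / stats$beta_x
  se2 <- stats$se_y^2 / stats$beta_x^2
  if (second_order)
    se2 <- se2 + stats$beta_y^2 * stats$se_x^2 / stats$beta_x^4
  out <- data.frame(variant_id = stats$variant_id, ratio = ratio,
                    se = sqrt(se2), weight = 1 / se2,
                    stringsAsFactors = FALSE)
  class(out) <- c("wald_ratio_set", "data.frame")
  out
}

# Closed-form IVW slope (weights 1/se_y^2, regression through the origin).
ivw_closed_form <- function(bx, by, sy) {
  sum(bx * by / sy^2) / sum(bx^2 / sy^2)
}

ivw_q <- function(b, bx, by, sx, sy) {
  sum((by - b * bx)^2 / (sy^2 + b^2 * sx^2))
}

#' Exact-weights inverse-variance-weighted estimator
#'
#' Minimizes `Q(b) = sum_j (beta_yj - b beta_xj)^2 / (se_yj^2 + b^2
#' se_xj^2)` over the causal slope b, letting the weights depend on b
#' itself (which also guards against regression-dilution bias). The
#' optimization is a bracketed 1-D search seeded at the closed-form IVW
#' value; when all exposure SEs are zero the closed form is returned
#' exactly. The fixed-effects SE is `1 / sqrt(sum_j beta_xj^2 w_j(b))`; the
#' random-effects SE multiplies it by `sqrt(max(1, Q / (J - 1)))`.
#'
#' @param stats A `harmonized_stats` data.frame with J >= 2 rows.
#' @param effects_model `"random"` (default) or `"fixed"`.
#' @param tol Optimizer tolerance (default 1e-10 on the slope).
#' @return An `mr_estimate` with extra fields `Q`, `J`, `effects_model`.
#' @export
ivw_exact <- function(stats, effects_model = c("random", "fixed"),
                      tol = 1e-10) {
  effects_model <- match.arg(effects_model)
  J <- nrow(stats)
  if (J < 2) stop_mr("need at least 2 SNPs for IVW")
  bx <- stats$beta_x; by <- stats$beta_y
  sx <- stats$se_x; sy <- stats$se_y
  if (any(sy <= 0)) stop_mr("outcome SEs must be positive")
  b0 <- ivw_closed_form(bx, by, sy)
  if (all(sx == 0)) {
    bhat <- b0
  } else {
    half <- max(1, 20 * abs(b0), 20 / sqrt(sum(bx^2 / sy^2)))
    opt <- stats::optimize(function(b) ivw_q(b, bx, by, sx, sy),
                           interval = c(b0 - half, b0 + half), tol = tol)
    if (abs(opt$minimum - b0) > 0.99 * half)
      stop_mr("exact-weights IVW failed to converge inside the bracket; ",
              "seed = ", signif(b0, 6))
    bhat <- opt$minimum
  }
  w <- 1 / (sy^2 + bhat^2 * sx^2)
  se <- 1 / sqrt(sum(bx^2 * w))
  Q <- ivw_q(bhat, bx, by, sx, sy)
  if (effects_model == "random") se <- se * sqrt(max(1, Q / (J - 1)))
  new_mr_estimate("ivw_exact", bhat, se, n = NA_integer_,
                  extra = list(Q = Q, J = J, effects_model = effects_model))
}

# Orient rows so every exposure beta is positive (outcome beta in tandem).
orient_positive <- function(stats) {
  s <- sign(stats$beta_x)
  s[s == 0] <- 1
  stats$beta_y <- stats$beta_y * s
  stats$beta_x <- abs(stats$beta_x)
  stats
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept, weights `se_y^-2`, after orienting all exposure associations
#' to be positive. The intercept estimates the average directional
#' pleiotropic effect; its test is reported against a t distribution with
#' J - 2 df. Standard errors use multiplicative random effects with the
#' dispersion floored at one (`sqrt(max(1, Q_R / (J - 2)))`).
#'
#' @param stats A `harmonized_stats` data.frame with J >= 3 rows.
#' @return An `mr_estimate` for the slope with extra fields `intercept`,
#'   `intercept_se`, `intercept_p`, `Q_R`, `J`.
#' @export
mr_egger <- function(stats) {
  J <- nrow(stats)
  if (J < 3) stop_mr("need at least 3 SNPs for MR-Egger")
  st <- orient_positive(stats)
  if (stats::var(st$beta_x) == 0)
    stop_mr("slope/intercept not separable: all exposure betas equal")
  w <- 1 / st$se_y^2
  X <- cbind(1, st$beta_x)
  XtW <- t(X * w)
  V <- solve(XtW %*% X)
  coefs <- as.vector(V %*% (XtW %*% st$beta_y))
  resid <- st$beta_y - as.vector(X %*% coefs)
  Q_R <- sum(w * resid^2)
  infl <- sqrt(max(1, Q_R / (J - 2)))
  se <- sqrt(diag(V)) * infl
  int_p <- 2 * stats::pt(-abs(coefs[1] / se[1]), J - 2)
  new_mr_estimate("egger", coefs[2], se[2],
                  extra = list(intercept = coefs[1], intercept_se = se[1],
                               intercept_p = int_p, Q_R = Q_R, J = J))
}

# Weighted median with linear interpolation at cumulative weight 0.5;
# ties in the ratios broken by variant id for determinism.
weighted_median_est <- function(b, w, id = seq_along(b)) {
  ord <- order(b, id)
  b <- b[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (p[1] >= 0.5) return(b[1])
  if (p[length(p)] <= 0.5) return(b[length(b)])
  stats::approx(p, b, xout = 0.5, ties = "ordered")$y
}

#' Penalized weighted median estimator
#'
#' Weighted median of the ordered per-SNP Wald ratios with inverse-variance
#' weights, after down-weighting heterogeneous SNPs: each weight is
#' multiplied by `min(1, penalty * p_j)` where `p_j` is the upper chi-square(1)
#' tail probability of SNP j's Cochran Q contribution at the current
#' estimate. The penalization is iterated to a fixed point (starting from
#' the unpenalized weighted median), which removes the asymmetric
#' down-weighting of valid SNPs that a single penalization pass inherits
#' from a pleiotropy-shifted starting value. The standard error comes from
#' a parametric bootstrap that redraws both beta vectors from their
#' reported sampling distributions.
#'
#' @param stats A `harmonized_stats` data.frame with J >= 3 rows.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param penalty Penalization constant (default 20).
#' @return An `mr_estimate` with extra field `J`.
#' @export
penalized_weighted_median <- function(stats, n_boot = 1000L, seed = 1L,
                                      penalty = 20) {
  J <- nrow(stats)
  if (J < 3) stop_mr("need at least 3 SNPs for the weighted median")
  est_fun <- function(bx, by) {
    b <- by / bx
    w <- bx^2 / stats$se_y^2
    est <- weighted_median_est(b, w, stats$variant_id)
    for (i in 1:10) {
      q <- w * (b - est)^2
      pj <- stats::pchisq(q, df = 1, lower.tail = FALSE)
      wp <- w * pmin(1, penalty * pj)
      if (sum(wp) == 0) stop_mr("total weight zero after penalization")
      new <- weighted_median_est(b, wp, stats$variant_id)
      if (abs(new - est) < 1e-10) {
        est <- new
        break
      }
      est <- new
    }
    est
  }
  est <- est_fun(stats$beta_x, stats$beta_y)
  boot <- with_seed(derive_seed(seed, "pwm_bootstrap"), {
    vapply(seq_len(n_boot), function(i) {
      est_fun(stats::rnorm(J, stats$beta_x, stats$se_x),
              stats::rnorm(J, stats$beta_y, stats$se_y))
    }, numeric(1))
  })
  new_mr_estimate("penalized_weighted_median", est, stats::sd(boot),
                  extra = list(J = J))
}

#' Weighted mode estimator
#'
#' The causal estimate is the maximizer of a normal-kernel weighted density
#' of the per-SNP Wald ratios, with inverse-variance weights and bandwidth
#' `bandwidth_factor` times the modified Silverman scale
#' `0.9 min(sd, mad) J^{-1/5}`. Consistent when the largest homogeneous
#' cluster of SNPs is valid. SE by parametric bootstrap.
#'
#' @param stats A `harmonized_stats` data.frame with J >= 3 rows.
#' @param bandwidth_factor Multiplier on the Silverman bandwidth.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return An `mr_estimate` with extra fields `bandwidth`, `J`.
#' @export
weighted_mode <- function(stats, bandwidth_factor = 1, n_boot = 1000L,
                          seed = 1L) {
  J <- nrow(stats)
  if (J < 3) stop_mr("need at least 3 SNPs for the weighted mode")
  if (bandwidth_factor <= 0) stop_mr("zero bandwidth")
  mode_fun <- function(bx, by) {
    b <- by / bx
    w <- (bx / stats$se_y)^2
    spread <- c(stats::sd(b), stats::mad(b))
    if (all(spread == 0)) # degenerate: every ratio identical
      return(list(est = b[1], h = 0))
    s <- 0.9 * min(spread[spread > 0]) / J^0.2
    h <- bandwidth_factor * s
    if (!is.finite(h) || h <= 0) stop_mr("zero bandwidth")
    grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 2048)
    dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - b) / h)),
                   numeric(1))
    list(est = grid[which.max(dens)], h = h)
  }
  point <- mode_fun(stats$beta_x, stats$beta_y)
  boot <- with_seed(derive_seed(seed, "mode_bootstrap"), {
    vapply(seq_len(n_boot), function(i) {
      mode_fun(stats::rnorm(J, stats$beta_x, stats$se_x),
               stats::rnorm(J, stats$beta_y, stats$se_y))$est
    }, numeric(1))
  })
  new_mr_estimate("weighted_mode", point$est, stats::sd(boot),
                  extra = list(bandwidth = point$h, J = J))
}

#' Multivariable two-sample IVW
#'
#' Weighted least squares of outcome betas on K exposure-beta columns
#' through the origin with weights `se_y^-2`; per-exposure standard errors
#' are inflated by `sqrt(max(1, Q / (J - K)))` (multiplicative random
#' effects).
#'
#' @param beta_x_matrix J x K matrix of exposure betas (one column per
#'   exposure).
#' @param beta_y,se_y Outcome betas and their SEs.
#' @return A named list of `mr_estimate` objects (one per exposure), each
#'   with extra fields `Q`, `J`, `K`.
#' @export
mvmr_ivw_twosample <- function(beta_x_matrix, beta_y, se_y) {
  X <- as.matrix(beta_x_matrix)
  J <- nrow(X); K <- ncol(X)
  if (J <= K) stop_mr("need more SNPs than exposures")
  if (qr(X)$rank < K) stop_mr("collinear exposure beta columns")
  w <- 1 / se_y^2
  XtW <- t(X * w)
  V <- solve(XtW %*% X)
  coefs <- as.vector(V %*% (XtW %*% beta_y))
  Q <- sum(w * (beta_y - as.vector(X %*% coefs))^2)
  infl <- sqrt(max(1, Q / (J - K)))
  se <- sqrt(diag(V)) * infl
  xnames <- colnames(X) %||% paste0("x", seq_len(K))
  out <- lapply(seq_len(K), function(k)
    new_mr_estimate("mvmr_ivw", coefs[k], se[k], exposure = xnames[k],
                    extra = list(Q = Q, J = J, K = K)))
  names(out) <- xnames
  out
}
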