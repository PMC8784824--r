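#' Cochran's Q heterogeneity statistic for per-SNP Wald ratios
#'
#' `Q = sum_j (beta_xj^2 / se_yj^2) (ratio_j - beta_ref)^2`, equivalently
#' the weighted residual sum of squares of the outcome betas around the
#' fitted slope `beta_ref` with weights `se_y^-2`. Compared against a
#' chi-squared distribution with J - 1 degrees of freedom.
#'
#' @param stats A `harmonized_stats` data.frame (J >= 2 rows).
#' @param beta_ref Reference slope; defaults to the exact-weights IVW
#'   estimate.
#' @return A list of class `heterogeneity_q` with `Q`, `df`, `p_value`,
#'   `beta_ref` and per-SNP `contributions` (named, summing to `Q`).
#' @export
cochran_q <- function(stats, beta_ref = NULL) {
  J <- nrow(stats)
  if (J < 2) stop_mr("need at least 2 SNPs for Cochran's Q")
  if (is.null(beta_ref)) beta_ref <- ivw_exact(stats)$estimate
  contrib <- (stats$beta_y - beta_ref * stats$beta_x)^2 / stats$se_y^2
  names(contrib) <- stats$variant_id
  out <- list(Q = sum(contrib), df = J - 1L,
              p_value = stats::pchisq(sum(contrib), J - 1L,
                                      lower.tail = FALSE),
              beta_ref = beta_ref, contributions = contrib)
  class(out) <- "heterogeneity_q"
  out
}

#' Rucker's Q' heterogeneity statistic under the MR-Egger model
#'
#' Residual heterogeneity after adjusting for the mean pleiotropic effect:
#' `Q' = sum_j se_yj^-2 (beta_yj - b0 - b1 beta_xj)^2` at the Egger
#' intercept and slope, compared against chi-squared with J - 2 df. Because
#' the Egger fit nests the origin-constrained IVW fit, `Q' <= Q` always
#' when both are evaluated at their own minimizers.
#'
#' @param stats A `harmonized_stats` data.frame (J >= 3 rows).
#' @param egger_fit Optional result of [mr_egger()] on the same data.
#' @return A list of class `heterogeneity_q` with `Q`, `df`, `p_value` and
#'   per-SNP `contributions`.
#' @export
rucker_q <- function(stats, egger_fit = NULL) {
  J <- nrow(stats)
  if (J < 3) stop_mr("need at least 3 SNPs for Rucker's Q'")
  if (is.null(egger_fit)) egger_fit <- mr_egger(stats)
  st <- orient_positive(stats)
  resid <- st$beta_y - egger_fit$intercept - egger_fit$estimate * st$beta_x
  contrib <- resid^2 / st$se_y^2
  names(contrib) <- st$variant_id
  out <- list(Q = sum(contrib), df = J - 2L,
              p_value = stats::pchisq(sum(contrib), J - 2L,
                                      lower.tail = FALSE),
              beta_ref = egger_fit$estimate, contributions = contrib)
  class(out) <- "heterogeneity_q"
  out
}

#' @export
print.heterogeneity_q <- function(x, ...) {
  cat(sprintf("Q = %.3f on %d df (p = %.3g)\n", x$Q, x$df, x$p_value))
  invisible(x)
}

#' Leave-one-out outlier screening
#'
#' Recomputes the exact-weights IVW estimate, Cochran's Q and Rucker's Q'
#' with each SNP removed in turn, ranks SNPs by their Q contribution, and
#' flags candidates for a sensitivity rerun by a reproducible rule:
#' Q-contribution p-value below a Bonferroni-adjusted threshold, with an
#' optional top-k override.
#'
#' @param stats A `harmonized_stats` data.frame (J >= 3 rows).
#' @param p_threshold Per-family flagging level before Bonferroni
#'   adjustment (default 0.05).
#' @param top_k If given, flag the k largest Q contributors instead.
#' @return A data.frame of class `loo_table` with one row per SNP:
#'   `variant_id`, `estimate_loo` (IVW without that SNP), `delta_estimate`,
#'   `q_contribution`, `q_c_loo`, `q_r_loo`, `flagged`; attribute `full`
#'   holds the all-SNP estimate and Q statistics.
#' @export
leave_one_out <- function(stats, p_threshold = 0.05, top_k = NULL) {
  J <- nrow(stats)
  if (J < 3) stop_mr("need at least 3 SNPs for leave-one-out screening")
  full_ivw <- ivw_exact(stats)
  full_qc <- cochran_q(stats, full_ivw$estimate)
  full_qr <- rucker_q(stats)
  est <- qc <- qr_ <- numeric(J)
  for (j in seq_len(J)) {
    sub <- stats[-j, ]
    e <- ivw_exact(sub)
    est[j] <- e$estimate
    qc[j] <- cochran_q(sub, e$estimate)$Q
    qr_[j] <- if (J - 1 >= 3) rucker_q(sub)$Q else NA_real_
  }
  contrib <- full_qc$contributions
  pj <- stats::pchisq(contrib, df = 1, lower.tail = FALSE)
  flagged <- if (is.null(top_k)) pj < p_threshold / J
  else rank(-contrib, ties.method = "first") <= top_k
  out <- data.frame(variant_id = stats$variant_id,
                    estimate_loo = est,
                    delta_estimate = est - full_ivw$estimate,
                    q_contribution = unname(contrib),
                    q_c_loo = qc, q_r_loo = qr_,
                    flagged = flagged,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$q_contribution), ]
  class(out) <- c("loo_table", "data.frame")
  attr(out, "full") <- list(estimate = full_ivw$estimate, Q_C = full_qc$Q,
                            Q_R = full_qr$Q)
  out
}
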