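#' Orient variant weights to the exposure-increasing allele
#'
#' For each variant with a negative weight, the effect and other alleles are
#' swapped, the weight negated and, when present, the effect-allele
#' frequency replaced by its complement, so that every weight refers to the
#' exposure-increasing allele. The operation is idempotent.
#'
#' @param weights A data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `weight` and optionally `eaf`.
#' @return The oriented table (all weights strictly positive).
#' @export
orient_weights <- function(weights) {
  req <- c("variant_id", "effect_allele", "other_allele", "weight")
  if (!all(req %in% names(weights)))
    stop_mr("weights table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(weights$variant_id))
    stop_mr("variant ids must be unique")
  if (any(weights$weight == 0))
    stop_mr("zero weight for variant(s) ",
            paste(weights$variant_id[weights$weight == 0], collapse = ", "),
            ": no exposure-increasing allele defined")
  flip <- weights$weight < 0
  if (any(flip)) {
    ea <- weights$effect_allele[flip]
    weights$effect_allele[flip] <- weights$other_allele[flip]
    weights$other_allele[flip] <- ea
    weights$weight[flip] <- -weights$weight[flip]
    if ("eaf" %in% names(weights))
      weights$eaf[flip] <- 1 - weights$eaf[flip]
  }
  weights
}

#' Compute a weighted genetic risk score
#'
#' The score is the weighted sum of effect-allele dosages divided by the sum
#' of the weights, i.e. an estimate of the average number of
#' exposure-increasing alleles per participant: `G_i = sum_j w_j d_ij /
#' sum_j w_j`. It is invariant under positive rescaling of all weights and
#' lies in \[0, 2\] whenever dosages do.
#'
#' @param dosages Dosage matrix with variant ids as column names.
#' @param weights An oriented weight table (see [orient_weights()]).
#' @return Numeric vector of per-participant scores.
#' @export
compute_grs <- function(dosages, weights) {
  weights <- orient_weights(weights)
  missing_ids <- setdiff(weights$variant_id, colnames(dosages))
  if (length(missing_ids) > 0)
    stop_mr("dosage columns missing for variant(s): ",
            paste(missing_ids, collapse = ", "))
  D <- dosages[, weights$variant_id, drop = FALSE]
  if (anyNA(D))
    stop_mr("missing dosage values; exclude incomplete participants ",
            "rather than imputing")
  as.vector(D %*% weights$weight) / sum(weights$weight)
}

#' First-stage regression of an exposure on a genetic risk score
#'
#' Ordinary least squares of the exposure on the score (plus optional
#' covariates). Reports the score coefficient, its standard error, the
#' instrument's partial R-squared and partial F statistic. For a single
#' unadjusted regressor the F statistic equals `(n - 2) R^2 / (1 - R^2)`
#' exactly.
#'
#' @param exposure Numeric exposure vector.
#' @param grs Numeric score vector from [compute_grs()].
#' @param covariates Optional data.frame/matrix of covariates.
#' @return An object of class `first_stage_fit`: list with `beta_exp`,
#'   `se_exp`, `r_squared` (partial, for the score), `f_statistic`
#'   (partial F), `n`, `df_residual`, `covariates`.
#' @export
fit_first_stage <- function(exposure, grs, covariates = NULL) {
  n <- length(exposure)
  stopifnot(length(grs) == n)
  CV <- NULL
  if (!is.null(covariates)) {
    CV <- as.matrix(covariates)
    qrc <- qr(cbind(1, CV))
    if (qrc$rank < ncol(CV) + 1) {
      drop_idx <- qrc$pivot[(qrc$rank + 1):(ncol(CV) + 1)] - 1L
      drop_idx <- drop_idx[drop_idx > 0]
      stop_mr("collinear covariates: ",
              paste(colnames(CV)[drop_idx], collapse = ", "))
    }
  }
  X1 <- cbind(`(Intercept)` = rep(1, n), grs = grs, CV)
  if (n <= ncol(X1)) stop_mr("too few observations for the first stage")
  q1 <- qr(X1)
  coefs <- qr.coef(q1, exposure)
  res1 <- qr.resid(q1, exposure)
  rss1 <- sum(res1^2)
  df1 <- n - ncol(X1)
  X0 <- cbind(rep(1, n), CV)
  rss0 <- sum(qr.resid(qr(X0), exposure)^2)
  r2 <- (rss0 - rss1) / rss0
  fstat <- (rss0 - rss1) / (rss1 / df1)
  XtXinv <- chol2inv(qr.R(q1))[order(q1$pivot), order(q1$pivot), drop = FALSE]
  se <- sqrt(rss1 / df1 * XtXinv[2L, 2L])
  out <- list(beta_exp = unname(coefs["grs"]), se_exp = se,
              r_squared = r2, f_statistic = fstat,
              n = n, df_residual = df1,
              covariates = colnames(CV) %||% character(0))
  class(out) <- "first_stage_fit"
  out
}

#' @export
print.first_stage_fit <- function(x, ...) {
  cat(sprintf(
    "First stage: beta = %.4g (SE %.3g), partial R2 = %.4g%%, F = %.4g, n = %d\n",
    x$beta_exp, x$se_exp, 100 * x$r_squared, x$f_statistic, x$n))
  invisible(x)
}

#' First-stage F statistic from a reported R-squared and sample size
#'
#' Convenience helper for the single-instrument identity
#' `F = (n - 2) R^2 / (1 - R^2)`.
#'
#' @param r_squared Instrument R-squared (proportion, not percent).
#' @param n Sample size.
#' @return The implied F statistic.
#' @export
f_from_r2 <- function(r_squared, n) {
  stopifnot(r_squared >= 0, r_squared < 1, n > 2)
  (n - 2) * r_squared / (1 - r_squared)
}

#' Conditional Sanderson-Windmeijer F statistics for multivariable MR
#'
#' Quantifies the instrument strength available for each exposure after
#' conditioning on the other exposures. For exposure k: (1) every other
#' exposure is regressed on the full instrument set and its fitted values
#' retained; (2) exposure k is regressed on those fitted values and the
#' residuals taken; (3) the residuals are regressed on the instruments and
#' the regression F statistic computed with residual degrees of freedom
#' `n - J - (K - 1) - 1` (J instruments, K exposures).
#'
#' @param exposures Matrix or data.frame with K >= 2 exposure columns.
#' @param dosages Instrument (dosage) matrix with J >= K columns.
#' @return Named numeric vector of conditional F statistics.
#' @export
conditional_sw_f <- function(exposures, dosages) {
  X <- as.matrix(exposures)
  Z <- as.matrix(dosages)
  K <- ncol(X)
  J <- ncol(Z)
  n <- nrow(X)
  if (K < 2) stop_mr("need at least two exposures")
  if (J < K) stop_mr("not identified: fewer instruments than exposures")
  qz <- qr(cbind(1, Z))
  fitted_all <- X - qr.resid(qz, X) # instrumented component of each exposure
  out <- stats::setNames(numeric(K), colnames(X) %||% paste0("x", seq_len(K)))
  df <- n - J - (K - 1) - 1
  for (k in seq_len(K)) {
    Fhat <- fitted_all[, -k, drop = FALSE]
    e <- qr.resid(qr(cbind(1, Fhat)), X[, k])
    res <- qr.resid(qz, e)
    ess <- sum(e^2) - sum(res^2)
    out[k] <- (ess / J) / (sum(res^2) / df)
  }
  out
}
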