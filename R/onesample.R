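new_mr_estimate <- function(method, estimate, se, n = NA_integer_,
                            exposure = NA_character_, level = 0.95,
                            extra = list()) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- c(list(method = method, exposure = exposure,
                estimate = estimate, se = se,
                rate_ratio = exp(estimate),
                ci_low = exp(estimate - z * se),
                ci_high = exp(estimate + z * se),
                n = n), extra)
  class(out) <- "mr_estimate"
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: log-rate coef %.4g (SE %.3g); rate ratio %.4g [%.4g, %.4g]\n",
              x$method, x$estimate, x$se, x$rate_ratio, x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, exposure = x$exposure,
             estimate = x$estimate, se = x$se, rate_ratio = x$rate_ratio,
             ci_low = x$ci_low, ci_high = x$ci_high, n = x$n,
             stringsAsFactors = FALSE)
}

#' Report an MR estimate on another exposure scale
#'
#' @param x An `mr_estimate` (per exposure unit).
#' @param scale Units per reporting step (e.g. the exposure SD).
#' @return A new `mr_estimate` on the requested scale.
#' @export
scale_mr_estimate <- function(x, scale) {
  stopifnot(inherits(x, "mr_estimate"))
  sc <- rate_per_sd(x$estimate, x$se, scale)
  out <- x
  out$estimate <- sc$estimate
  out$se <- sc$se
  out$rate_ratio <- sc$rate_ratio
  out$ci_low <- sc$ci_low
  out$ci_high <- sc$ci_high
  out
}

#' Second-stage quasi-Poisson regression of counts on a risk score
#'
#' The gene-outcome association of the one-sample design: quasi-Poisson GLM
#' of admission counts on the genetic risk score (plus covariates) with a
#' log person-years offset.
#'
#' @inheritParams fit_quasipoisson
#' @param grs Genetic risk score vector from [compute_grs()].
#' @return An object of class `second_stage_fit`: list with `beta_out`,
#'   `se_out`, `dispersion`, `n`, and the full `quasipois_fit`.
#' @export
fit_second_stage <- function(counts, grs, person_years, covariates = NULL) {
  fit <- fit_quasipoisson(counts, data.frame(grs = grs), person_years,
                          covariates)
  out <- list(beta_out = unname(fit$coefficients["grs"]),
              se_out = unname(fit$se["grs"]),
              dispersion = fit$dispersion, n = fit$n, fit = fit)
  class(out) <- "second_stage_fit"
  out
}

#' @export
print.second_stage_fit <- function(x, ...) {
  cat(sprintf("Second stage: beta_out = %.4g (SE %.3g), dispersion %.3f, n = %d\n",
              x$beta_out, x$se_out, x$dispersion, x$n))
  invisible(x)
}

#' One-sample Wald-ratio instrumental-variable estimate
#'
#' The causal log-rate coefficient per exposure unit is the ratio of the
#' second-stage (gene-outcome) to first-stage (gene-exposure) coefficients;
#' its exponent is the admission rate ratio per exposure unit. The standard
#' error uses the first-order Taylor (delta-method) expansion treating the
#' two stages as uncorrelated:
#' `se^2 = se_out^2 / beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4`.
#'
#' @param first A `first_stage_fit`, or a list with `beta_exp` and `se_exp`
#'   (use `se_exp = 0` for an external weight treated as fixed).
#' @param second A `second_stage_fit`.
#' @param weak_f_threshold Warn when the first-stage F (squared t statistic)
#'   falls below this value (default 10).
#' @param exposure Optional exposure label.
#' @return An `mr_estimate` (per exposure unit) with extra fields
#'   `beta_exp`, `beta_out`.
#' @export
wald_iv <- function(first, second, weak_f_threshold = 10,
                    exposure = NA_character_) {
  be <- first$beta_exp
  se_e <- first$se_exp %||% 0
  if (is.null(be) || be == 0) stop_mr("irrelevant instrument: beta_exp is zero")
  if (se_e > 0 && (be / se_e)^2 < weak_f_threshold)
    warning(sprintf("weak instrument: first-stage F = %.2f < %.1f",
                    (be / se_e)^2, weak_f_threshold), call. = FALSE)
  bo <- second$beta_out
  so <- second$se_out
  est <- bo / be
  se <- sqrt(so^2 / be^2 + bo^2 * se_e^2 / be^4)
  new_mr_estimate("wald_iv", est, se, n = second$n, exposure = exposure,
                  extra = list(beta_exp = be, beta_out = bo))
}

#' Residual-adjusted secondary exposure
#'
#' Returns the residuals of an ordinary least squares regression (with
#' intercept) of the secondary exposure on the primary one — e.g. WHR
#' adjusted for BMI — which have exactly zero sample correlation with the
#' primary exposure.
#'
#' @param secondary,primary Numeric vectors of equal length, no missing
#'   values.
#' @return The residual exposure vector.
#' @export
residual_exposure <- function(secondary, primary) {
  if (length(secondary) != length(primary))
    stop_mr("exposure vectors must have equal length")
  if (anyNA(secondary) || anyNA(primary))
    stop_mr("exposure vectors must be complete")
  if (stats::var(primary) == 0) stop_mr("primary exposure is constant")
  stats::lm.fit(cbind(1, primary), secondary)$residuals
}

#' Multivariable one-sample MR with bootstrap confidence intervals
#'
#' Stage one regresses each exposure on the full instrument set (plus
#' covariates) by OLS; stage two is a quasi-Poisson regression of admission
#' counts on the K fitted-value columns (plus covariates) with a log
#' person-years offset. Standard errors and percentile intervals come from
#' a full-sample nonparametric bootstrap of both stages; normal-theory
#' intervals from the bootstrap SE are also returned.
#'
#' @param counts Admission counts.
#' @param person_years Follow-up times.
#' @param exposures Data.frame/matrix with K >= 2 exposure columns.
#' @param dosages Instrument matrix (full combined SNP set).
#' @param covariates Optional covariates included in both stages.
#' @param n_boot Number of bootstrap replicates (default 10000; reduce for
#'   exploratory runs).
#' @param seed Integer seed for the bootstrap resampling.
#' @return A list of `mr_estimate` objects, one per exposure, each with
#'   extra fields `ci_low_perc`, `ci_high_perc` (percentile interval) and
#'   `conditional_f`; plus attribute `conditional_f` for the whole fit.
#' @export
mvmr_onesample <- function(counts, person_years, exposures, dosages,
                           covariates = NULL, n_boot = 10000L, seed = 1L) {
  check_counts(counts)
  check_offset(person_years)
  X <- as.matrix(exposures)
  Z <- as.matrix(dosages)
  K <- ncol(X)
  n <- nrow(X)
  if (n_boot < 100) stop_mr("n_boot must be at least 100")
  CV <- if (is.null(covariates)) NULL else as.matrix(covariates)
  xnames <- colnames(X) %||% paste0("x", seq_len(K))
  off <- log(person_years)

  two_stage <- function(rows) {
    Zr <- cbind(1, Z[rows, , drop = FALSE], CV[rows, , drop = FALSE])
    fitted <- X[rows, , drop = FALSE] -
      qr.resid(qr(Zr), X[rows, , drop = FALSE])
    D2 <- cbind(1, fitted, CV[rows, , drop = FALSE])
    if (qr(D2)$rank < ncol(D2))
      stop_mr("exposures not separately identified: ",
              "fitted-value columns are collinear")
    fit <- suppressWarnings(
      stats::glm.fit(D2, counts[rows], family = stats::poisson(),
                     offset = off[rows]))
    fit$coefficients[2:(K + 1)]
  }

  point <- two_stage(seq_len(n))
  swf <- conditional_sw_f(X, Z)
  boot <- matrix(NA_real_, n_boot, K)
  with_seed(derive_seed(seed, "mvmr_bootstrap"), {
    for (b in seq_len(n_boot)) {
      rows <- sample.int(n, n, replace = TRUE)
      boot[b, ] <- tryCatch(two_stage(rows), error = function(e) rep(NA, K))
    }
  })
  out <- lapply(seq_len(K), function(k) {
    bk <- boot[, k][!is.na(boot[, k])]
    est <- new_mr_estimate("mvmr_onesample", unname(point[k]),
                           stats::sd(bk), n = n, exposure = xnames[k],
                           extra = list(
                             ci_low_perc = exp(stats::quantile(bk, 0.025,
                                                               names = FALSE)),
                             ci_high_perc = exp(stats::quantile(bk, 0.975,
                                                                names = FALSE)),
                             conditional_f = unname(swf[k]),
                             n_boot = length(bk)))
    est
  })
  names(out) <- xnames
  attr(out, "conditional_f") <- swf
  out
}
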