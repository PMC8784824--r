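#' Per-SNP marginal association statistics from an individual-level cohort
#'
#' Computes GWAS-style summary statistics for every SNP in the cohort:
#' ordinary least squares for a continuous exposure, or quasi-Poisson
#' regression of admission counts with a log person-years offset for the
#' outcome. Covariates, when given, are included in each per-SNP model.
#' SNPs with zero dosage variance are omitted with a warning.
#'
#' @param cohort An `mr_cohort` from [simulate_cohort()].
#' @param which `"exposure"` (linear model) or `"outcome"` (quasi-Poisson
#'   rate model).
#' @param exposure Exposure column name used when `which = "exposure"`.
#' @param covariates Optional character vector of covariate columns in
#'   `cohort$data`.
#' @param snps Optional subset of variant ids (default: all).
#' @return A data.frame of class `summary_stats_table` with columns
#'   `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`,
#'   `eaf`, `n`. Outcome betas are on the log admission rate scale per
#'   effect allele.
#' @export
generate_summary_stats <- function(cohort,
                                   which = c("exposure", "outcome"),
                                   exposure = "bmi",
                                   covariates = NULL,
                                   snps = NULL) {
  stopifnot(inherits(cohort, "mr_cohort"))
  which <- match.arg(which)
  dos <- cohort$dosages
  ids <- snps %||% colnames(dos)
  missing_ids <- setdiff(ids, colnames(dos))
  if (length(missing_ids) > 0)
    stop_mr("unknown variant ids: ", paste(missing_ids, collapse = ", "))
  D <- dos[, ids, drop = FALSE]
  n <- nrow(D)
  keep <- apply(D, 2, stats::var) > 0
  if (any(!keep)) {
    warning("omitting ", sum(!keep), " constant dosage column(s): ",
            paste(ids[!keep], collapse = ", "), call. = FALSE)
    D <- D[, keep, drop = FALSE]
    ids <- ids[keep]
  }
  if (length(ids) == 0) stop_mr("no variable SNPs left")
  eaf <- colMeans(D) / 2
  CV <- NULL
  if (!is.null(covariates))
    CV <- as.matrix(cohort$data[, covariates, drop = FALSE])

  if (which == "exposure") {
    y <- cohort$data[[exposure]]
    base <- cbind(`(Intercept)` = rep(1, n), CV)
    qrb <- qr(base)
    ry <- qr.resid(qrb, y)
    RD <- qr.resid(qrb, D)
    df <- n - ncol(base) - 1L
    sdd <- colSums(RD^2)
    sdy <- colSums(RD * ry)
    beta <- sdy / sdd
    rss <- sum(ry^2) - beta * sdy
    se <- sqrt(pmax(rss, 0) / df / sdd)
    tval <- beta / se
    pval <- 2 * stats::pt(-abs(tval), df)
  } else {
    y <- check_counts(cohort$data$admissions)
    off <- log(check_offset(cohort$data$person_years))
    beta <- se <- pval <- numeric(length(ids))
    for (j in seq_along(ids)) {
      X <- cbind(`(Intercept)` = rep(1, n), snp = D[, j], CV)
      fit <- stats::glm.fit(X, y, family = stats::poisson(), offset = off)
      mu <- fit$fitted.values
      p <- ncol(X)
      disp <- sum((y - mu)^2 / mu) / (n - p)
      vc <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
      beta[j] <- fit$coefficients[2L]
      se[j] <- sqrt(disp * vc[2L, 2L])
      pval[j] <- 2 * stats::pt(-abs(beta[j] / se[j]), n - p)
    }
  }
  out <- data.frame(
    variant_id = ids,
    effect_allele = unname(attr(dos, "effect_allele")[ids]),
    other_allele = unname(attr(dos, "other_allele")[ids]),
    beta = unname(beta), se = unname(se), pval = unname(pval),
    eaf = unname(eaf), n = n,
    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats_table", "data.frame")
  out
}

#' Simulate harmonized two-sample summary statistics directly
#'
#' Summary-level generator for testing and calibrating the two-sample
#' estimators without building an individual-level cohort. True per-allele
#' exposure effects `w_j` are drawn uniformly; observed exposure betas add
#' `N(0, se_x^2)` noise and outcome betas follow
#' `beta_y = b * w_j + alpha_j + N(0, se_y^2)` where `alpha_j` are direct
#' (pleiotropic) effects.
#'
#' @param J Number of SNPs.
#' @param b True causal slope (log-rate units per exposure unit).
#' @param w_range Range of true per-allele exposure effects.
#' @param se_x,se_y Standard errors of the exposure and outcome betas
#'   (recycled to length `J`).
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_mean,pleiotropy_sd Direct-effect moments.
#' @param prop_invalid Fraction of SNPs receiving a direct effect (the rest
#'   stay valid); 1 means all.
#' @param seed Integer seed.
#' @return A data.frame of class `harmonized_stats` with columns
#'   `variant_id`, `effect_allele`, `other_allele`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y`, `eaf`, plus attribute `truth` (list with `b`, `w`,
#'   `alpha`).
#' @export
sim_summary_mr <- function(J, b,
                           w_range = c(0.05, 0.25),
                           se_x = 0.01, se_y = 0.05,
                           pleiotropy = c("none", "balanced", "directional"),
                           pleiotropy_mean = 0, pleiotropy_sd = 0.02,
                           prop_invalid = 1,
                           seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  se_x <- rep_len(se_x, J)
  se_y <- rep_len(se_y, J)
  with_seed(derive_seed(seed, "summary_mr"), {
    w <- stats::runif(J, w_range[1], w_range[2])
    alpha <- rep(0, J)
    if (pleiotropy != "none") {
      mu <- if (pleiotropy == "balanced") 0 else pleiotropy_mean
      inv <- seq_len(max(0L, round(prop_invalid * J)))
      alpha[inv] <- stats::rnorm(length(inv), mu, pleiotropy_sd)
    }
    out <- data.frame(
      variant_id = sprintf("rs%04d", seq_len(J)),
      effect_allele = "A", other_allele = "G",
      beta_x = w + stats::rnorm(J, 0, se_x),
      se_x = se_x,
      beta_y = b * w + alpha + stats::rnorm(J, 0, se_y),
      se_y = se_y,
      eaf = stats::runif(J, 0.1, 0.9),
      stringsAsFactors = FALSE)
    class(out) <- c("harmonized_stats", "data.frame")
    attr(out, "truth") <- list(b = b, w = w, alpha = alpha)
    out
  })
}
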