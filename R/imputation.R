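#' Multiple imputation by multivariate-normal predictive draws
#'
#' Completes missing covariate cells m times under a joint-normal working
#' model estimated from the complete cases: for each incomplete row the
#' missing entries are drawn from their conditional normal distribution
#' given the observed entries. Factor columns are handled on an underlying
#' integer scale and mapped back to the nearest level, which is documented
#' as approximate. Observed cells are never altered; the scheme assumes
#' missingness at random given the included columns.
#'
#' @param table A data.frame; only numeric and factor columns may contain
#'   missing values.
#' @param m Number of completed copies (default 10).
#' @param seed Integer seed.
#' @return A list of `m` completed data.frames. With no missing cells the
#'   list holds `m` identical copies of the input.
#' @export
impute_missing <- function(table, m = 10L, seed = 1L) {
  stopifnot(is.data.frame(table), m >= 1)
  is_fac <- vapply(table, is.factor, logical(1))
  num <- table
  for (j in which(is_fac)) num[[j]] <- as.numeric(table[[j]])
  is_num <- vapply(num, is.numeric, logical(1))
  bad <- !is_num & vapply(num, anyNA, logical(1))
  if (any(bad))
    stop_mr("non-numeric, non-factor column(s) with missing values: ",
            paste(names(num)[bad], collapse = ", "))
  M <- as.matrix(num[, is_num, drop = FALSE])
  miss <- is.na(M)
  frac <- colMeans(miss)
  if (any(frac == 1))
    stop_mr("column(s) entirely missing: ",
            paste(colnames(M)[frac == 1], collapse = ", "))
  if (any(frac > 0.5))
    warning("column(s) with >50% missing: ",
            paste(colnames(M)[frac > 0.5], collapse = ", "), call. = FALSE)
  if (!any(miss)) return(replicate(m, table, simplify = FALSE))

  cc <- stats::complete.cases(M)
  if (sum(cc) < ncol(M) + 2)
    stop_mr("too few complete cases to estimate the working model")
  mu <- colMeans(M[cc, , drop = FALSE])
  Sigma <- stats::cov(M[cc, , drop = FALSE])
  # ridge for numerically singular covariance (e.g. collinear columns)
  eps <- 1e-10 * mean(diag(Sigma))
  rows <- which(rowSums(miss) > 0)

  with_seed(derive_seed(seed, "imputation"), {
    lapply(seq_len(m), function(rep) {
      Mi <- M
      for (i in rows) {
        mis <- miss[i, ]
        obs <- !mis
        S_oo <- Sigma[obs, obs, drop = FALSE] + diag(eps, sum(obs))
        S_mo <- Sigma[mis, obs, drop = FALSE]
        A <- S_mo %*% solve(S_oo)
        cmu <- mu[mis] + as.vector(A %*% (M[i, obs] - mu[obs]))
        cS <- Sigma[mis, mis, drop = FALSE] - A %*% t(S_mo)
        cS <- (cS + t(cS)) / 2
        ev <- eigen(cS, symmetric = TRUE)
        L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(cmu))
        Mi[i, mis] <- cmu + as.vector(L %*% stats::rnorm(length(cmu)))
      }
      out <- table
      k <- 0
      for (j in which(is_num)) {
        k <- k + 1
        col <- Mi[, k]
        if (is_fac[j]) {
          lev <- levels(table[[j]])
          idx <- pmin(pmax(round(col), 1), length(lev))
          out[[j]] <- factor(lev[idx], levels = lev)
        } else {
          out[[j]] <- col
        }
      }
      out
    })
  })
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Pooled estimate = mean of the per-imputation estimates; within-imputation
#' variance W = mean squared SE; between-imputation variance B = sample
#' variance of the estimates; total variance T = W + (1 + 1/m) B.
#'
#' @param estimates An m x p matrix (or list of `quasipois_fit` objects) of
#'   per-imputation coefficient estimates.
#' @param ses Matching m x p matrix of standard errors (ignored when a list
#'   of fits is supplied).
#' @return An object of class `pooled_fit`: list with `estimate`, `W`, `B`,
#'   `total_variance`, `se`, `df` (Rubin small-sample df), `m`.
#' @export
pool_rubin <- function(estimates, ses = NULL) {
  if (is.list(estimates) && !is.data.frame(estimates) &&
      !is.matrix(estimates)) {
    fits <- estimates
    if (length(fits) < 2) stop_mr("need at least 2 imputations to pool")
    layouts <- lapply(fits, function(f) names(f$coefficients))
    if (!all(vapply(layouts, identical, logical(1), y = layouts[[1]])))
      stop_mr("mismatched coefficient layouts across imputations")
    estimates <- do.call(rbind, lapply(fits, function(f) f$coefficients))
    ses <- do.call(rbind, lapply(fits, function(f) f$se))
  }
  estimates <- as.matrix(estimates)
  ses <- as.matrix(ses)
  if (!identical(dim(estimates), dim(ses)))
    stop_mr("estimates and ses must have identical layout")
  m <- nrow(estimates)
  if (m < 2) stop_mr("need at least 2 imputations to pool")
  est <- colMeans(estimates)
  W <- colMeans(ses^2)
  B <- apply(estimates, 2, stats::var)
  total <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  out <- list(estimate = est, W = W, B = B, total_variance = total,
              se = sqrt(total), df = df, m = m)
  class(out) <- "pooled_fit"
  out
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimates over m = %d imputations\n", x$m))
  print(data.frame(estimate = x$estimate, se = x$se, df = round(x$df, 1)),
        digits = 4)
  invisible(x)
}
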