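#' Build a pipeline run configuration
#'
#' Declarative configuration for [run_pipeline()]: which stages to run,
#' the synthetic-cohort block, analysis options and the root seed. Every
#' stochastic stage derives its own sub-seed from the root seed via
#' [derive_seed()], and the derivations are recorded in the run log.
#'
#' @param stages Character vector from `c("simulate", "grs",
#'   "observational", "onesample", "twosample", "mvmr")`.
#' @param sim Named list of [sim_config()] arguments. The demo default is a
#'   deliberately desk-sized cohort (n = 20000, 60 SNPs).
#' @param covariates Covariate columns used for adjustment (default age and
#'   sex).
#' @param n_boot Bootstrap replicates for the multivariable one-sample
#'   stage (default 200 at demo scale; the full-scale analysis convention
#'   is 10000).
#' @param two_sample_fraction Fraction of the cohort used for the exposure
#'   associations in the two-sample split.
#' @param r2_threshold LD pruning threshold (default 0.001).
#' @param seed Root seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(stages = c("simulate", "grs", "observational",
                                  "onesample", "twosample", "mvmr"),
                       sim = list(n_participants = 20000L,
                                  n_snps_bmi = 40L, n_snps_whr = 20L),
                       covariates = c("age", "sex"),
                       n_boot = 200L,
                       two_sample_fraction = 0.5,
                       r2_threshold = 0.001,
                       seed = 1L) {
  known <- c("simulate", "grs", "observational", "onesample", "twosample",
             "mvmr")
  if (!all(stages %in% known))
    stop_mr("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  out <- list(stages = stages, sim = sim, covariates = covariates,
              n_boot = as.integer(n_boot),
              two_sample_fraction = two_sample_fraction,
              r2_threshold = r2_threshold, seed = as.integer(seed))
  class(out) <- "run_config"
  out
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

results_row <- function(analysis, exposure, method, scale, est, log = NULL,
                        n = NA, f_stat = NA, phi = NA, q_c = NA, q_r = NA,
                        j_snps = NA) {
  data.frame(analysis = analysis, exposure = exposure, method = method,
             scale = scale, estimate = est$rate_ratio,
             ci_low = est$ci_low, ci_high = est$ci_high,
             n = n, f_stat = f_stat, phi = phi, q_c = q_c, q_r = q_r,
             j_snps = j_snps, stringsAsFactors = FALSE)
}

#' Run the full simulation-to-report pipeline
#'
#' Executes the declared stages in dependency order on one synthetic
#' cohort: simulate, genetic risk scores and first stages, observational
#' quasi-Poisson benchmarks, one-sample Wald-ratio MR (including the
#' residual-adjusted WHR exposure), two-sample summary MR with all four
#' estimators and heterogeneity statistics, and multivariable MR (one- and
#' two-sample). Identical configuration and seed give an identical results
#' table.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result` with `results` (the results
#'   table: analysis, exposure, method, scale, estimate and 95% CI on the
#'   rate scale, n, diagnostics), `cohort`, and `log` (character vector of
#'   run records).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  stages <- config$stages
  rows <- list()

  sim_args <- config$sim
  if (is.null(sim_args$seed))
    sim_args$seed <- derive_seed(config$seed, "simulate")
  scfg <- do.call(sim_config, sim_args)
  note("simulate: n = %d, snps = %d + %d, seed = %d", scfg$n_participants,
       scfg$n_snps_bmi, scfg$n_snps_whr, scfg$seed)
  cohort <- simulate_cohort(scfg)
  dat <- cohort$data
  note("simulate: mean admissions %.3f, mean person-years %.3f",
       mean(dat$admissions), mean(dat$person_years))
  if (identical(stages, "simulate")) {
    out <- list(results = NULL, cohort = cohort, log = log)
    class(out) <- "pipeline_result"
    return(out)
  }

  CV <- dat[, config$covariates, drop = FALSE]
  sds <- c(bmi = stats::sd(dat$bmi), whr = stats::sd(dat$whr))
  scales <- list(bmi = c(unit = 1, sd = sds[["bmi"]]),
                 whr = c(per_0.1 = 0.1, sd = sds[["whr"]]))

  weight_table <- function(w) {
    ids <- names(w)
    data.frame(variant_id = ids,
               effect_allele = unname(attr(cohort$dosages, "effect_allele")[ids]),
               other_allele = unname(attr(cohort$dosages, "other_allele")[ids]),
               weight = unname(w), stringsAsFactors = FALSE)
  }
  wt <- list(bmi = weight_table(cohort$weights_bmi),
             whr = weight_table(cohort$weights_whr))
  grs <- firsts <- list()
  if (any(c("grs", "onesample", "mvmr") %in% stages)) {
    for (ex in c("bmi", "whr")) {
      grs[[ex]] <- compute_grs(cohort$dosages, wt[[ex]])
      firsts[[ex]] <- fit_first_stage(dat[[ex]], grs[[ex]], CV)
      note("grs %s: partial R2 = %.4g%%, F = %.4g", ex,
           100 * firsts[[ex]]$r_squared, firsts[[ex]]$f_statistic)
    }
  }

  if ("observational" %in% stages) {
    for (ex in c("bmi", "whr")) {
      fit <- fit_quasipoisson(dat$admissions, dat[, ex, drop = FALSE],
                              dat$person_years, CV)
      note("observational %s: dispersion %.3f", ex, fit$dispersion)
      for (sc in names(scales[[ex]])) {
        r <- rate_per_sd(fit$coefficients[[ex]], fit$se[[ex]],
                         scales[[ex]][[sc]])
        rows[[length(rows) + 1]] <- results_row(
          "observational", ex, "quasipoisson", sc, r,
          n = fit$n, phi = fit$dispersion)
      }
    }
  }

  if ("onesample" %in% stages) {
    for (ex in c("bmi", "whr")) {
      second <- fit_second_stage(dat$admissions, grs[[ex]],
                                 dat$person_years, CV)
      est <- wald_iv(firsts[[ex]], second, exposure = ex)
      for (sc in names(scales[[ex]])) {
        rows[[length(rows) + 1]] <- results_row(
          "onesample_mr", ex, "wald_iv", sc,
          scale_mr_estimate(est, scales[[ex]][[sc]]),
          n = est$n, f_stat = firsts[[ex]]$f_statistic,
          phi = second$dispersion)
      }
    }
    # WHR adjusted for BMI: residual exposure, instrumented by the WHR SNPs
    resid <- residual_exposure(dat$whr, dat$bmi)
    fs <- fit_first_stage(resid, grs$whr, CV)
    ss <- fit_second_stage(dat$admissions, grs$whr, dat$person_years, CV)
    est <- wald_iv(fs, ss, exposure = "whr_adj_bmi")
    rows[[length(rows) + 1]] <- results_row(
      "onesample_mr", "whr_adj_bmi", "wald_iv", "sd",
      scale_mr_estimate(est, stats::sd(resid)),
      n = est$n, f_stat = fs$f_statistic, phi = ss$dispersion)
  }

  harmonized <- list()
  if (any(c("twosample", "mvmr") %in% stages)) {
    halves <- split_two_sample(cohort, config$two_sample_fraction,
                               seed = derive_seed(config$seed, "split"))
    note("two-sample split: %d / %d", nrow(halves$a$data),
         nrow(halves$b$data))
    # LD estimated on the full genotype panel for precision; the split only
    # separates the association estimates
    r2 <- ld_matrix(cohort$dosages)
    for (ex in c("bmi", "whr")) {
      exs <- generate_summary_stats(halves$a, "exposure", exposure = ex,
                                    covariates = config$covariates,
                                    snps = wt[[ex]]$variant_id)
      ous <- generate_summary_stats(halves$b, "outcome",
                                    covariates = config$covariates,
                                    snps = wt[[ex]]$variant_id)
      h <- harmonize(exs, ous)
      kept <- ld_prune(h$variant_id, h$pval_x, r2, config$r2_threshold)
      h <- h[h$variant_id %in% kept, ]
      class(h) <- c("harmonized_stats", "data.frame")
      harmonized[[ex]] <- h
      note("twosample %s: %d SNPs after harmonization + LD pruning", ex,
           nrow(h))
    }
  }

  if ("twosample" %in% stages) {
    for (ex in c("bmi", "whr")) {
      h <- harmonized[[ex]]
      qc <- cochran_q(h)
      qr_ <- rucker_q(h)
      ests <- list(
        ivw_exact(h),
        mr_egger(h),
        penalized_weighted_median(h, n_boot = 500L,
                                  seed = derive_seed(config$seed, "pwm")),
        weighted_mode(h, n_boot = 500L,
                      seed = derive_seed(config$seed, "mode")))
      for (e in ests) for (sc in names(scales[[ex]])) {
        rows[[length(rows) + 1]] <- results_row(
          "twosample_mr", ex, e$method, sc,
          scale_mr_estimate(e, scales[[ex]][[sc]]),
          q_c = qc$Q, q_r = qr_$Q, j_snps = nrow(h))
      }
    }
  }

  if ("mvmr" %in% stages) {
    expos <- dat[, c("bmi", "whr")]
    ests <- mvmr_onesample(dat$admissions, dat$person_years, expos,
                           cohort$dosages, CV, n_boot = config$n_boot,
                           seed = derive_seed(config$seed, "mvmr_boot"))
    for (ex in c("bmi", "whr")) {
      e <- ests[[ex]]
      for (sc in names(scales[[ex]])) {
        rows[[length(rows) + 1]] <- results_row(
          "mvmr_onesample", ex, "mvmr_onesample", sc,
          scale_mr_estimate(e, scales[[ex]][[sc]]),
          n = e$n, f_stat = e$conditional_f)
      }
    }
    if (length(harmonized) == 2) {
      shared <- intersect(harmonized$bmi$variant_id,
                          harmonized$whr$variant_id)
      # per-SNP exposure betas for both exposures over the combined SNP set
      all_ids <- union(harmonized$bmi$variant_id, harmonized$whr$variant_id)
      halves <- split_two_sample(cohort, config$two_sample_fraction,
                                 seed = derive_seed(config$seed, "split"))
      bx <- sapply(c("bmi", "whr"), function(ex)
        generate_summary_stats(halves$a, "exposure", exposure = ex,
                               covariates = config$covariates,
                               snps = all_ids)$beta)
      ou <- generate_summary_stats(halves$b, "outcome",
                                   covariates = config$covariates,
                                   snps = all_ids)
      mv <- mvmr_ivw_twosample(bx, ou$beta, ou$se)
      for (ex in c("bmi", "whr")) {
        e <- mv[[ex]]
        for (sc in names(scales[[ex]])) {
          rows[[length(rows) + 1]] <- results_row(
            "mvmr_twosample", ex, "mvmr_ivw", sc,
            scale_mr_estimate(e, scales[[ex]][[sc]]),
            q_c = e$Q, j_snps = e$J)
        }
      }
    }
  }

  results <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(results)) rownames(results) <- NULL
  out <- list(results = results, cohort = cohort, log = log)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", length(x$log), "log records\n")
  if (!is.null(x$results)) print(x$results, digits = 4, row.names = FALSE)
  invisible(x)
}
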