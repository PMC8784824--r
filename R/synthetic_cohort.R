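#' Generate a dosage matrix of independent biallelic variants
#'
#' Each SNP's dosage is drawn as Binomial(2, maf) per participant, with the
#' minor-allele frequency itself drawn uniformly from `config$maf_range`.
#' SNPs are mutually independent; linkage can be injected afterwards with
#' [duplicate_snps()].
#'
#' @param config A [sim_config()] object.
#' @return An `n x J` integer matrix with dosages in \{0, 1, 2\}, column
#'   names `rs0001, ...`, and attributes `maf` (generating frequencies),
#'   `effect_allele` and `other_allele` (randomly assigned nucleotide pair
#'   per SNP).
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$n_snps_bmi + config$n_snps_whr
  if (J == 0) stop_mr("no instruments")
  n <- config$n_participants
  with_seed(derive_seed(config$seed, "genotypes"), {
    maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
    d <- matrix(stats::rbinom(n * J, 2L, rep(maf, each = n)), nrow = n)
    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, J, replace = TRUE)
    oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), "")
    colnames(d) <- sprintf("rs%04d", seq_len(J))
    attr(d, "maf") <- stats::setNames(maf, colnames(d))
    attr(d, "effect_allele") <- stats::setNames(ea, colnames(d))
    attr(d, "other_allele") <- stats::setNames(unname(oa), colnames(d))
    d
  })
}

#' Duplicate SNP columns to inject perfect or partial linkage
#'
#' Utility for testing LD pruning: appends copies of selected columns,
#' optionally degraded by swapping a fraction of genotypes so the squared
#' correlation with the parent column falls below one.
#'
#' @param dosages Dosage matrix from [generate_genotypes()].
#' @param which Column indices or names to duplicate.
#' @param noise Fraction of rows whose duplicated genotype is resampled.
#' @param seed Seed for the resampling.
#' @return The augmented matrix; duplicated columns are named `<id>_dup`.
#' @export
duplicate_snps <- function(dosages, which, noise = 0, seed = 1L) {
  dup <- dosages[, which, drop = FALSE]
  if (noise > 0) {
    with_seed(derive_seed(seed, "dup_noise"), {
      for (j in seq_len(ncol(dup))) {
        flip <- stats::runif(nrow(dup)) < noise
        dup[flip, j] <- stats::rbinom(sum(flip), 2L, mean(dup[, j]) / 2)
      }
    })
  }
  colnames(dup) <- paste0(colnames(dup), "_dup")
  cbind(dosages, dup)
}

#' Generate exposures driven by genotypes and a latent confounder
#'
#' Builds the BMI-like and WHR-like exposures as
#' `exposure = intercept + sum_j w_j d_ij + gamma * C_i + noise`, with
#' disjoint instrument sets (the first `n_snps_bmi` columns drive BMI, the
#' rest drive WHR). Per-SNP weights are drawn i.i.d. half-normal and jointly
#' rescaled so the instrument set explains exactly the configured variance
#' fraction in expectation; residual noise absorbs the remainder so the
#' marginal SD matches its target.
#'
#' @param dosages Dosage matrix from [generate_genotypes()].
#' @param config A [sim_config()] object.
#' @return A list with `exposures` (data.frame `bmi`, `whr`), `confounder`
#'   (standard-normal vector), and the true per-allele weights
#'   `weights_bmi`, `weights_whr` (named by variant).
#' @export
generate_exposures <- function(dosages, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(dosages)) stop_mr("dosage matrix required")
  n <- nrow(dosages)
  maf <- attr(dosages, "maf")
  ids <- colnames(dosages)
  idx_bmi <- seq_len(config$n_snps_bmi)
  idx_whr <- setdiff(seq_len(config$n_snps_bmi + config$n_snps_whr), idx_bmi)

  with_seed(derive_seed(config$seed, "exposures"), {
    confounder <- stats::rnorm(n)
    build <- function(idx, mean, sd, r2, gamma) {
      if (r2 >= 1) stop_mr("grs_r2 target must be < 1")
      w <- numeric(0)
      score <- 0
      if (length(idx) > 0 && r2 > 0) {
        raw <- abs(stats::rnorm(length(idx)))
        v_snp <- 2 * maf[idx] * (1 - maf[idx]) # dosage variance per SNP
        scale <- sqrt(r2 * sd^2 / sum(raw^2 * v_snp))
        w <- stats::setNames(raw * scale, ids[idx])
        score <- as.vector(dosages[, idx, drop = FALSE] %*% w)
      } else if (length(idx) > 0) {
        w <- stats::setNames(rep(0, length(idx)), ids[idx])
      }
      noise_var <- sd^2 * (1 - r2) - gamma^2
      if (noise_var < 0)
        stop_mr("confounder effect too large for the target exposure SD")
      intercept <- mean - sum(w * 2 * maf[idx])
      x <- intercept + score + gamma * confounder +
        stats::rnorm(n, 0, sqrt(noise_var))
      list(x = x, w = w)
    }
    bmi <- build(idx_bmi, config$bmi_mean, config$bmi_sd,
                 config$grs_r2_bmi, config$confounder_effect_bmi)
    whr <- build(idx_whr, config$whr_mean, config$whr_sd,
                 config$grs_r2_whr, config$confounder_effect_whr)
    list(exposures = data.frame(bmi = bmi$x, whr = whr$x),
         confounder = confounder,
         weights_bmi = bmi$w, weights_whr = whr$w)
  })
}

#' Generate staggered entry, censoring and death
#'
#' Entry times are uniform over the recruitment window; follow-up runs from
#' entry to the administrative horizon or an exponential death time,
#' whichever comes first.
#'
#' @param config A [sim_config()] object.
#' @param n Number of participants (defaults to `config$n_participants`).
#' @return A data.frame with `person_years` (> 0) and `died` (0/1).
#' @export
generate_followup <- function(config, n = config$n_participants) {
  stopifnot(inherits(config, "sim_config"))
  if (config$max_followup_years <= 0) stop_mr("nonpositive horizon")
  with_seed(derive_seed(config$seed, "followup"), {
    entry <- stats::runif(n, 0, config$recruit_window_years)
    censor <- config$max_followup_years - entry
    if (config$death_hazard > 0) {
      death <- stats::rexp(n, config$death_hazard)
      died <- as.integer(death < censor)
      t <- pmin(death, censor)
    } else {
      died <- integer(n)
      t <- censor
    }
    data.frame(person_years = t, died = died)
  })
}

#' Draw direct SNP-to-log-rate (pleiotropic) effects
#'
#' @param config A [sim_config()] object; `config$pleiotropy` selects the
#'   mode: `"none"` (zero vector), `"balanced"` (i.i.d. mean zero) or
#'   `"directional"` (i.i.d. with the configured nonzero mean).
#' @param n_snps Length of the effect vector.
#' @return Numeric vector of direct effects on the log admission rate.
#' @export
inject_pleiotropy <- function(config, n_snps) {
  stopifnot(inherits(config, "sim_config"))
  mode <- config$pleiotropy
  if (!mode %in% c("none", "balanced", "directional"))
    stop_mr("unknown pleiotropy mode: ", mode)
  if (mode == "none") return(rep(0, n_snps))
  mu <- if (mode == "balanced") 0 else config$pleiotropy_mean
  with_seed(derive_seed(config$seed, "pleiotropy"),
            stats::rnorm(n_snps, mu, config$pleiotropy_sd))
}

#' Generate admission counts from exposures, follow-up and frailty
#'
#' Counts follow `y ~ Poisson(t * nu * exp(b0 + b'X + g*C + d'alpha))` with
#' `nu` a mean-one gamma frailty of variance `config$frailty_variance`. The
#' intercept `b0` comes from [baseline_log_rate()], so the marginal mean is
#' calibrated analytically (exact when no pleiotropy is active).
#'
#' @param cohort A data.frame with columns `bmi`, `whr`, `confounder`,
#'   `person_years`.
#' @param config A [sim_config()] object.
#' @param dosages Optional dosage matrix, required when `pleio` is nonzero.
#' @param pleio Optional vector of direct SNP effects from
#'   [inject_pleiotropy()].
#' @return Integer vector of admission counts.
#' @export
generate_admissions <- function(cohort, config, dosages = NULL, pleio = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$frailty_variance < 0) stop_mr("frailty_variance must be nonnegative")
  check_offset(cohort$person_years)
  n <- nrow(cohort)
  b <- true_log_rate(config)
  eta <- baseline_log_rate(config) +
    b[["bmi"]] * cohort$bmi + b[["whr"]] * cohort$whr +
    config$confounder_log_rate * cohort$confounder
  if (!is.null(pleio) && any(pleio != 0)) {
    if (is.null(dosages)) stop_mr("dosages required for pleiotropic effects")
    eta <- eta + as.vector(dosages %*% pleio)
  }
  with_seed(derive_seed(config$seed, "admissions"), {
    nu <- if (config$frailty_variance > 0) {
      shape <- 1 / config$frailty_variance
      stats::rgamma(n, shape = shape, rate = shape)
    } else rep(1, n)
    stats::rpois(n, cohort$person_years * nu * exp(eta))
  })
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates genotype, exposure, follow-up, pleiotropy and admission
#' generation into one cohort object. Identical configurations (including
#' the seed) yield identical cohorts.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `mr_cohort`: a list with `data` (data.frame:
#'   `id`, `age`, `sex`, `bmi`, `whr`, `confounder`, `person_years`,
#'   `admissions`, `died`), `dosages` (matrix), `weights_bmi`,
#'   `weights_whr` (true per-allele exposure effects), `pleiotropy`
#'   (true direct effects) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dos <- generate_genotypes(config)
  exp_out <- generate_exposures(dos, config)
  fup <- generate_followup(config)
  pleio <- inject_pleiotropy(config, ncol(dos))
  demo <- with_seed(derive_seed(config$seed, "demographics"), {
    n <- config$n_participants
    data.frame(age = pmin(pmax(stats::rnorm(n, 57.4, 7.99), 39), 72),
               sex = stats::rbinom(n, 1L, 0.463)) # 1 = male
  })
  cohort <- cbind(data.frame(id = seq_len(config$n_participants)), demo,
                  exp_out$exposures,
                  data.frame(confounder = exp_out$confounder), fup)
  cohort$admissions <- generate_admissions(cohort, config, dos, pleio)
  out <- list(data = cohort, dosages = dos,
              weights_bmi = exp_out$weights_bmi,
              weights_whr = exp_out$weights_whr,
              pleiotropy = pleio, config = config)
  class(out) <- "mr_cohort"
  out
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$data), "participants,",
      ncol(x$dosages), "SNPs\n")
  cat(sprintf("  admissions: mean %.3f var %.2f | person-years: mean %.3f\n",
              mean(x$data$admissions), stats::var(x$data$admissions),
              mean(x$data$person_years)))
  invisible(x)
}

#' Split a cohort into two disjoint subsamples
#'
#' Used to build non-overlapping exposure and outcome summary statistics for
#' two-sample analyses.
#'
#' @param cohort An `mr_cohort`.
#' @param fraction Fraction of participants in the first subsample, in (0,1).
#' @param seed Seed for the random split.
#' @return A list of two `mr_cohort` objects whose participant sets are
#'   disjoint and jointly exhaust the input.
#' @export
split_two_sample <- function(cohort, fraction = 0.5, seed = 1L) {
  stopifnot(inherits(cohort, "mr_cohort"))
  n <- nrow(cohort$data)
  if (n < 2) stop_mr("need at least 2 participants to split")
  if (fraction <= 0 || fraction >= 1) stop_mr("fraction must be in (0, 1)")
  idx <- with_seed(derive_seed(seed, "two_sample_split"),
                   sample.int(n, size = floor(n * fraction)))
  take <- function(rows) {
    out <- cohort
    out$data <- cohort$data[rows, , drop = FALSE]
    out$dosages <- cohort$dosages[rows, , drop = FALSE]
    for (a in c("maf", "effect_allele", "other_allele"))
      attr(out$dosages, a) <- attr(cohort$dosages, a)
    out
  }
  list(a = take(sort(idx)), b = take(sort(setdiff(seq_len(n), idx))))
}
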