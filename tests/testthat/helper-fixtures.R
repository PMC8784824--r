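# Shared fixture builders; everything is generated in code.

small_cfg <- function(n = 2000L, seed = 1L, ...) {
  args <- list(n_participants = n, n_snps_bmi = 8L, n_snps_whr = 4L,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Weight table built from a cohort's true per-allele effects.
true_weight_table <- function(cohort, exposure = c("bmi", "whr")) {
  exposure <- match.arg(exposure)
  w <- if (exposure == "bmi") cohort$weights_bmi else cohort$weights_whr
  ids <- names(w)
  data.frame(variant_id = ids,
             effect_allele = unname(attr(cohort$dosages, "effect_allele")[ids]),
             other_allele = unname(attr(cohort$dosages, "other_allele")[ids]),
             weight = unname(w), stringsAsFactors = FALSE)
}

# Random harmonized summary set with heterogeneous true ratios (not a
# valid-instrument draw; used for algebraic property checks).
random_stats <- function(J, seed) {
  set.seed(seed)
  out <- data.frame(variant_id = sprintf("v%03d", seq_len(J)),
                    effect_allele = "A", other_allele = "G",
                    beta_x = runif(J, 0.02, 0.3) * sample(c(-1, 1), J, TRUE),
                    se_x = runif(J, 0.005, 0.02),
                    beta_y = rnorm(J, 0, 0.05),
                    se_y = runif(J, 0.01, 0.08),
                    eaf = runif(J, 0.1, 0.9),
                    stringsAsFactors = FALSE)
  class(out) <- c("harmonized_stats", "data.frame")
  out
}

# Manual weight-table rows for harmonization/orientation tests.
wt_row <- function(id, ea, oa, weight, eaf = NA) {
  data.frame(variant_id = id, effect_allele = ea, other_allele = oa,
             weight = weight, eaf = eaf, stringsAsFactors = FALSE)
}
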