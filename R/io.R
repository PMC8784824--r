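#' Write a synthetic cohort to tab-delimited text with a JSON sidecar
#'
#' The participant table and dosage matrix are written as one TSV (dosage
#' columns named by variant id); the configuration, allele assignments and
#' true generative parameters go to `<path>.meta.json`.
#'
#' @param cohort An `mr_cohort`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "mr_cohort"))
  tab <- cbind(cohort$data, as.data.frame(cohort$dosages))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(config = unclass(cohort$config),
               maf = as.list(attr(cohort$dosages, "maf")),
               effect_allele = as.list(attr(cohort$dosages, "effect_allele")),
               other_allele = as.list(attr(cohort$dosages, "other_allele")),
               weights_bmi = as.list(cohort$weights_bmi),
               weights_whr = as.list(cohort$weights_whr),
               pleiotropy = cohort$pleiotropy)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path TSV path (the sidecar `<path>.meta.json` must exist).
#' @return An `mr_cohort`.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  snp_cols <- grep("^rs", names(tab), value = TRUE)
  dos <- as.matrix(tab[, snp_cols, drop = FALSE])
  attr(dos, "maf") <- unlist(meta$maf)
  attr(dos, "effect_allele") <- unlist(meta$effect_allele)
  attr(dos, "other_allele") <- unlist(meta$other_allele)
  cfg <- meta$config
  cfg$maf_range <- as.numeric(cfg$maf_range)
  class(cfg) <- "sim_config"
  out <- list(data = tab[, setdiff(names(tab), snp_cols)],
              dosages = dos,
              weights_bmi = unlist(meta$weights_bmi),
              weights_whr = unlist(meta$weights_whr),
              pleiotropy = as.numeric(meta$pleiotropy),
              config = cfg)
  class(out) <- "mr_cohort"
  out
}

#' Write summary statistics in GWAS-summary style
#'
#' Tab-delimited with columns `variant_id`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `pval`, `eaf`, `n`.
#'
#' @param stats A `summary_stats_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GWAS-summary-style table
#'
#' @param path TSV path with the columns written by
#'   [write_summary_stats()]; also accepts a variant weight table (columns
#'   `variant_id`, `effect_allele`, `other_allele`, `weight`).
#' @return A data.frame (class `summary_stats_table` when `beta` present).
#' @export
read_summary_stats <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if ("beta" %in% names(out))
    class(out) <- c("summary_stats_table", "data.frame")
  out
}

#' Write a pipeline results table
#'
#' Tab-delimited with a fixed column order and six-significant-digit
#' formatting; round-trips losslessly at that precision.
#'
#' @param table A nonempty results data.frame (see [run_pipeline()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  if (is.null(table) || nrow(table) == 0)
    stop_mr("results table is empty; nothing written")
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  for (j in which(num)) out[[j]] <- signif(table[[j]], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
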