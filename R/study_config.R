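#' Analysis configuration
#'
#' Bundles the tunable choices of the pipeline. Defaults reproduce the
#' canonical analysis: Welch t screen at raw p < 0.001, Pearson correlation,
#' raw correlation differences (no Fisher z), combined regulator score
#' |z1| + |z2|, and PIF based on the overall mean abundance.
#'
#' @param de_pvalue_threshold DE screen threshold; genes with p strictly below
#'   it become targets. Must lie in (0, 1).
#' @param de_test Two-group test for the screen: \code{"welch"} (default) or a
#'   function \code{f(s_values, c_values)} returning a two-sided p-value,
#'   so alternative tests can be plugged in.
#' @param regulator_universe \code{"all_expressed"} (every gene in the study,
#'   DE genes included) or an explicit character vector of gene ids.
#' @param correlation_method \code{"pearson"} (default) or \code{"spearman"}.
#' @param fisher_z If \code{TRUE}, differential co-expression is the
#'   difference of Fisher-z transformed correlations instead of the raw
#'   difference. Off by default.
#' @param combine Combined regulator score: \code{"sum_abs"} (default,
#'   |z1| + |z2|) or \code{"mean_abs"} ((|z1| + |z2|) / 2).
#' @param pif_variant \code{"overall_mean"} (default, PIF = x_j * d_j with x_j
#'   the mean over all samples) or \code{"half_sum"}
#'   (PIF = (x_jS + x_jC) / 2 * d_j).
#' @param min_samples_per_condition Minimum group size; at least 3.
#' @param seed Integer seed recorded in output headers and used by any
#'   stochastic step.
#' @return A list of class \code{"StudyConfig"}.
#' @export
study_config <- function(de_pvalue_threshold = 0.001,
                         de_test = "welch",
                         regulator_universe = "all_expressed",
                         correlation_method = c("pearson", "spearman"),
                         fisher_z = FALSE,
                         combine = c("sum_abs", "mean_abs"),
                         pif_variant = c("overall_mean", "half_sum"),
                         min_samples_per_condition = 3L,
                         seed = 1L) {
  stopifnot(is.numeric(de_pvalue_threshold), length(de_pvalue_threshold) == 1L,
            de_pvalue_threshold > 0, de_pvalue_threshold < 1,
            min_samples_per_condition >= 3L)
  if (!is.function(de_test)) de_test <- match.arg(de_test, "welch")
  structure(
    list(de_pvalue_threshold = de_pvalue_threshold,
         de_test = de_test,
         regulator_universe = regulator_universe,
         correlation_method = match.arg(correlation_method),
         fisher_z = isTRUE(fisher_z),
         combine = match.arg(combine),
         pif_variant = match.arg(pif_variant),
         min_samples_per_condition = as.integer(min_samples_per_condition),
         seed = as.integer(seed)),
    class = "StudyConfig")
}

#' Resolve the regulator universe of a study
#'
#' @param study An \code{ExpressionStudy}.
#' @param config A \code{StudyConfig}.
#' @return Character vector of regulator gene ids.
#' @export
regulator_universe <- function(study, config = study_config()) {
  u <- config$regulator_universe
  if (identical(u, "all_expressed")) return(study$gene_ids)
  u <- as.character(u)
  absent <- setdiff(u, study$gene_ids)
  if (length(absent))
    stop("regulators absent from study: ", paste(absent, collapse = ", "))
  u
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config[!vapply(config, is.function, TRUE)],
                              auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
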