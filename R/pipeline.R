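pkg_version <- function() {
  as.character(utils::packageVersion("rifnet"))
}

# Result tables carry a comment line with version, seed and config hash so a
# table can always be traced back to the run that produced it.
write_result_table <- function(df, path, config) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# rifnet %s | seed=%d | config_hash=%s",
                     pkg_version(), config$seed, config_hash(config)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

write_manifest <- function(path, config, inputs, outputs) {
  manifest <- list(
    tool = "rifnet", version = pkg_version(),
    config_hash = config_hash(config), seed = config$seed,
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    outputs = basename(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full differential-network pipeline
#'
#' Chains the stages: load and validate the study, screen for DE targets,
#' score and rank every regulator in the universe by combined RIF, and - when
#' a focal regulator is given - rank the DE targets by PIF times absolute
#' differential co-expression to it, optionally testing gene sets for
#' enrichment in both extremes of that ranking. All result tables plus a
#' reproducibility manifest are written to \code{out_dir}; on any stage
#' failure partially written outputs are removed.
#'
#' @param matrix_path,conditions_path Study input files
#'   (see \code{\link{read_expression_study}}).
#' @param out_dir Output directory, created if needed.
#' @param config A \code{StudyConfig}.
#' @param focal_regulator Optional gene id for the PIF target ranking.
#' @param gene_sets_path Optional GMT file; with a focal regulator set, each
#'   gene set is tested in the negative (head) and positive (tail) extreme of
#'   the PIF product ranking.
#' @param treated_label,control_label Condition role assignment
#'   (see \code{\link{expression_study}}).
#' @return Invisibly, the output directory. Files written:
#'   \code{de_summary.tsv}, \code{rif_scores.tsv}, \code{ma_plot.tsv},
#'   \code{rif_scatter.tsv}, optionally \code{pif_targets.tsv} and
#'   \code{enrichment.tsv}, and \code{manifest.json}.
#' @export
run_pipeline <- function(matrix_path, conditions_path, out_dir,
                         config = study_config(), focal_regulator = NULL,
                         gene_sets_path = NULL,
                         treated_label = NULL, control_label = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_result_table(df, path, config)
    written <<- c(written, path)
    path
  }
  tryCatch({
    stage <- "load"
    study <- read_expression_study(matrix_path, conditions_path,
                                   treated_label = treated_label,
                                   control_label = control_label)
    stage <- "de_screen"
    summaries <- summarize_targets(study, config)
    de <- select_de_targets(summaries, config$de_pvalue_threshold)
    emit(summaries, "de_summary.tsv")
    emit(export_ma_plot(summaries), "ma_plot.tsv")
    stage <- "rif"
    scores <- score_regulators(study, regulator_universe(study, config),
                               de, config)
    emit(scores, "rif_scores.tsv")
    emit(export_rif_scatter(scores), "rif_scatter.tsv")
    if (!is.null(focal_regulator)) {
      stage <- "pif"
      pif <- pif_rank_targets(focal_regulator, de, study, config)
      emit(pif, "pif_targets.tsv")
      if (!is.null(gene_sets_path)) {
        stage <- "enrichment"
        sets <- read_gmt(gene_sets_path)
        head_res <- ranked_enrichment(pif$target_id, sets, "head")
        tail_res <- ranked_enrichment(pif$target_id, sets, "tail")
        head_res$direction <- "negative_extreme"
        tail_res$direction <- "positive_extreme"
        emit(rbind(head_res, tail_res), "enrichment.tsv")
      }
    }
    stage <- "manifest"
    write_manifest(file.path(out_dir, "manifest.json"), config,
                   inputs = c(matrix_path, conditions_path,
                              if (!is.null(gene_sets_path)) gene_sets_path),
                   outputs = written)
  }, error = function(e) {
    unlink(c(written, file.path(out_dir, "manifest.json")))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(out_dir)
}

#' Write a simulated study and its truth labels to disk
#'
#' Emits the matrix/conditions pair consumed by the pipeline plus a
#' \code{truth.tsv} labelling the planted DE targets and planted
#' differentially connected regulators.
#'
#' @param sim Result of \code{\link{simulate_study}}.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the output directory.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_study(sim$study,
                         file.path(out_dir, "expression.tsv"),
                         file.path(out_dir, "conditions.tsv"))
  truth <- sim$truth
  block_of <- character(0)
  for (r in names(truth$blocks))
    block_of[truth$blocks[[r]]] <- r
  ids <- sim$study$gene_ids
  df <- data.frame(
    gene_id = ids,
    planted_de = ids %in% truth$de_gene_ids,
    planted_regulator = ids %in% truth$dc_regulator_ids,
    block_regulator = ifelse(ids %in% names(block_of), block_of[ids], ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
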