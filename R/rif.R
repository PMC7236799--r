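#' Condition-wise co-expression and differential co-expression
#'
#' For every (regulator, target) pair computes the correlation across the
#' treated (S) samples, the correlation across the control (C) samples, and
#' their difference DC = r_S - r_C, the differential co-expression.
#'
#' A regulator that is itself a target (the universe includes DE genes) gets
#' the self-link r_S = r_C = 1 and DC = 0. A gene with zero variance within a
#' condition has no defined correlation on that side; that r is set to 0 and
#' the link flagged, so the regulator stays in the standardization population
#' instead of silently vanishing.
#'
#' @param study An \code{ExpressionStudy}.
#' @param regulators Character vector of candidate regulator gene ids.
#' @param de_targets DE summaries (rows of \code{\link{summarize_targets}})
#'   or a character vector of target gene ids.
#' @param config A \code{StudyConfig} (correlation method, Fisher-z switch).
#' @return A data.frame with one row per pair: \code{regulator_id},
#'   \code{target_id}, \code{r_S}, \code{r_C}, \code{dc}, \code{flagged}.
#' @export
coexpression_links <- function(study, regulators, de_targets,
                               config = study_config()) {
  m <- coexpression_matrices(study, regulators, target_ids(de_targets), config)
  data.frame(
    regulator_id = rep(rownames(m$r_S), times = ncol(m$r_S)),
    target_id = rep(colnames(m$r_S), each = nrow(m$r_S)),
    r_S = as.vector(m$r_S), r_C = as.vector(m$r_C),
    dc = as.vector(m$dc), flagged = as.vector(m$flagged),
    stringsAsFactors = FALSE)
}

target_ids <- function(de_targets) {
  if (is.data.frame(de_targets)) de_targets$gene_id else as.character(de_targets)
}

# Regulator-by-target correlation matrices per condition plus DC.
coexpression_matrices <- function(study, regulators, targets,
                                  config = study_config()) {
  stopifnot(inherits(study, "ExpressionStudy"))
  absent <- setdiff(c(regulators, targets), study$gene_ids)
  if (length(absent))
    stop("genes absent from study: ", paste(absent, collapse = ", "))
  corr <- function(role) {
    cols <- condition_samples(study, role)
    suppressWarnings(stats::cor(
      t(study$values[regulators, cols, drop = FALSE]),
      t(study$values[targets, cols, drop = FALSE]),
      method = config$correlation_method))
  }
  r_s <- corr("S")
  r_c <- corr("C")
  flagged <- is.na(r_s) | is.na(r_c)
  r_s[is.na(r_s)] <- 0
  r_c[is.na(r_c)] <- 0
  self <- outer(regulators, targets, "==")
  r_s[self] <- 1
  r_c[self] <- 1
  flagged[self] <- FALSE
  if (config$fisher_z) {
    clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    dc <- atanh(clamp(r_s)) - atanh(clamp(r_c))
    dc[self] <- 0
  } else {
    dc <- r_s - r_c
  }
  list(r_S = r_s, r_C = r_c, dc = dc, flagged = flagged)
}

check_link_coverage <- function(de_targets, links) {
  want <- target_ids(de_targets)
  hit <- match(want, links$target_id)
  if (anyNA(hit) || anyDuplicated(links$target_id[links$target_id %in% want]))
    stop("links must cover every DE target exactly once; missing or ",
         "duplicated: ",
         paste(unique(c(want[is.na(hit)],
                        links$target_id[duplicated(links$target_id)])),
               collapse = ", "))
  links[hit, , drop = FALSE]
}

#' RIF1 for one regulator
#'
#' RIF1 = (1 / nDE) * sum_j x_j * d_j * DC_rj^2: the abundance- and
#' DE-weighted average of the squared differential co-expression, favouring
#' regulators consistently rewired against abundant, strongly shifted targets.
#'
#' @param de_targets DE summaries (one row per DE target).
#' @param links Link rows for a single regulator covering every DE target
#'   exactly once (columns \code{target_id}, \code{dc}).
#' @return The raw RIF1 value.
#' @export
rif1 <- function(de_targets, links) {
  links <- check_link_coverage(de_targets, links)
  mean(de_targets$x_j * de_targets$d_j * links$dc^2)
}

#' RIF2 for one regulator
#'
#' RIF2 = (1 / nDE) * sum_j [(x_jS * r_rjS)^2 - (x_jC * r_rjC)^2]: the change
#' between conditions in the regulator's squared abundance-weighted
#' correlation, favouring regulators whose ability to predict target
#' abundance is most altered.
#'
#' @inheritParams rif1
#' @return The raw RIF2 value.
#' @export
rif2 <- function(de_targets, links) {
  links <- check_link_coverage(de_targets, links)
  mean((de_targets$x_jS * links$r_S)^2 - (de_targets$x_jC * links$r_C)^2)
}

#' Combine standardized RIF scores and rank regulators
#'
#' Applies the combination rule (default: combined = |z1| + |z2|) and assigns
#' 1-based ranks by descending combined score, breaking exact ties by lexical
#' regulator id so output is deterministic.
#'
#' @param regulator_id Character vector.
#' @param rif1_z,rif2_z Standardized scores, parallel to \code{regulator_id}.
#' @param combine \code{"sum_abs"} or \code{"mean_abs"}.
#' @return data.frame sorted by rank with columns \code{regulator_id},
#'   \code{rif1_z}, \code{rif2_z}, \code{combined}, \code{rank}.
#' @export
rif_rank_table <- function(regulator_id, rif1_z, rif2_z,
                           combine = c("sum_abs", "mean_abs")) {
  combine <- match.arg(combine)
  combined <- abs(rif1_z) + abs(rif2_z)
  if (combine == "mean_abs") combined <- combined / 2
  ord <- order(-combined, regulator_id, method = "radix")
  data.frame(regulator_id = regulator_id[ord],
             rif1_z = rif1_z[ord], rif2_z = rif2_z[ord],
             combined = combined[ord], rank = seq_along(ord),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score and rank every candidate regulator
#'
#' Computes raw RIF1/RIF2 per regulator, z-standardizes each statistic across
#' the regulator universe (raw RIF magnitudes depend on the abundance scale;
#' standardized scores are comparable and match how combined scores of about
#' +/- 3 arise), combines them, and ranks.
#'
#' @param study An \code{ExpressionStudy}.
#' @param regulators Character vector of regulator ids (the universe), or
#'   \code{NULL} to use \code{regulator_universe(study, config)}.
#' @param de_targets DE summaries from \code{\link{select_de_targets}}.
#' @param config A \code{StudyConfig}.
#' @return data.frame sorted by rank: \code{regulator_id}, \code{rif1_raw},
#'   \code{rif2_raw}, \code{rif1_z}, \code{rif2_z}, \code{combined},
#'   \code{rank}.
#' @export
score_regulators <- function(study, regulators = NULL, de_targets,
                             config = study_config()) {
  if (is.null(regulators)) regulators <- regulator_universe(study, config)
  regulators <- as.character(regulators)
  if (length(regulators) < 2L)
    stop("standardization needs at least 2 regulators")
  stopifnot(is.data.frame(de_targets), nrow(de_targets) >= 1L)
  m <- coexpression_matrices(study, regulators, de_targets$gene_id, config)
  n_de <- nrow(de_targets)
  rif1_raw <- as.vector(m$dc^2 %*% (de_targets$x_j * de_targets$d_j)) / n_de
  rif2_raw <- as.vector(m$r_S^2 %*% de_targets$x_jS^2 -
                          m$r_C^2 %*% de_targets$x_jC^2) / n_de
  zscore <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  z1 <- zscore(rif1_raw)
  z2 <- zscore(rif2_raw)
  ranked <- rif_rank_table(regulators, z1, z2, combine = config$combine)
  i <- match(ranked$regulator_id, regulators)
  cbind(ranked[, "regulator_id", drop = FALSE],
        rif1_raw = rif1_raw[i], rif2_raw = rif2_raw[i],
        ranked[, c("rif1_z", "rif2_z", "combined", "rank"), drop = FALSE])
}

#' Table behind a RIF1-versus-RIF2 scatter
#'
#' Pure projection of regulator scores onto the standardized axes; extreme
#' points mark the differentially connected candidates.
#'
#' @param scores Output of \code{\link{score_regulators}}.
#' @return data.frame with columns \code{rif1_z}, \code{rif2_z}, \code{label}.
#' @export
export_rif_scatter <- function(scores) {
  stopifnot(is.data.frame(scores))
  data.frame(rif1_z = scores$rif1_z, rif2_z = scores$rif2_z,
             label = scores$regulator_id, stringsAsFactors = FALSE)
}
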