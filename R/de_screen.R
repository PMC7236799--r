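#' Per-gene abundance and differential-expression summaries
#'
#' For every gene computes the quantities that parameterize both RIF and PIF:
#' the average expression x_j over all samples, the condition means x_jS and
#' x_jC, the differential expression d_j = x_jS - x_jC, and a two-sided
#' p-value from the configured two-group test (Welch t by default). All means
#' are taken on the stored log scale.
#'
#' Genes with zero variance in both groups carry no evidence either way; they
#' get p = 1 and \code{degenerate = TRUE} rather than an error. Zero variance
#' in only one group keeps the Welch formula, which stays finite.
#'
#' @param study An \code{ExpressionStudy}.
#' @param config A \code{StudyConfig}; supplies the test and threshold.
#' @return A data.frame with one row per gene and columns \code{gene_id},
#'   \code{x_j}, \code{x_jS}, \code{x_jC}, \code{d_j}, \code{p_value},
#'   \code{is_DE}, \code{degenerate}.
#' @export
summarize_targets <- function(study, config = study_config()) {
  stopifnot(inherits(study, "ExpressionStudy"))
  s_cols <- condition_samples(study, "S")
  c_cols <- condition_samples(study, "C")
  xs <- study$values[, s_cols, drop = FALSE]
  xc <- study$values[, c_cols, drop = FALSE]
  n_s <- length(s_cols); n_c <- length(c_cols)

  m_s <- rowMeans(xs)
  m_c <- rowMeans(xc)
  x_j <- rowMeans(study$values)
  d_j <- m_s - m_c
  v_s <- rowSums((xs - m_s)^2) / (n_s - 1)
  v_c <- rowSums((xc - m_c)^2) / (n_c - 1)

  degenerate <- v_s == 0 & v_c == 0
  if (is.function(config$de_test)) {
    p <- vapply(seq_len(nrow(xs)),
                function(i) config$de_test(xs[i, ], xc[i, ]), numeric(1L))
  } else {
    p <- welch_p(m_s, m_c, v_s, v_c, n_s, n_c)
  }
  p[degenerate] <- 1

  data.frame(gene_id = study$gene_ids,
             x_j = unname(x_j), x_jS = unname(m_s), x_jC = unname(m_c),
             d_j = unname(d_j), p_value = unname(p),
             is_DE = unname(p < config$de_pvalue_threshold),
             degenerate = unname(degenerate),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized Welch two-sample t on precomputed group moments.
welch_p <- function(m_s, m_c, v_s, v_c, n_s, n_c) {
  se2 <- v_s / n_s + v_c / n_c
  tt <- (m_s - m_c) / sqrt(se2)
  df <- se2^2 / ((v_s / n_s)^2 / (n_s - 1) + (v_c / n_c)^2 / (n_c - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0] <- 1
  p
}

#' Select the DE target set
#'
#' Returns exactly the genes whose p-value is strictly below the threshold.
#' The output order follows the input order of the summaries; the selection
#' itself is order-invariant.
#'
#' @param summaries Output of \code{\link{summarize_targets}}.
#' @param threshold Strict upper bound on the p-value.
#' @return The DE subset of \code{summaries}, with attribute \code{n_de}.
#' @export
select_de_targets <- function(summaries, threshold = 0.001) {
  stopifnot(is.data.frame(summaries),
            all(c("gene_id", "p_value") %in% colnames(summaries)))
  de <- summaries[summaries$p_value < threshold, , drop = FALSE]
  if (nrow(de) == 0L)
    stop("no gene passed p < ", threshold,
         "; RIF is undefined over an empty target set - relax the threshold")
  rownames(de) <- NULL
  attr(de, "n_de") <- nrow(de)
  de
}

#' Table behind an MA ("rocket") plot
#'
#' Pure projection of the DE summaries onto the axes of an
#' abundance-versus-differential-expression scatter; no recomputation.
#'
#' @param summaries Output of \code{\link{summarize_targets}}.
#' @return data.frame with columns \code{gene_id}, \code{x_j}, \code{d_j},
#'   \code{is_DE}.
#' @export
export_ma_plot <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  summaries[, c("gene_id", "x_j", "d_j", "is_DE"), drop = FALSE]
}
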