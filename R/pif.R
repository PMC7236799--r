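#' Rank DE targets around a focal regulator
#'
#' For each DE target computes its phenotypic impact factor
#' PIF_j = x_j * d_j (abundance times differential expression) and the signed
#' product PIF_j * |DC_rj| with the absolute differential co-expression to
#' the focal regulator. Because the co-expression term enters as an absolute
#' value, the sign of the product is the sign of the differential expression:
#' positive means higher expression in the treated (S) condition, negative
#' means higher in control (C). The list is sorted ascending, so the most
#' extreme negative products (down in treated, strongly rewired) head the
#' list and the most extreme positives tail it.
#'
#' @param focal_regulator Gene id of the regulator of interest.
#' @param de_targets DE summaries (one row per DE target).
#' @param links Either the link data.frame from
#'   \code{\link{coexpression_links}} (the focal regulator's rows are
#'   extracted) or an \code{ExpressionStudy}, in which case the links are
#'   computed here.
#' @param config A \code{StudyConfig}; \code{pif_variant} selects
#'   \code{"overall_mean"} (x_j, default) or \code{"half_sum"}
#'   ((x_jS + x_jC) / 2) as the abundance term.
#' @return data.frame sorted ascending by product with columns
#'   \code{target_id}, \code{pif_j}, \code{abs_dc}, \code{product},
#'   \code{rank}; ties broken by target id.
#' @export
pif_rank_targets <- function(focal_regulator, de_targets, links,
                             config = study_config()) {
  stopifnot(is.data.frame(de_targets))
  if (inherits(links, "ExpressionStudy"))
    links <- coexpression_links(links, focal_regulator, de_targets, config)
  links <- links[links$regulator_id == focal_regulator, , drop = FALSE]
  if (nrow(links) == 0L)
    stop("focal regulator '", focal_regulator, "' absent from link set")
  links <- check_link_coverage(de_targets, links)
  abundance <- switch(config$pif_variant,
                      overall_mean = de_targets$x_j,
                      half_sum = (de_targets$x_jS + de_targets$x_jC) / 2)
  pif <- abundance * de_targets$d_j
  abs_dc <- abs(links$dc)
  product <- pif * abs_dc
  ord <- order(product, de_targets$gene_id, method = "radix")
  data.frame(target_id = de_targets$gene_id[ord],
             pif_j = pif[ord], abs_dc = abs_dc[ord],
             product = product[ord], rank = seq_along(ord),
             stringsAsFactors = FALSE, row.names = NULL)
}
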