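#' Two-condition expression study
#'
#' Container for a gene-by-sample matrix of normalized, log-scale expression
#' values together with the assignment of each sample to one of two
#' conditions: treated (role \code{"S"}) and control (role \code{"C"}).
#' All downstream statistics (differential expression, differential
#' co-expression, RIF, PIF) are computed on the values exactly as stored;
#' no transformation or normalization is applied by this package.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#'   \code{rownames} are gene identifiers, \code{colnames} sample identifiers;
#'   alternatively supply \code{gene_ids}/\code{sample_ids}.
#' @param condition_of Named character vector mapping every sample id to a
#'   condition label. Exactly two distinct labels must occur.
#' @param gene_ids,sample_ids Optional identifier vectors overriding dimnames.
#' @param treated_label,control_label Which condition label plays the treated
#'   (S) and control (C) role. RIF2 and the differential expression d_j are
#'   antisymmetric in the roles, so the assignment matters. If both are
#'   \code{NULL} the lexically first label is taken as control and the second
#'   as treated, with a message.
#'
#' @return An object of class \code{"ExpressionStudy"}: a list with elements
#'   \code{values} (numeric matrix), \code{gene_ids}, \code{sample_ids},
#'   \code{condition_of} (named vector with levels \code{"S"}/\code{"C"} after
#'   role mapping), and \code{labels} (the original treated/control labels).
#' @export
expression_study <- function(values, condition_of,
                             gene_ids = rownames(values),
                             sample_ids = colnames(values),
                             treated_label = NULL, control_label = NULL) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required (dimnames or explicit)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("matrix dimensions do not match identifier lengths")
  if (length(gene_ids) == 0L)
    stop("study must contain at least one gene")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!is.numeric(values))
    stop("expression values must be numeric")
  if (anyNA(values))
    stop("missing values in expression matrix; drop or impute before loading ",
         "(see read_expression_study(missing = ...))")
  dimnames(values) <- list(gene_ids, sample_ids)

  condition_of <- condition_of[sample_ids]
  if (anyNA(condition_of) || is.null(names(condition_of)))
    stop("samples without a condition assignment: ",
         paste(sample_ids[is.na(condition_of)], collapse = ", "))
  condition_of <- as.character(condition_of)
  names(condition_of) <- sample_ids
  labels <- sort(unique(condition_of))
  if (length(labels) != 2L)
    stop("exactly two condition labels are required, found: ",
         paste(labels, collapse = ", "))

  if (is.null(treated_label) && is.null(control_label)) {
    control_label <- labels[1L]
    treated_label <- labels[2L]
    if (!identical(labels, c("C", "S")))
      message("condition roles assigned by lexical order: control=",
              control_label, ", treated=", treated_label)
  } else {
    if (is.null(treated_label)) treated_label <- setdiff(labels, control_label)
    if (is.null(control_label)) control_label <- setdiff(labels, treated_label)
  }
  if (!all(c(treated_label, control_label) %in% labels) ||
      treated_label == control_label)
    stop("treated/control labels must name the two distinct condition labels")

  roles <- ifelse(condition_of == treated_label, "S", "C")
  names(roles) <- sample_ids
  n_s <- sum(roles == "S"); n_c <- sum(roles == "C")
  if (n_s < 3L || n_c < 3L)
    stop("each condition needs >= 3 samples (correlation is undefined below ",
         "that); got S=", n_s, ", C=", n_c)

  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         condition_of = roles,
         labels = c(treated = treated_label, control = control_label)),
    class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat("ExpressionStudy: ", length(x$gene_ids), " genes x ",
      length(x$sample_ids), " samples (S=", sum(x$condition_of == "S"),
      " [", x$labels[["treated"]], "], C=", sum(x$condition_of == "C"),
      " [", x$labels[["control"]], "])\n", sep = "")
  invisible(x)
}

#' Samples belonging to one condition role
#'
#' @param study An \code{ExpressionStudy}.
#' @param role \code{"S"} (treated) or \code{"C"} (control).
#' @return Character vector of sample ids.
#' @export
condition_samples <- function(study, role = c("S", "C")) {
  role <- match.arg(role)
  names(study$condition_of)[study$condition_of == role]
}

guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a two-condition expression study from delimited text
#'
#' The matrix file carries gene ids in the first column and a header row of
#' sample ids; the conditions file has columns \code{sample_id} and
#' \code{condition}. Samples are reconciled by id, never by position, so the
#' two files may list them in any order.
#'
#' @param matrix_path Path to the expression matrix (TSV by default; files
#'   ending in \code{.csv} are read comma-separated).
#' @param conditions_path Path to the sample-condition table.
#' @param missing Policy for missing cells: \code{"error"} (default) rejects
#'   the file; \code{"drop_genes"} removes genes with any missing value and
#'   reports how many were dropped.
#' @inheritParams expression_study
#' @param sep Field separator; defaults from the file extension.
#' @return An \code{ExpressionStudy}.
#' @export
read_expression_study <- function(matrix_path, conditions_path,
                                  missing = c("error", "drop_genes"),
                                  treated_label = NULL, control_label = NULL,
                                  sep = guess_sep(matrix_path)) {
  missing <- match.arg(missing)
  raw <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character", quote = "\"")
  if (ncol(raw) < 2L)
    stop("matrix file needs a gene-id column plus at least one sample column")
  gene_ids <- raw[[1L]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene ids in ", matrix_path, ": ",
         paste(dup, collapse = ", "))
  sample_ids <- colnames(raw)[-1L]

  cells <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells) &
                 !(trimws(cells) %in% c("", "NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell(s) in ", matrix_path, ": ",
         paste(sprintf("gene %s, sample %s (%s)",
                       gene_ids[bad[, 1L]], sample_ids[bad[, 2L]],
                       cells[bad]),
               collapse = "; "))
  if (anyNA(num)) {
    if (missing == "error")
      stop("missing values in ", matrix_path,
           "; use missing = \"drop_genes\" to remove affected genes")
    keep <- rowSums(is.na(num)) == 0L
    message("dropping ", sum(!keep), " gene(s) with missing values")
    num <- num[keep, , drop = FALSE]
    gene_ids <- gene_ids[keep]
  }
  dimnames(num) <- list(gene_ids, sample_ids)

  cond <- utils::read.table(conditions_path, header = TRUE, sep = "\t",
                            check.names = FALSE, comment.char = "#",
                            colClasses = "character")
  if (!all(c("sample_id", "condition") %in% colnames(cond)))
    stop("conditions file must have columns 'sample_id' and 'condition'")
  only_matrix <- setdiff(sample_ids, cond$sample_id)
  only_table <- setdiff(cond$sample_id, sample_ids)
  if (length(only_matrix) || length(only_table))
    stop("sample reconciliation failed;",
         if (length(only_matrix))
           paste0(" in matrix but not conditions: ",
                  paste(only_matrix, collapse = ", "), ";"),
         if (length(only_table))
           paste0(" in conditions but not matrix: ",
                  paste(only_table, collapse = ", ")))
  condition_of <- stats::setNames(cond$condition, cond$sample_id)

  expression_study(num, condition_of,
                   treated_label = treated_label,
                   control_label = control_label)
}

#' Write an expression study as the matrix/conditions file pair
#'
#' Inverse of \code{\link{read_expression_study}}: gene order, sample order
#' and the original condition labels are preserved, and the written pair
#' re-reads to an identical study up to float round-trip.
#'
#' @param study An \code{ExpressionStudy}.
#' @param matrix_path,conditions_path Output paths.
#' @param sep Field separator for the matrix file.
#' @return Invisibly, the two paths.
#' @export
write_expression_study <- function(study, matrix_path, conditions_path,
                                   sep = guess_sep(matrix_path)) {
  stopifnot(inherits(study, "ExpressionStudy"))
  if (length(study$gene_ids) == 0L)
    stop("refusing to write a study with no genes")
  df <- data.frame(gene_id = study$gene_ids, study$values,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, matrix_path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  orig <- ifelse(study$condition_of == "S",
                 study$labels[["treated"]], study$labels[["control"]])
  cond <- data.frame(sample_id = study$sample_ids,
                     condition = orig[study$sample_ids])
  utils::write.table(cond, conditions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(c(matrix_path, conditions_path))
}
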