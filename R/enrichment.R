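#' Read gene sets from a GMT file
#'
#' One set per line: set id, description, then member ids, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list of unique member-id vectors; per-set descriptions are
#'   kept in the \code{"descriptions"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("malformed GMT line(s) (need id, description, >=1 member): ",
         paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate set ids in ", path)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Hypergeometric enrichment in the extremes of a ranked list
#'
#' For each gene set, scans prefix cutoffs n = step, 2*step, ..., N/2 of the
#' ranked list (suffixes when \code{direction = "tail"}, implemented by
#' reversing the list) and computes the hypergeometric upper tail
#' P(X >= b | N, B, n), where b is the number of set members in the prefix
#' and B the set size within the universe. The minimum over cutoffs and the
#' cutoff achieving it are reported, with Benjamini-Hochberg correction of
#' the minima across sets.
#'
#' The minimum over cutoffs is anti-conservative (no multiple-cutoff
#' correction is applied, unlike the exact mHG statistic); an optional
#' permutation pass estimates an honest empirical p per set.
#'
#' @param ranked_ids Character vector, the ranked universe; ids unique.
#' @param sets Named list of member-id vectors (see \code{\link{read_gmt}}).
#' @param direction \code{"head"} tests the top of the list, \code{"tail"}
#'   the bottom.
#' @param step Cutoff spacing; default \code{max(1, floor(N / 100))}.
#' @param n_permutations If > 0, number of ranked-list permutations used to
#'   compute \code{p_empirical} per set.
#' @param seed Seed for the permutation pass.
#' @return data.frame, one row per set: \code{set_id}, \code{best_cutoff},
#'   \code{b}, \code{B}, \code{N}, \code{p_min}, \code{q} (BH across sets),
#'   \code{flagged} (empty intersection with the universe), and
#'   \code{p_empirical} when permutations were requested.
#' @export
ranked_enrichment <- function(ranked_ids, sets,
                              direction = c("head", "tail"),
                              step = NULL, n_permutations = 0, seed = NULL) {
  direction <- match.arg(direction)
  ranked_ids <- as.character(ranked_ids)
  if (length(ranked_ids) == 0L) stop("empty ranked list")
  if (anyDuplicated(ranked_ids)) stop("ranked list contains duplicate ids")
  if (direction == "tail") ranked_ids <- rev(ranked_ids)
  n_univ <- length(ranked_ids)
  if (is.null(step)) step <- max(1L, floor(n_univ / 100))
  step <- as.integer(step)
  cutoffs <- as.integer(seq.int(step, max(step, floor(n_univ / 2)), by = step))

  scan_one <- function(members) {
    members <- intersect(members, ranked_ids)
    b_size <- length(members)
    if (b_size == 0L)
      return(list(best_cutoff = NA_integer_, b = 0L, B = 0L,
                  p_min = 1, flagged = TRUE))
    cum_b <- cumsum(ranked_ids %in% members)
    b_at <- cum_b[cutoffs]
    p_at <- stats::phyper(b_at - 1L, b_size, n_univ - b_size, cutoffs,
                          lower.tail = FALSE)
    k <- which.min(p_at)
    list(best_cutoff = cutoffs[k], b = b_at[k], B = b_size,
         p_min = p_at[k], flagged = FALSE)
  }

  rows <- lapply(sets, scan_one)
  res <- data.frame(
    set_id = names(sets),
    best_cutoff = vapply(rows, `[[`, 0L, "best_cutoff"),
    b = vapply(rows, function(r) as.integer(r$b), 0L),
    B = vapply(rows, `[[`, 0L, "B"),
    N = n_univ,
    p_min = vapply(rows, `[[`, 0, "p_min"),
    flagged = vapply(rows, `[[`, FALSE, "flagged"),
    stringsAsFactors = FALSE, row.names = NULL)
  res$q <- stats::p.adjust(res$p_min, method = "BH")

  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    mins <- matrix(NA_real_, nrow = n_permutations, ncol = length(sets))
    for (i in seq_len(n_permutations)) {
      perm <- sample(ranked_ids)
      for (s in seq_along(sets)) {
        members <- intersect(sets[[s]], ranked_ids)
        if (length(members) == 0L) { mins[i, s] <- 1; next }
        cum_b <- cumsum(perm %in% members)
        mins[i, s] <- min(stats::phyper(
          cum_b[cutoffs] - 1L, length(members),
          n_univ - length(members), cutoffs, lower.tail = FALSE))
      }
    }
    res$p_empirical <- vapply(seq_along(sets), function(s)
      (1 + sum(mins[, s] <= res$p_min[s])) / (n_permutations + 1), 0)
  }
  res[, c("set_id", "best_cutoff", "b", "B", "N", "p_min", "q", "flagged",
          if (n_permutations > 0) "p_empirical"), drop = FALSE]
}
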