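# Ultraconservation and sequence-identity summaries.

#' Maximal perfect-identity runs in an alignment
#'
#' Finds maximal runs of columns where all rows are identical and none is a
#' gap — the defining signature of ultraconserved elements (>= 200 nt of
#' perfect identity between distant genomes). Gaps break runs: a gap is not
#' identity.
#'
#' @param aln Named character vector of two or more equal-length aligned
#'   sequences.
#' @param min_len Minimum run length in columns (default 200, the classical
#'   ultraconservation cutoff).
#' @return Data frame `start`, `end` (0-based half-open alignment columns),
#'   `length`, plus per-sequence gap-excluded start coordinates in columns
#'   `start_in_<name>`.
#' @export
perfect_identity_runs <- function(aln, min_len = 200L) {
  if (length(aln) < 2) sv_stop("need at least two sequences", "input_error")
  lens <- nchar(aln)
  if (length(unique(lens)) != 1) sv_stop("aligned rows differ in length", "input_error")
  m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  agree <- colSums(m == m[rep(1L, nrow(m)), , drop = FALSE]) == nrow(m) &
    m[1L, ] != "-"
  r <- rle(agree)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep])
  # gap-excluded per-sequence coordinates of each run start
  if (nrow(out) && !is.null(names(aln))) {
    for (i in seq_along(aln)) {
      nongap_before <- cumsum(m[i, ] != "-")
      out[[paste0("start_in_", names(aln)[i])]] <-
        ifelse(out$start == 0L, 0L, nongap_before[out$start])
    }
  }
  rownames(out) <- NULL
  out
}

#' Smoothed per-column identity profile of an alignment
#'
#' Per column, the fraction of row pairs that agree (gaps count as
#' disagreement, including gap-gap pairs), smoothed by a centered moving
#' average. Edge columns average over the available part of the window.
#'
#' @param aln Named character vector of aligned sequences (>= 2 rows).
#' @param window Smoothing window in columns (default 25; purely
#'   presentational).
#' @return Numeric vector, one value per alignment column.
#' @export
column_identity_profile <- function(aln, window = 25L) {
  if (length(aln) < 2) sv_stop("need at least two sequences", "input_error")
  if (length(unique(nchar(aln))) != 1) sv_stop("aligned rows differ in length", "input_error")
  m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  n <- nrow(m)
  npairs <- n * (n - 1) / 2
  raw <- apply(m, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) < 2) return(0)
    sum(choose(table(col), 2)) / npairs
  })
  half <- window %/% 2L
  cs <- c(0, cumsum(raw))
  idx <- seq_along(raw)
  lo <- pmax(idx - half, 1L); hi <- pmin(idx + half, length(raw))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Percentile of an intron length within a length distribution
#'
#' Answers "is this intron in the longest q fraction?" — e.g. the fungal
#' retained intron sits in the longest 1% of its genome's introns.
#'
#' @param lengths Vector of intron lengths (nt).
#' @param query Query intron length (nt, > 0).
#' @return List with `percentile` (fraction strictly shorter than the query)
#'   and `top_fraction` (fraction >= query); the query is "in the longest q"
#'   iff `top_fraction <= q`.
#' @export
intron_length_percentile <- function(lengths, query) {
  if (length(lengths) == 0) sv_stop("empty length distribution", "input_error")
  if (query <= 0) sv_stop("query length must be positive", "input_error")
  list(percentile = mean(lengths < query),
       top_fraction = mean(lengths >= query))
}
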