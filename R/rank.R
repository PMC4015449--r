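#' Summarize one spread's class labels
#'
#' Tallies the four class counts and derives `n_individual`, the number of
#' individually separable chromosomes (Class 1 + Class 2) — the primary
#' ranking key for karyotyping suitability.
#'
#' @param image_id Identifier (typically the image file name).
#' @param labels Data frame from [classify_spread()] (column `class`), or
#'   an integer vector of class labels.
#' @param stats Optional [width_stats()] result; its `fallback_used` flag
#'   is carried into the summary.
#' @return One-row data frame: `image_id`, `n_class1` .. `n_class4`,
#'   `n_individual`, `fallback_used`.
#' @export
summarize_spread <- function(image_id, labels, stats = NULL) {
  cls <- if (is.data.frame(labels)) labels$class else as.integer(labels)
  stopifnot(all(cls %in% 1:4))
  n <- tabulate(cls, nbins = 4L)
  data.frame(image_id = as.character(image_id),
             n_class1 = n[1L], n_class2 = n[2L],
             n_class3 = n[3L], n_class4 = n[4L],
             n_individual = n[1L] + n[2L],
             fallback_used = isTRUE(stats$fallback_used),
             stringsAsFactors = FALSE)
}

#' Rank spreads by karyotyping suitability
#'
#' Orders spread summaries by `n_individual` descending. Ties are broken by
#' `n_class3` (more is better under the published guidance: touching or
#' overlapping clusters hold chromosomes recoverable by manual editing),
#' then by `n_class4` ascending (less debris is better), and finally by
#' `image_id` lexicographically so the ranking is fully deterministic.
#' Users who consider the Class-3 direction a mistake can flip it with
#' `class3_more_better = FALSE`.
#'
#' @param summaries Data frame of rows from [summarize_spread()]; image ids
#'   must be unique.
#' @param class3_more_better Direction of the Class-3 tie-break
#'   (default `TRUE`, the published rule).
#' @return The input rows reordered, with a 1-based `rank` column prepended.
#' @export
rank_spreads <- function(summaries, class3_more_better = TRUE) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1L)
  if (anyDuplicated(summaries$image_id))
    stop("duplicate image_id in summaries")
  c3 <- if (class3_more_better) -summaries$n_class3 else summaries$n_class3
  ord <- order(-summaries$n_individual, c3, summaries$n_class4,
               summaries$image_id, method = "radix")
  out <- summaries[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}
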