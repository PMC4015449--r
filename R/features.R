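#' Per-object geometric features of a vertically oriented mask
#'
#' Reads the enclosing-rectangle dimensions off the tight crop and derives
#' the absolute shape quantities used by the rule tree:
#' * `A_o` — object pixel count;
#' * `W_rect`, `H_rect` — width and height of the smallest enclosing
#'   rectangle (the crop), in pixels;
#' * `area_ratio` — `A_o / (W_rect * H_rect)`, the rectangle fill fraction;
#' * `W_i` — `A_o / H_rect`, the average per-row object width;
#' * `W_max` — the maximum per-row foreground pixel count.
#'
#' @param obj An `oriented_object` from [orient_vertical()].
#' @return One-row data frame with columns `object_id`, `A_o`, `W_rect`,
#'   `H_rect`, `area_ratio`, `W_i`, `W_max`.
#' @export
basic_features <- function(obj) {
  mask <- obj$mask
  if (is.null(mask) || sum(mask) == 0L) stop("empty mask")
  A_o <- sum(mask)
  H_rect <- nrow(mask)
  W_rect <- ncol(mask)
  data.frame(object_id = obj$object_id,
             A_o = A_o,
             W_rect = W_rect,
             H_rect = H_rect,
             area_ratio = A_o / (W_rect * H_rect),
             W_i = A_o / H_rect,
             W_max = as.integer(max(rowSums(mask))))
}

#' Image-level average chromosome width
#'
#' The reference width `W_avg` is estimated in two passes over the straight
#' candidates (objects whose `area_ratio` exceeds `gate`): first the
#' preliminary mean of their `W_i`; then objects wider than
#' `discard_factor` times that mean are excluded (they are typically large
#' residues) and `W_avg` is the mean `W_i` over the surviving set `O_w`.
#' If no object passes the gate, `W_avg` falls back to the median `W_i`
#' over all objects and `fallback_used` is set.
#'
#' @param features Data frame of per-object features from
#'   [basic_features()] (rows may be in any order).
#' @param gate Area-ratio gate for straight candidates (default 0.6784).
#' @param discard_factor Width-discard multiplier (default 1.5).
#' @return List with `straight_candidate_ids`, `prelim_avg_width`,
#'   `O_w_ids`, `W_avg`, `fallback_used`.
#' @export
width_stats <- function(features, gate = 0.6784, discard_factor = 1.5) {
  stopifnot(is.data.frame(features), nrow(features) >= 1L,
            gate > 0, gate < 1, discard_factor > 1)
  cand <- features$object_id[features$area_ratio > gate]
  if (length(cand) == 0L) {
    return(list(straight_candidate_ids = integer(0),
                prelim_avg_width = NA_real_,
                O_w_ids = integer(0),
                W_avg = median(features$W_i),
                fallback_used = TRUE))
  }
  w_cand <- features$W_i[match(cand, features$object_id)]
  prelim <- mean(w_cand)
  keep <- w_cand <= discard_factor * prelim
  ow <- cand[keep]
  list(straight_candidate_ids = cand,
       prelim_avg_width = prelim,
       O_w_ids = ow,
       W_avg = mean(w_cand[keep]),
       fallback_used = FALSE)
}

#' Complete per-object features with image-relative ratios
#'
#' Fills the ratios that depend on the image-level average width:
#' `Wrect_ratio = W_rect / W_avg`, `H_i = A_o / W_avg`,
#' `Hi_ratio = H_i / H_rect`, and `Wmax_ratio = W_max / W_avg`.
#'
#' @param features Data frame from [basic_features()] (one or more rows).
#' @param stats Image width statistics from [width_stats()].
#' @return `features` with the four ratio columns appended.
#' @export
relative_features <- function(features, stats) {
  if (!is.finite(stats$W_avg) || stats$W_avg <= 0)
    stop("W_avg must be positive")
  features$Wrect_ratio <- features$W_rect / stats$W_avg
  features$H_i <- features$A_o / stats$W_avg
  features$Hi_ratio <- features$H_i / features$H_rect
  features$Wmax_ratio <- features$W_max / stats$W_avg
  features
}

#' Full feature table for one spread
#'
#' Convenience wrapper: [basic_features()] for every oriented object,
#' [width_stats()] over the image, then [relative_features()].
#'
#' @param objects List of `oriented_object`s.
#' @param gate,discard_factor Passed to [width_stats()].
#' @return List with `features` (completed data frame, one row per object)
#'   and `stats` (the [width_stats()] result).
#' @export
compute_features <- function(objects, gate = 0.6784, discard_factor = 1.5) {
  if (length(objects) == 0L)
    return(list(features = .empty_features(), stats = NULL))
  feats <- do.call(rbind, lapply(objects, basic_features))
  stats <- width_stats(feats, gate = gate, discard_factor = discard_factor)
  list(features = relative_features(feats, stats), stats = stats)
}

.empty_features <- function() {
  data.frame(object_id = integer(0), A_o = integer(0), W_rect = integer(0),
             H_rect = integer(0), area_ratio = numeric(0), W_i = numeric(0),
             W_max = numeric(0), Wrect_ratio = numeric(0), H_i = numeric(0),
             Hi_ratio = numeric(0), Wmax_ratio = numeric(0))
}
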