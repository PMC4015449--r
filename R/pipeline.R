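#' Run the full classification pipeline on one grayscale spread
#'
#' Segments foreground objects at the Otsu threshold of the original
#' image, rotates each object to vertical, computes the shape-feature
#' table, and applies the rule tree. This is the per-image unit of work
#' used by the batch driver and the validation harness.
#'
#' Thresholding runs on the original rather than the equalized image:
#' histogram equalization is a monotone intensity remap, so it cannot
#' improve the foreground/background separation that Otsu's criterion
#' measures, and on fields dominated by background it stretches the
#' background mode until the maximal-variance split falls inside it.
#' [equalize()] remains available as a display/contrast enhancement.
#'
#' @param img Integer matrix of intensities in \[0, 255\].
#' @param thresholds A [rule_thresholds()] object.
#' @param min_object_px Minimum component size kept (pixels).
#' @return List with `objects` (segmented objects), `oriented`, `features`
#'   (completed data frame), `stats` ([width_stats()] result) and `labels`
#'   (data frame from [classify_spread()]).
#' @export
classify_spread_image <- function(img, thresholds = rule_thresholds(),
                                  min_object_px = 20L) {
  objs <- segment_objects(img, min_object_px = min_object_px)
  oriented <- lapply(objs, orient_vertical)
  fs <- compute_features(oriented,
                         gate = thresholds$area_gate,
                         discard_factor = thresholds$discard_factor)
  labels <- classify_spread(fs$features, thresholds)
  list(objects = objs, oriented = oriented, features = fs$features,
       stats = fs$stats, labels = labels)
}
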