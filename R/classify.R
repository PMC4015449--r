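#' Decision-rule thresholds
#'
#' The five decision constants of the chromosome classification rule tree
#' plus the width-discard factor. Defaults are the published constants,
#' each originally derived as the intercept of two class-conditional
#' Gaussian densities fitted to labeled samples (see [calibrate_threshold()]
#' to re-derive them from your own data):
#'
#' * `area_gate` (0.6784) — rectangle fill fraction above which an object
#'   enters the straight branch;
#' * `wrect_lo`, `wrect_hi` (0.9897, 1.5597) — the `Wrect_ratio` band of a
#'   straight individual chromosome; below it small residue, above it large
#'   residue;
#' * `hi_min` (0.7507) — `Hi_ratio` below which an object in the
#'   skewed/overlap branch is residue;
#' * `wmax_gate` (2.3453) — `Wmax_ratio` above which it is a
#'   touching/overlapping cluster rather than a skewed individual;
#' * `discard_factor` (1.5) — `W_i` multiple of the preliminary average
#'   width above which an object is excluded from the width-averaging set.
#'
#' `gate_feature` selects which feature is compared against `area_gate` at
#' the root of the tree. The source text is ambiguous at one point (a
#' sentence gates the skewed/overlap branch on `Wrect_ratio` where the
#' flowchart and all surrounding text use the area ratio); the default
#' `"area_ratio"` follows the flowchart, `"wrect_ratio"` implements the
#' alternative reading.
#'
#' @param area_gate,wrect_lo,wrect_hi,hi_min,wmax_gate,discard_factor
#'   Numeric thresholds, see above. `area_gate` is a fraction in (0, 1);
#'   reports render it as a percentage.
#' @param gate_feature `"area_ratio"` (default) or `"wrect_ratio"`.
#' @return A `rule_thresholds` list.
#' @export
#' @examples
#' t <- rule_thresholds()
#' t$area_gate
rule_thresholds <- function(area_gate = 0.6784,
                            wrect_lo = 0.9897,
                            wrect_hi = 1.5597,
                            hi_min = 0.7507,
                            wmax_gate = 2.3453,
                            discard_factor = 1.5,
                            gate_feature = c("area_ratio", "wrect_ratio")) {
  gate_feature <- match.arg(gate_feature)
  stopifnot(area_gate > 0, area_gate < 1,
            wrect_lo > 0, wrect_lo < wrect_hi,
            hi_min > 0, wmax_gate > 1, discard_factor > 1)
  structure(list(area_gate = area_gate, wrect_lo = wrect_lo,
                 wrect_hi = wrect_hi, hi_min = hi_min,
                 wmax_gate = wmax_gate, discard_factor = discard_factor,
                 gate_feature = gate_feature),
            class = "rule_thresholds")
}

# Vectorized rule tree over a completed feature data frame. Returns a data
# frame with integer `class` and character `subtype` (NA except Class 4).
# Boundary semantics follow the published inequalities: strict > at the
# area gate, inclusive Wrect_ratio band, strict < for the residue cutoff,
# strict > for the overlap gate.
.rule_labels <- function(features, thresholds) {
  req <- c("area_ratio", "Wrect_ratio", "Hi_ratio", "Wmax_ratio")
  miss <- setdiff(req, names(features))
  if (length(miss) > 0L)
    stop("incomplete features: missing ", paste(miss, collapse = ", "))
  if (anyNA(features[req]))
    stop("incomplete features: NA values present")
  gate_val <- if (thresholds$gate_feature == "area_ratio")
    features$area_ratio else features$Wrect_ratio
  straight <- gate_val > thresholds$area_gate
  wr <- features$Wrect_ratio
  cls <- ifelse(straight,
                ifelse(wr < thresholds$wrect_lo, 4L,
                       ifelse(wr > thresholds$wrect_hi, 4L, 1L)),
                ifelse(features$Hi_ratio < thresholds$hi_min, 4L,
                       ifelse(features$Wmax_ratio > thresholds$wmax_gate,
                              3L, 2L)))
  sub <- rep(NA_character_, length(cls))
  sub[straight & wr < thresholds$wrect_lo] <- "small_residue"
  sub[straight & wr > thresholds$wrect_hi] <- "large_residue"
  sub[!straight & features$Hi_ratio < thresholds$hi_min] <- "short_residue"
  data.frame(class = as.integer(cls), subtype = sub,
             stringsAsFactors = FALSE)
}

#' Classify one object by the rule tree
#'
#' Applies the four-class decision rule to a completed feature vector:
#' straight individual chromosome (1), skewed individual chromosome (2),
#' touching/overlapping chromosomes (3), or non-chromosome residue (4).
#' Class 4 carries a `subtype` tag (`small_residue`, `large_residue` or
#' `short_residue`) identifying which branch rejected the object.
#'
#' @param f A one-row data frame (or coercible list) with `area_ratio`,
#'   `Wrect_ratio`, `Hi_ratio`, `Wmax_ratio`.
#' @param thresholds A [rule_thresholds()] object.
#' @return List with `value` (integer class) and `subtype` (character or
#'   `NA`).
#' @export
#' @examples
#' classify_object(data.frame(area_ratio = 0.8, Wrect_ratio = 1.2,
#'                            Hi_ratio = 1, Wmax_ratio = 1.2),
#'                 rule_thresholds())
classify_object <- function(f, thresholds = rule_thresholds()) {
  if (!is.data.frame(f)) f <- as.data.frame(f)
  stopifnot(nrow(f) == 1L)
  lab <- .rule_labels(f, thresholds)
  list(value = lab$class[1L], subtype = lab$subtype[1L])
}

#' Classify every object of a spread
#'
#' @param features Completed feature data frame (all objects measured
#'   against the same image-level width statistics).
#' @param thresholds A [rule_thresholds()] object.
#' @return Data frame with `object_id`, `class`, `subtype`; input order
#'   preserved.
#' @export
classify_spread <- function(features, thresholds = rule_thresholds()) {
  if (nrow(features) == 0L)
    return(data.frame(object_id = integer(0), class = integer(0),
                      subtype = character(0), stringsAsFactors = FALSE))
  lab <- .rule_labels(features, thresholds)
  data.frame(object_id = features$object_id, class = lab$class,
             subtype = lab$subtype, stringsAsFactors = FALSE)
}

#' Read rule thresholds from a key/value config file
#'
#' The file holds `key = value` lines (hash comments allowed); keys match
#' the [rule_thresholds()] field names. Missing keys keep their defaults.
#'
#' @param path Path to the config file.
#' @return A `rule_thresholds` object.
#' @export
read_thresholds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  args <- formals(rule_thresholds)
  unknown <- setdiff(keys, names(args))
  if (length(unknown) > 0L)
    stop("unknown config key: ", paste(unknown, collapse = ", "))
  spec <- as.list(setNames(vals, keys))
  num <- setdiff(keys, "gate_feature")
  spec[num] <- lapply(spec[num], as.numeric)
  do.call(rule_thresholds, spec)
}

#' Write rule thresholds to a key/value config file
#'
#' @param thresholds A [rule_thresholds()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  num <- setdiff(names(thresholds), "gate_feature")
  lines <- c(sprintf("%s = %.10g", num, unlist(thresholds[num])),
             sprintf("gate_feature = %s", thresholds$gate_feature))
  writeLines(lines, path)
  invisible(path)
}
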