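#' trizone: trichotomization of quantitative diagnostic tests
#'
#' Tools for partitioning the score range of a quantitative diagnostic test
#' into negative, inconclusive and positive decision zones. Three methods are
#' implemented: TG-ROC ([tgroc_zones()]), the grey-zone method
#' ([grey_zone()]) and the uncertain-interval method ([ui_binormal()],
#' [ui_nonparametric()]), together with the Bayes/likelihood-ratio
#' calculations that connect pre-test probability, sensitivity, specificity
#' and post-test probability ([required_lrs()], [posttest_probs()]),
#' evaluation of trichotomized decisions ([three_by_two()],
#' [outer_metrics()]), a decision-reliability simulator
#' ([simulate_retest()]) and synthetic bi-normal data generators
#' ([sample_binormal()], [synth_fixture()]).
#'
#' @keywords internal
"_PACKAGE"

DIRECTIONS <- c("higher", "lower")

match_direction <- function(direction) {
  match.arg(direction, DIRECTIONS)
}

#' Bi-normal model of a diagnostic marker
#'
#' Describes a marker whose scores are normally distributed within the
#' non-diseased class (`mu0`, `sd0`) and within the diseased class
#' (`mu1`, `sd1`). `direction` states which side of the scale indicates
#' disease: `"higher"` when diseased subjects tend to score higher (e.g.
#' serum creatine kinase for muscular dystrophy carriers), `"lower"` when
#' they tend to score lower (e.g. reticulocyte haemoglobin content in iron
#' deficiency).
#'
#' @param mu0,sd0 Mean and standard deviation of the non-diseased scores.
#' @param mu1,sd1 Mean and standard deviation of the diseased scores.
#' @param direction `"higher"` if higher scores indicate disease,
#'   `"lower"` otherwise.
#' @return An object of class `binormal_model`.
#' @examples
#' binormal_model(0, 1, 2, 1)
#' @seealso [fit_binormal()] to estimate a model from data, [orient()].
#' @export
binormal_model <- function(mu0, sd0, mu1, sd1, direction = c("higher", "lower")) {
  direction <- match_direction(direction)
  stopifnot(is.numeric(mu0), is.numeric(sd0), is.numeric(mu1), is.numeric(sd1),
            length(mu0) == 1, length(sd0) == 1, length(mu1) == 1, length(sd1) == 1)
  if (!all(is.finite(c(mu0, sd0, mu1, sd1)))) {
    stop("model parameters must be finite", call. = FALSE)
  }
  if (sd0 <= 0 || sd1 <= 0) {
    stop("standard deviations must be strictly positive", call. = FALSE)
  }
  structure(list(mu0 = mu0, sd0 = sd0, mu1 = mu1, sd1 = sd1,
                 direction = direction),
            class = "binormal_model")
}

#' @export
print.binormal_model <- function(x, ...) {
  cat("Bi-normal marker model (", x$direction, " scores indicate disease)\n",
      sep = "")
  cat(sprintf("  non-diseased: N(%g, %g)\n  diseased:     N(%g, %g)\n",
              x$mu0, x$sd0, x$mu1, x$sd1))
  invisible(x)
}

#' Labeled diagnostic score sample
#'
#' Pairs a numeric score vector with binary disease labels. Labels must be
#' coded exactly 0 (non-diseased) and 1 (diseased); any other coding is
#' rejected rather than coerced, so data errors surface at ingestion.
#'
#' @param scores Numeric vector of test scores; must be finite.
#' @param labels Vector of 0/1 disease labels, same length as `scores`.
#' @param direction `"higher"` if higher scores indicate disease,
#'   `"lower"` otherwise.
#' @return An object of class `labeled_sample` with elements `scores`,
#'   `labels` and `direction`.
#' @examples
#' labeled_sample(c(1.2, 3.4, 2.8), c(0, 1, 1))
#' @export
labeled_sample <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match_direction(direction)
  if (!is.numeric(scores)) stop("scores must be numeric", call. = FALSE)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length", call. = FALSE)
  }
  if (anyNA(scores) || !all(is.finite(scores))) {
    stop("scores must be finite and non-missing", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("labels must be coded exactly 0 (non-diseased) or 1 (diseased)",
         call. = FALSE)
  }
  structure(list(scores = as.numeric(scores), labels = as.integer(labels),
                 direction = direction),
            class = "labeled_sample")
}

#' @export
print.labeled_sample <- function(x, ...) {
  n1 <- sum(x$labels == 1L)
  cat(sprintf("Labeled sample: %d diseased, %d non-diseased (%s scores indicate disease)\n",
              n1, length(x$labels) - n1, x$direction))
  invisible(x)
}

#' Decision zones: the two cut-points of a trichotomized test
#'
#' A pair of thresholds `lower <= upper` defining a closed inconclusive band
#' `[lower, upper]` on the ORIGINAL score scale. After orientation (so that
#' higher scores indicate disease), scores strictly below `lower` give a
#' negative decision, scores strictly above `upper` a positive decision, and
#' scores in the closed band are inconclusive. The closed band means a score
#' lying exactly on a cut-point is treated as not yet conclusive, which
#' reproduces the behaviour of discrete-score tests where a threshold score
#' itself belongs to the uncertain middle section.
#'
#' @param lower,upper The two cut-points on the original score scale.
#'   For a `"lower"`-direction marker `lower` is the boundary of the
#'   positive (diseased) zone and `upper` of the negative zone; decisions
#'   are still produced correctly by [trichotomize()].
#' @param direction Score direction the zones belong to.
#' @param collapsed Logical flag: `TRUE` when a method found no inconclusive
#'   band to be necessary and collapsed the zones to a single cut-point.
#' @return An object of class `decision_zones`.
#' @examples
#' z <- decision_zones(4, 6)
#' trichotomize(c(1, 5, 9), z)
#' @export
decision_zones <- function(lower, upper, direction = c("higher", "lower"),
                           collapsed = FALSE) {
  direction <- match_direction(direction)
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1, length(upper) == 1)
  if (is.na(lower) || is.na(upper)) stop("zone boundaries must not be NA", call. = FALSE)
  if (lower > upper) {
    stop("lower zone boundary must not exceed upper boundary", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, direction = direction,
                 collapsed = isTRUE(collapsed)),
            class = "decision_zones")
}

#' @export
print.decision_zones <- function(x, ...) {
  if (x$collapsed) {
    cat(sprintf("Decision zones: collapsed to single cut-point %g (no inconclusive band; %s scores indicate disease)\n",
                x$lower, x$direction))
  } else {
    cat(sprintf("Decision zones: inconclusive band [%g, %g] (%s scores indicate disease)\n",
                x$lower, x$upper, x$direction))
  }
  invisible(x)
}

#' Orient a sample, model or zones so higher scores indicate disease
#'
#' All threshold mathematics in the package assumes the diseased class sits
#' above the non-diseased class on the score scale. `orient()` maps an
#' object onto that convention by negating scores (and means) when its
#' direction is `"lower"`; already-oriented objects are returned unchanged.
#' The negation is self-inverse, so thresholds computed on the oriented
#' scale map back to the original scale by negating and swapping the two
#' zone boundaries — which is exactly what `orient()` does to a
#' `decision_zones` object.
#'
#' @param x A `labeled_sample`, `binormal_model` or `decision_zones`.
#' @return The same class of object with `direction = "higher"`.
#' @examples
#' orient(binormal_model(2, 1, 0, 1, direction = "lower"))
#' @export
orient <- function(x) UseMethod("orient")

#' @export
orient.binormal_model <- function(x) {
  if (x$direction == "higher") return(x)
  binormal_model(-x$mu0, x$sd0, -x$mu1, x$sd1, direction = "higher")
}

#' @export
orient.labeled_sample <- function(x) {
  if (x$direction == "higher") return(x)
  labeled_sample(-x$scores, x$labels, direction = "higher")
}

#' @export
orient.decision_zones <- function(x) {
  if (x$direction == "higher") return(x)
  decision_zones(-x$upper, -x$lower, direction = "higher",
                 collapsed = x$collapsed)
}

# Map oriented-scale zones back onto the original scale of `direction`.
unorient_zones <- function(lower, upper, direction, collapsed = FALSE) {
  if (direction == "higher") {
    decision_zones(lower, upper, "higher", collapsed)
  } else {
    decision_zones(-upper, -lower, "lower", collapsed)
  }
}

# Oriented-scale boundaries of a decision_zones object.
oriented_bounds <- function(zones) {
  if (zones$direction == "higher") {
    c(zones$lower, zones$upper)
  } else {
    c(-zones$upper, -zones$lower)
  }
}

#' Trichotomize scores into negative / inconclusive / positive decisions
#'
#' Applies the closed-band convention of [decision_zones()]: after
#' orientation, a score strictly below the band is negative, strictly above
#' it positive, and inside the closed band inconclusive.
#'
#' @param x A numeric score vector (assumed to share the zones' direction)
#'   or a `labeled_sample`.
#' @param zones A `decision_zones` object.
#' @return A factor of decisions with levels
#'   `negative`, `inconclusive`, `positive`, one per score.
#' @examples
#' trichotomize(c(1, 5, 9), decision_zones(4, 6))
#' @export
trichotomize <- function(x, zones) {
  stopifnot(inherits(zones, "decision_zones"))
  if (inherits(x, "labeled_sample")) {
    if (x$direction != zones$direction) {
      stop("sample and zones have conflicting score directions", call. = FALSE)
    }
    s <- x$scores
  } else {
    s <- as.numeric(x)
  }
  if (anyNA(s) || !all(is.finite(s))) {
    stop("scores must be finite and non-missing", call. = FALSE)
  }
  if (zones$direction == "lower") s <- -s
  b <- oriented_bounds(zones)
  dec <- ifelse(s < b[1], "negative", ifelse(s > b[2], "positive", "inconclusive"))
  factor(dec, levels = c("negative", "inconclusive", "positive"))
}

#' Read a labeled score sample from a delimited text file
#'
#' Expects a header row and (at least) a numeric score column and a 0/1
#' label column. Every invalid row is reported with its line number and
#' ingestion aborts, rather than silently dropping or coercing records.
#'
#' @param path Path to the file.
#' @param delim Field delimiter (default tab).
#' @param score_col,label_col Column names holding the score and the label.
#' @param direction Score direction of the marker.
#' @return A [labeled_sample()].
#' @export
read_scores <- function(path, delim = "\t", score_col = "score",
                        label_col = "label",
                        direction = c("higher", "lower")) {
  direction <- match_direction(direction)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  for (col in c(score_col, label_col)) {
    if (!col %in% names(raw)) {
      stop(sprintf("column '%s' not found in %s", col, path), call. = FALSE)
    }
  }
  score <- suppressWarnings(as.numeric(raw[[score_col]]))
  label <- suppressWarnings(as.numeric(raw[[label_col]]))
  bad <- which(!is.finite(score) | is.na(label) | !(label %in% c(0, 1)))
  if (length(bad)) {
    # +1: header occupies line 1
    stop(sprintf("invalid rows in %s at line(s): %s", path,
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  labeled_sample(score, label, direction = direction)
}

#' Write a labeled sample to a delimited text file
#'
#' Inverse of [read_scores()]; used by the `simulate` command-line
#' subcommand to emit fixture files.
#'
#' @param sample A `labeled_sample`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_scores <- function(sample, path, delim = "\t") {
  stopifnot(inherits(sample, "labeled_sample"))
  df <- data.frame(score = sample$scores, label = sample$labels)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared input checks -------------------------------------------------------

check_probability <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stop(sprintf("%s must be a single number", name), call. = FALSE)
  }
  if (open) {
    if (x <= 0 || x >= 1) stop(sprintf("%s must lie strictly in (0, 1)", name),
                               call. = FALSE)
  } else {
    if (x < 0 || x > 1) stop(sprintf("%s must lie in [0, 1]", name),
                             call. = FALSE)
  }
  invisible(x)
}

# Oriented model must have the diseased mean above the non-diseased mean for
# any thresholding operation to make sense.
check_separated <- function(model) {
  if (model$mu1 <= model$mu0) {
    stop("after orientation the diseased mean must exceed the non-diseased mean",
         call. = FALSE)
  }
  invisible(model)
}

split_classes <- function(sample) {
  list(s0 = sample$scores[sample$labels == 0L],
       s1 = sample$scores[sample$labels == 1L])
}

check_both_classes <- function(sample) {
  cl <- split_classes(sample)
  if (length(cl$s0) == 0 || length(cl$s1) == 0) {
    stop("sample must contain at least one record of each class", call. = FALSE)
  }
  cl
}
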