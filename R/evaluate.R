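# 3 x 2 tables and outer-section performance of trichotomized decisions.

#' Cross-tabulate trichotomized decisions against disease status
#'
#' Builds the 3 x 2 table of decisions (negative / inconclusive / positive)
#' by disease status (0 / 1), the natural report for a test whose
#' inconclusive results are kept visible instead of being discarded or
#' folded into one of the decision arms.
#'
#' @param sample A `labeled_sample`.
#' @param zones A `decision_zones` object (same direction as the sample).
#' @return An integer matrix of class `table` with rows
#'   `negative`, `inconclusive`, `positive` and columns `0`, `1`.
#' @examples
#' s <- labeled_sample(c(1, 2, 5, 6, 9, 10), c(0, 0, 0, 1, 1, 1))
#' three_by_two(s, decision_zones(4, 7))
#' @export
three_by_two <- function(sample, zones) {
  stopifnot(inherits(sample, "labeled_sample"))
  dec <- trichotomize(sample, zones)
  table(decision = dec, disease = factor(sample$labels, levels = c(0, 1)))
}

new_outer_metrics <- function(proportion, prevalence, se, sp, accuracy, yield) {
  structure(list(proportion = proportion, prevalence = prevalence,
                 se = se, sp = sp, accuracy = accuracy, yield = yield),
            class = "outer_metrics")
}

#' @export
print.outer_metrics <- function(x, ...) {
  cat("Outer-section metrics (decided records only):\n")
  cat(sprintf("  proportion decided %.4f, prevalence %.4f\n",
              x$proportion, x$prevalence))
  cat(sprintf("  se %.4f, sp %.4f, accuracy %.4f, net yield %.4f\n",
              x$se, x$sp, x$accuracy, x$yield))
  invisible(x)
}

#' Outer-section metrics from a 3 x 2 table
#'
#' Summarizes the performance of the decisions actually made, i.e. the
#' records falling outside the inconclusive band: the proportion of all
#' records receiving a decision, the prevalence among them, sensitivity,
#' specificity and accuracy over the decided records, and the net yield —
#' correctly diagnosed records as a fraction of ALL records, so that
#' `yield = accuracy * proportion`. Because trichotomization can deselect
#' the two classes unequally, the outer-section prevalence generally
#' differs from the whole-sample prevalence.
#'
#' @param tab A 3 x 2 table from [three_by_two()] (rows negative /
#'   inconclusive / positive; columns non-diseased / diseased).
#' @param total_n Total number of records the table was built from
#'   (defaults to the table sum).
#' @return An object of class `outer_metrics`. A zero denominator for
#'   `se` or `sp` (no diseased, or no non-diseased, among the decided)
#'   yields `NA` for that field with a warning rather than a silent 0.
#' @export
outer_metrics <- function(tab, total_n = sum(tab)) {
  stopifnot(is.table(tab) || is.matrix(tab), nrow(tab) == 3, ncol(tab) == 2)
  if (!is.null(rownames(tab)) &&
      setequal(rownames(tab), c("negative", "inconclusive", "positive"))) {
    tab <- tab[c("negative", "inconclusive", "positive"), , drop = FALSE]
  }
  tn <- tab[1, 1]; fn <- tab[1, 2]; fp <- tab[3, 1]; tp <- tab[3, 2]
  decided <- tn + fn + fp + tp
  if (decided == 0) stop("no records received a decision", call. = FALSE)
  se <- if (tp + fn == 0) {
    warning("no diseased records among the decided: se undefined", call. = FALSE)
    NA_real_
  } else tp / (tp + fn)
  sp <- if (tn + fp == 0) {
    warning("no non-diseased records among the decided: sp undefined", call. = FALSE)
    NA_real_
  } else tn / (tn + fp)
  new_outer_metrics(proportion = decided / total_n,
                    prevalence = (tp + fn) / decided,
                    se = se, sp = sp,
                    accuracy = (tp + tn) / decided,
                    yield = (tp + tn) / total_n)
}

#' Expected outer-section metrics under a bi-normal model
#'
#' The model-based counterpart of [outer_metrics()]: the same six
#' quantities computed from normal tail probabilities weighted by the
#' pre-test probability, i.e. the values the zones are expected to deliver
#' if the fitted class distributions are correct.
#'
#' @param model A `binormal_model`.
#' @param pretest Probability that a tested subject is diseased.
#' @param zones A `decision_zones` object (same direction as the model).
#' @return An object of class `outer_metrics`.
#' @export
outer_metrics_binormal <- function(model, pretest, zones) {
  stopifnot(inherits(model, "binormal_model"), inherits(zones, "decision_zones"))
  check_probability(pretest, "pretest")
  if (model$direction != zones$direction) {
    stop("model and zones have conflicting score directions", call. = FALSE)
  }
  m <- orient(model)
  check_separated(m)
  b <- oriented_bounds(zones)
  tp <- pretest * stats::pnorm(b[2], m$mu1, m$sd1, lower.tail = FALSE)
  fn <- pretest * stats::pnorm(b[1], m$mu1, m$sd1)
  tn <- (1 - pretest) * stats::pnorm(b[1], m$mu0, m$sd0)
  fp <- (1 - pretest) * stats::pnorm(b[2], m$mu0, m$sd0, lower.tail = FALSE)
  decided <- tp + fn + tn + fp
  new_outer_metrics(proportion = decided,
                    prevalence = (tp + fn) / decided,
                    se = tp / (tp + fn), sp = tn / (tn + fp),
                    accuracy = (tp + tn) / decided,
                    yield = tp + tn)
}

#' Dichotomous Youden baseline
#'
#' The single-threshold comparator for the trichotomization methods: the
#' cut-point maximizing `Se + Sp` together with its sensitivity,
#' specificity and accuracy when every record is forced into a positive or
#' negative decision.
#'
#' @param x A `binormal_model` or `labeled_sample`.
#' @param pretest Disease probability used to weight accuracy for a model
#'   (default 0.5); ignored for a sample, whose own prevalence applies.
#' @return A list with `threshold`, `se`, `sp` and `accuracy`.
#' @export
dichotomous_baseline <- function(x, pretest = 0.5) {
  UseMethod("dichotomous_baseline")
}

#' @export
dichotomous_baseline.binormal_model <- function(x, pretest = 0.5) {
  check_probability(pretest, "pretest")
  theta <- intersection_binormal(x)
  cv <- se_sp_curves(x)
  se <- cv$se(theta); sp <- cv$sp(theta)
  list(threshold = theta, se = se, sp = sp,
       accuracy = pretest * se + (1 - pretest) * sp)
}

#' @export
dichotomous_baseline.labeled_sample <- function(x, pretest = 0.5) {
  theta <- youden_threshold(x)
  cv <- se_sp_curves(x)
  se <- cv$se(theta); sp <- cv$sp(theta)
  p1 <- mean(x$labels == 1L)
  list(threshold = theta, se = se, sp = sp,
       accuracy = p1 * se + (1 - p1) * sp)
}

#' Area under the ROC curve (C-statistic)
#'
#' For a `binormal_model`, the closed form
#' `pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))` on the oriented scale. For a
#' `labeled_sample`, the rank (concordance) statistic with ties counted as
#' half-concordant — the probability that a randomly chosen diseased
#' subject outscores a randomly chosen non-diseased one in the direction
#' of disease.
#'
#' @param x A `binormal_model` or `labeled_sample`.
#' @return The AUC, in `[0, 1]`.
#' @examples
#' auc(binormal_model(0, 1, 2, 1)) # pnorm(sqrt(2)) = 0.9214
#' @export
auc <- function(x) UseMethod("auc")

#' @export
auc.binormal_model <- function(x) {
  m <- orient(x)
  stats::pnorm((m$mu1 - m$mu0) / sqrt(m$sd0^2 + m$sd1^2))
}

#' @export
auc.labeled_sample <- function(x) {
  s <- orient(x)
  cl <- check_both_classes(s)
  n0 <- as.double(length(cl$s0)); n1 <- as.double(length(cl$s1))
  r <- rank(c(cl$s0, cl$s1))
  (sum(r[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}
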