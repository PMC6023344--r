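# Grey-zone method: clinical context -> post-test requirements -> required
# likelihood ratios and minimum Se/Sp -> thresholds (TG-ROC mechanics).

#' Grey zone of inconclusive scores from post-test probability requirements
#'
#' Implements the four-step grey-zone procedure: (1) take the pre-test
#' probability of disease for the clinical setting; (2) take the post-test
#' probabilities required to rule the diagnosis in (`post_pos`) and out
#' (`post_neg`); (3) convert these to the minimum required likelihood
#' ratios via the odds form of Bayes' theorem and from those the joint
#' minimum sensitivity and specificity; (4) locate the two cut-points that
#' realize this minimum Se/Sp — mechanically identical to TG-ROC at those
#' targets. Scores between the cut-points form the grey zone.
#'
#' The minimum Se/Sp are passed to the thresholding step at full precision;
#' rounded values belong in reports only.
#'
#' @param x A `binormal_model` or `labeled_sample`.
#' @param post_pos Required probability of disease given a positive
#'   decision (rule-in requirement).
#' @param post_neg Required residual probability of disease given a
#'   negative decision (rule-out requirement).
#' @param pretest Pre-test probability. When `NULL` and `x` is a
#'   `labeled_sample`, the sample prevalence is used as an uninformed
#'   estimate, with a notice.
#' @return An object of class `grey_zone` extending `trichotomy`, with
#'   elements `required_lr_pos`, `required_lr_neg`, `min_se`, `min_sp` and
#'   `pretest` in addition to the zones.
#' @examples
#' grey_zone(binormal_model(0, 1, 2, 1), post_pos = 0.95, post_neg = 0.05,
#'           pretest = 0.5)
#' @export
grey_zone <- function(x, post_pos, post_neg, pretest = NULL) {
  if (is.null(pretest)) {
    if (inherits(x, "labeled_sample")) {
      pretest <- mean(x$labels == 1L)
      message(sprintf("using sample prevalence %.4f as pre-test probability",
                      pretest))
    } else {
      stop("pretest must be supplied when x is a model", call. = FALSE)
    }
  }
  req <- required_lrs(pretest, post_pos, post_neg)
  if (req$lr_pos <= 1) {
    stop(sprintf("infeasible requirement: required LR+ = %.4g is not > 1, so no test can attain post_pos = %g at pretest = %g",
                 req$lr_pos, post_pos, pretest), call. = FALSE)
  }
  if (req$lr_neg >= 1) {
    stop(sprintf("infeasible requirement: required LR- = %.4g is not < 1, so no test can attain post_neg = %g at pretest = %g",
                 req$lr_neg, post_neg, pretest), call. = FALSE)
  }
  acc <- min_se_sp_from_lrs(req$lr_pos, req$lr_neg)
  tri <- tgroc_zones(x, se_target = acc$se, sp_target = acc$sp)
  out <- unclass(tri)
  out$method <- sub("TG-ROC", "Grey zone", out$method)
  out$required_lr_pos <- req$lr_pos
  out$required_lr_neg <- req$lr_neg
  out$min_se <- acc$se
  out$min_sp <- acc$sp
  out$pretest <- pretest
  out$post_pos <- post_pos
  out$post_neg <- post_neg
  class(out) <- c("grey_zone", "trichotomy")
  out
}

#' @export
print.grey_zone <- function(x, ...) {
  cat(sprintf("Grey zone (pretest = %.4g, post-test targets %.4g / %.4g)\n",
              x$pretest, x$post_pos, x$post_neg))
  cat(sprintf("  required LR+ >= %.4f, LR- <= %.4f\n",
              x$required_lr_pos, x$required_lr_neg))
  cat(sprintf("  minimum se = %.4f, sp = %.4f\n", x$min_se, x$min_sp))
  print(x$zones)
  invisible(x)
}

#' Post-test probabilities realized in the outer sections
#'
#' After trichotomization, the patients who actually receive a decision
#' have their own prevalence, sensitivity and specificity (the
#' outer-section metrics). Feeding those back through Bayes' theorem gives
#' the post-test probabilities actually delivered, which in general differ
#' from the pre-selected targets: requirements defined on the full sample
#' are not automatically inherited by the selected subgroup.
#'
#' @param outer An [outer_metrics()] result (or any list with elements
#'   `prevalence`, `se`, `sp`).
#' @return A list with `post_pos` and `post_neg`, as in [posttest_probs()].
#' @export
realized_posttest <- function(outer) {
  stopifnot(is.list(outer), all(c("prevalence", "se", "sp") %in% names(outer)))
  posttest_probs(outer$prevalence, outer$se, outer$sp)
}
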