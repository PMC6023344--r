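# TG-ROC: dual thresholds pinned by a sensitivity target (lower cut-point)
# and a specificity target (upper cut-point).

# vectorized count of elements of sorted vector `v` strictly below each t
count_lt <- function(v_sorted, t) {
  findInterval(t, v_sorted, left.open = TRUE)
}

#' Sensitivity and specificity curves of a marker
#'
#' Returns the two monotone functions that TG-ROC plots: sensitivity
#' `Se(theta)` and specificity `Sp(theta)` of the dichotomous decision rule
#' at cut-point `theta` on the original score scale. On the oriented scale
#' (higher score = diseased) a score greater than or equal to the cut-point
#' counts as positive, so `Se(theta) = P(score >= theta | diseased)` and
#' `Sp(theta) = P(score < theta | non-diseased)`; for a `"lower"`-direction
#' marker the inequalities are mirrored automatically.
#'
#' @param x A `binormal_model` or `labeled_sample`.
#' @return A list of two vectorized functions, `se` and `sp`.
#' @examples
#' cv <- se_sp_curves(binormal_model(0, 1, 2, 1))
#' cv$se(2)      # 0.5: the diseased median
#' cv$sp(1.6449) # 0.95
#' @export
se_sp_curves <- function(x) UseMethod("se_sp_curves")

#' @export
se_sp_curves.binormal_model <- function(x) {
  m <- orient(x)
  check_separated(m)
  flip <- if (x$direction == "lower") -1 else 1
  list(
    se = function(theta) stats::pnorm(flip * theta, m$mu1, m$sd1, lower.tail = FALSE),
    sp = function(theta) stats::pnorm(flip * theta, m$mu0, m$sd0)
  )
}

#' @export
se_sp_curves.labeled_sample <- function(x) {
  cl <- check_both_classes(orient(x))
  s0 <- sort(cl$s0); s1 <- sort(cl$s1)
  n0 <- length(s0); n1 <- length(s1)
  flip <- if (x$direction == "lower") -1 else 1
  list(
    se = function(theta) (n1 - count_lt(s1, flip * theta)) / n1,
    sp = function(theta) count_lt(s0, flip * theta) / n0
  )
}

new_trichotomy <- function(method, zones, se_target, sp_target,
                           achieved_se, achieved_sp, extra = list()) {
  structure(c(list(method = method, zones = zones,
                   se_target = se_target, sp_target = sp_target,
                   achieved_se = achieved_se, achieved_sp = achieved_sp,
                   collapsed = zones$collapsed),
              extra),
            class = "trichotomy")
}

#' @export
print.trichotomy <- function(x, ...) {
  cat(sprintf("%s trichotomization (targets se = %g, sp = %g)\n",
              x$method, x$se_target, x$sp_target))
  print(x$zones)
  cat(sprintf("  achieved se = %.4f, sp = %.4f at the cut-points\n",
              x$achieved_se, x$achieved_sp))
  invisible(x)
}

#' TG-ROC decision zones
#'
#' Computes the two TG-ROC cut-points: the lower cut-point is pinned so the
#' sensitivity of "positive at or above lower" equals `se_target` (limiting
#' false negatives in the negative zone to `1 - se_target`), and the upper
#' cut-point so specificity equals `sp_target` (limiting false positives in
#' the positive zone to `1 - sp_target`). Scores between the cut-points are
#' inconclusive. Both cut-points are prevalence-independent.
#'
#' For a `binormal_model` the cut-points are the exact normal quantiles
#' `lower = mu1 + sd1 * qnorm(1 - se_target)` and
#' `upper = mu0 + sd0 * qnorm(sp_target)` (oriented scale). For a
#' `labeled_sample` the cut-points are restricted to observed score values:
#' `lower` is the largest observed score still achieving `Se >= se_target`
#' and `upper` the smallest achieving `Sp >= sp_target`, so on discrete
#' data the achieved values are greater than or equal to the targets.
#'
#' When the test is strong enough that the computed lower cut-point exceeds
#' the upper one, no inconclusive band is needed: the zones collapse to a
#' single cut-point at the midpoint of the crossed pair, the result carries
#' `collapsed = TRUE`, and a warning is issued.
#'
#' @param x A `binormal_model` or `labeled_sample`.
#' @param se_target,sp_target Desired sensitivity and specificity of the
#'   outer zones, in `(0, 1)`; conventionally 0.90 or 0.95.
#' @return An object of class `trichotomy`: the `decision_zones` (on the
#'   original score scale), the targets, the achieved Se/Sp at the
#'   cut-points, and the `collapsed` flag.
#' @examples
#' tgroc_zones(binormal_model(0, 1, 2, 1), 0.95, 0.95) # band [0.3551, 1.6449]
#' @export
tgroc_zones <- function(x, se_target = 0.95, sp_target = 0.95) {
  UseMethod("tgroc_zones")
}

#' @export
tgroc_zones.binormal_model <- function(x, se_target = 0.95, sp_target = 0.95) {
  check_probability(se_target, "se_target")
  check_probability(sp_target, "sp_target")
  m <- orient(x)
  check_separated(m)
  lower <- m$mu1 + m$sd1 * stats::qnorm(1 - se_target)
  upper <- m$mu0 + m$sd0 * stats::qnorm(sp_target)
  collapsed <- lower > upper
  if (collapsed) {
    mid <- (lower + upper) / 2
    warning("targets already met with a single cut-point; no inconclusive zone needed",
            call. = FALSE)
    lower <- upper <- mid
  }
  cv <- se_sp_curves(m)
  zones <- unorient_zones(lower, upper, x$direction, collapsed)
  new_trichotomy("TG-ROC (bi-normal)", zones, se_target, sp_target,
                 achieved_se = cv$se(lower), achieved_sp = cv$sp(upper))
}

#' @export
tgroc_zones.labeled_sample <- function(x, se_target = 0.95, sp_target = 0.95) {
  check_probability(se_target, "se_target")
  check_probability(sp_target, "sp_target")
  s <- orient(x)
  cl <- check_both_classes(s)
  cand <- sort(unique(s$scores))
  s0 <- sort(cl$s0); s1 <- sort(cl$s1)
  n0 <- length(s0); n1 <- length(s1)
  se_at <- (n1 - count_lt(s1, cand)) / n1   # non-increasing in cand
  sp_at <- count_lt(s0, cand) / n0          # non-decreasing in cand
  ok_se <- which(se_at >= se_target)
  lower <- cand[max(ok_se)]                 # Se(min(cand)) = 1, always ok
  ok_sp <- which(sp_at >= sp_target)
  upper <- if (length(ok_sp)) cand[min(ok_sp)] else Inf
  ach_se <- se_at[max(ok_se)]
  ach_sp <- if (length(ok_sp)) sp_at[min(ok_sp)] else 1
  # on discrete data the two cut-points can meet or cross (e.g. perfectly
  # separated classes); either way no inconclusive zone is needed
  collapsed <- lower >= upper && is.finite(upper)
  if (collapsed) {
    mid <- (lower + upper) / 2
    warning("targets already met with a single cut-point; no inconclusive zone needed",
            call. = FALSE)
    lower <- upper <- mid
    ach_se <- (n1 - count_lt(s1, mid)) / n1
    ach_sp <- count_lt(s0, mid) / n0
  }
  zones <- unorient_zones(lower, upper, x$direction, collapsed)
  new_trichotomy("TG-ROC (empirical)", zones, se_target, sp_target,
                 achieved_se = ach_se, achieved_sp = ach_sp)
}
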