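# Uncertain-interval method: the interval around the intersection of the
# two class densities within which test scores are barely better than a
# coin flip, defined by within-interval sensitivity and specificity targets
# slightly above 0.5.

#' Intersection of the two class densities of a bi-normal marker
#'
#' The score at which the diseased and non-diseased densities are equal --
#' the point of maximum diagnostic uncertainty, where a decision is no
#' better than flipping a coin. For equal class SDs this is the midpoint of
#' the means; otherwise equating the two normal log-densities gives a
#' quadratic with two roots, and the crossing at which `Se + Sp` is
#' maximized (where the non-diseased density falls below the diseased one)
#' is returned -- for any reasonably separated marker this is the root
#' between the two means. The intersection coincides with the
#' Youden-optimal dichotomous threshold and minimizes the total number of
#' misclassifications at equal class sizes.
#'
#' @param model A `binormal_model` whose oriented diseased mean exceeds the
#'   non-diseased mean.
#' @return The intersection score, on the original scale.
#' @examples
#' intersection_binormal(binormal_model(0, 1, 2, 1)) # 1
#' @export
intersection_binormal <- function(model) {
  stopifnot(inherits(model, "binormal_model"))
  m <- orient(model)
  if (m$mu0 == m$mu1 && m$sd0 == m$sd1) {
    stop("identical class distributions: intersection undefined", call. = FALSE)
  }
  check_separated(m)
  flip <- if (model$direction == "lower") -1 else 1
  if (m$sd0 == m$sd1) {
    return(flip * (m$mu0 + m$mu1) / 2)
  }
  # equate log-densities: a x^2 + b x + c = 0
  a <- 1 / m$sd0^2 - 1 / m$sd1^2
  b <- -2 * (m$mu0 / m$sd0^2 - m$mu1 / m$sd1^2)
  cc <- m$mu0^2 / m$sd0^2 - m$mu1^2 / m$sd1^2 - 2 * log(m$sd1 / m$sd0)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) {
    stop("no density-equality root between the means (negative discriminant)",
         call. = FALSE)
  }
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  # of the two crossings, take the Se + Sp maximizer
  J <- stats::pnorm(roots, m$mu1, m$sd1, lower.tail = FALSE) +
    stats::pnorm(roots, m$mu0, m$sd0)
  flip * roots[which.max(J)]
}

#' Empirical Youden threshold
#'
#' The observed score that maximizes `Se(theta) + Sp(theta)` — the
#' dichotomous cut-point with minimal total error rate at equal class
#' weights. Candidate thresholds are the observed score values; ties are
#' broken by the candidate closest to the midpoint of the two class
#' medians.
#'
#' @param sample A `labeled_sample` with both classes present.
#' @return The Youden-optimal threshold on the original scale.
#' @export
youden_threshold <- function(sample) {
  sweep_threshold(sample, function(se, sp) se + sp, maximize = TRUE)
}

#' Threshold closest to the ROC (0, 1) corner
#'
#' The cut-point minimizing the Euclidean distance
#' `sqrt((1 - Se)^2 + (1 - Sp)^2)` between the ROC point and the top-left
#' corner of the unit square. For symmetric bi-normal markers it coincides
#' with the Youden threshold; when the two differ strongly the Youden
#' threshold retains the smaller overall misclassification rate.
#'
#' @param x A `binormal_model` or `labeled_sample`.
#' @return The ROC(0, 1)-optimal threshold on the original scale.
#' @export
roc01_threshold <- function(x) UseMethod("roc01_threshold")

#' @export
roc01_threshold.labeled_sample <- function(x) {
  sweep_threshold(x, function(se, sp) (1 - se)^2 + (1 - sp)^2,
                  maximize = FALSE)
}

#' @export
roc01_threshold.binormal_model <- function(x) {
  m <- orient(x)
  check_separated(m)
  flip <- if (x$direction == "lower") -1 else 1
  obj <- function(t) {
    se <- stats::pnorm(t, m$mu1, m$sd1, lower.tail = FALSE)
    sp <- stats::pnorm(t, m$mu0, m$sd0)
    (1 - se)^2 + (1 - sp)^2
  }
  lo <- min(m$mu0, m$mu1) - 6 * max(m$sd0, m$sd1)
  hi <- max(m$mu0, m$mu1) + 6 * max(m$sd0, m$sd1)
  # coarse grid then local refinement, in case of flat shoulders
  grid <- seq(lo, hi, length.out = 2001)
  i <- which.min(vapply(grid, obj, 0))
  lo2 <- grid[max(1, i - 1)]; hi2 <- grid[min(length(grid), i + 1)]
  flip * stats::optimize(obj, c(lo2, hi2), tol = 1e-10)$minimum
}

# Shared empirical threshold sweep over observed candidate scores.
sweep_threshold <- function(sample, objective, maximize) {
  stopifnot(inherits(sample, "labeled_sample"))
  s <- orient(sample)
  cl <- check_both_classes(s)
  s0 <- sort(cl$s0); s1 <- sort(cl$s1)
  cand <- sort(unique(s$scores))
  se <- (length(s1) - count_lt(s1, cand)) / length(s1)
  sp <- count_lt(s0, cand) / length(s0)
  val <- objective(se, sp)
  if (!maximize) val <- -val
  best <- val >= max(val) - 1e-12
  mid <- (stats::median(s1) + stats::median(s0)) / 2
  pick <- which(best)[which.min(abs(cand[best] - mid))]
  theta <- cand[pick]
  if (sample$direction == "lower") -theta else theta
}

new_interval_solution <- function(method, zones, intersection,
                                  ui_se, ui_sp, achieved_se, achieved_sp) {
  structure(list(method = method, zones = zones, intersection = intersection,
                 ui_se = ui_se, ui_sp = ui_sp,
                 achieved_ui_se = achieved_se, achieved_ui_sp = achieved_sp),
            class = "interval_solution")
}

#' @export
print.interval_solution <- function(x, ...) {
  cat(sprintf("%s uncertain interval (targets se = %g, sp = %g)\n",
              x$method, x$ui_se, x$ui_sp))
  print(x$zones)
  cat(sprintf("  intersection %g; within-interval se = %.4f, sp = %.4f\n",
              x$intersection, x$achieved_ui_se, x$achieved_ui_sp))
  invisible(x)
}

check_ui_targets <- function(ui_se, ui_sp) {
  for (nm in c("ui_se", "ui_sp")) {
    v <- if (nm == "ui_se") ui_se else ui_sp
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0.5 || v >= 1) {
      stop(sprintf("%s must lie strictly in (0.5, 1): inside the interval a decision must be (slightly) better than a coin flip but clearly worse than a useful test",
                   nm), call. = FALSE)
    }
  }
}

#' Bi-normal uncertain interval
#'
#' Finds the interval `[L, U]` around the density intersection `I` such
#' that, for the scores inside the interval and with `I` as the implicit
#' decision point, the within-interval sensitivity
#' `(F1(U) - F1(I)) / (F1(U) - F1(L))` equals `ui_se` and the
#' within-interval specificity `(F0(I) - F0(L)) / (F0(U) - F0(L))` equals
#' `ui_sp` (`F1`, `F0` the diseased / non-diseased cumulative
#' distributions, oriented scale). Targets just above 0.5 mark scores whose
#' decisions are barely better than coin flips; as the targets approach
#' 0.5 the interval collapses onto the intersection.
#'
#' The two-equation system is reduced to one dimension: for a trial upper
#' bound `U`, the sensitivity equation fixes
#' `F1(L) = F1(U) - (F1(U) - F1(I)) / ui_se`, and the remaining
#' specificity residual is solved for `U` by bisection-based root finding
#' ([stats::uniroot()]) to machine precision. Residuals of both equations
#' are checked against `tol` before the solution is accepted.
#'
#' @param model A `binormal_model`.
#' @param ui_se,ui_sp Within-interval sensitivity and specificity targets,
#'   strictly in `(0.5, 1)`. Default 0.55.
#' @param tol Maximum acceptable absolute residual of either defining
#'   equation (default `1e-8`).
#' @return An object of class `interval_solution`: `zones` (original
#'   scale), `intersection`, targets and achieved within-interval values.
#' @examples
#' ui_binormal(binormal_model(0, 1, 2, 1)) # symmetric about 1
#' @export
ui_binormal <- function(model, ui_se = 0.55, ui_sp = 0.55, tol = 1e-8) {
  stopifnot(inherits(model, "binormal_model"))
  check_ui_targets(ui_se, ui_sp)
  m <- orient(model)
  check_separated(m)
  I <- intersection_binormal(m)  # oriented scale
  F0 <- function(q) stats::pnorm(q, m$mu0, m$sd0)
  F1 <- function(q) stats::pnorm(q, m$mu1, m$sd1)
  L_of_U <- function(U) {
    FL <- F1(U) - (F1(U) - F1(I)) / ui_se
    if (FL <= 0) -Inf else stats::qnorm(FL, m$mu1, m$sd1)
  }
  g <- function(U) {
    L <- L_of_U(U)
    denom <- F0(U) - F0(L)
    if (denom <= 0) return(-(ui_sp))  # degenerate: push root finder right
    (F0(I) - F0(L)) / denom - ui_sp
  }
  span <- max(m$sd0, m$sd1)
  hi <- I + 2 * span
  eps <- 1e-9 * span
  tries <- 0
  while (g(hi) < 0 && tries < 8) {
    hi <- I + (hi - I) * 2
    tries <- tries + 1
  }
  if (g(hi) < 0) {
    stop("uncertain-interval equations have no solution in the search range",
         call. = FALSE)
  }
  U <- stats::uniroot(g, c(I + eps, hi), tol = 1e-13)$root
  L <- L_of_U(U)
  ach_se <- (F1(U) - F1(I)) / (F1(U) - F1(L))
  ach_sp <- (F0(I) - F0(L)) / (F0(U) - F0(L))
  if (abs(ach_se - ui_se) > tol || abs(ach_sp - ui_sp) > tol) {
    stop(sprintf("uncertain-interval solver did not converge: residuals %.3g (se), %.3g (sp) at L = %g, U = %g",
                 ach_se - ui_se, ach_sp - ui_sp, L, U), call. = FALSE)
  }
  zones <- unorient_zones(L, U, model$direction)
  flip <- if (model$direction == "lower") -1 else 1
  new_interval_solution("Bi-normal", zones, flip * I, ui_se, ui_sp,
                        ach_se, ach_sp)
}

#' Distribution-free uncertain interval
#'
#' Non-parametric counterpart of [ui_binormal()]. The interval is anchored
#' at an empirical estimate of the Youden threshold: because the empirical
#' `Se + Sp` curve has a flat, noisy top (its argmax converges at a slow
#' cube-root rate), the anchor is taken as the observed score closest to
#' the centre of the near-maximal plateau -- all candidates within
#' `1/sqrt(min(n0, n1))` of the maximum -- which is considerably more
#' stable than the raw argmax returned by [youden_threshold()]. Candidate
#' endpoints are observed score values bracketing the anchor (the anchor
#' itself included). For a
#' candidate pair `[L, U]`, within-interval sensitivity is the fraction of
#' diseased observations inside the interval lying at or above the anchor,
#' and within-interval specificity the fraction of non-diseased
#' observations inside lying strictly below it (the same tie convention as
#' everywhere else in the package).
#'
#' The uncertain interval is the WIDEST bracketing pair whose
#' within-interval sensitivity and specificity both stay at or below the
#' targets, i.e. the largest region around the anchor in which decisions
#' remain close to coin flips. Widening the interval past the point where
#' either target is met makes the inside scores too informative, so at the
#' optimum both constraints bind and the rule converges to the bi-normal
#' equality solution as the sample grows. Ties in width are broken by the
#' summed squared deviation of the two within-interval values from their
#' targets, then by symmetry around the anchor. If not even a minimal
#' bracketing pair is feasible, the pair minimizing the squared deviation
#' is returned instead.
#'
#' The search is exhaustive over all bracketing pairs. On large samples
#' (more than about 4 million candidate pairs) the candidate grids are
#' first thinned to evenly spaced order statistics and the winning
#' neighbourhood is then re-searched at full resolution. On discrete data
#' the achieved within-interval values are step functions and only
#' approximate the targets; the bi-normal variant attains them exactly
#' when its distributional assumption is tenable.
#'
#' @param sample A `labeled_sample`; both classes need at least 10
#'   observations inside the region where the two classes overlap.
#' @param ui_se,ui_sp Within-interval targets, strictly in `(0.5, 1)`.
#' @return An object of class `interval_solution` (the `intersection`
#'   element holds the empirical anchor).
#' @export
ui_nonparametric <- function(sample, ui_se = 0.55, ui_sp = 0.55) {
  stopifnot(inherits(sample, "labeled_sample"))
  check_ui_targets(ui_se, ui_sp)
  s <- orient(sample)
  cl <- check_both_classes(s)
  s0 <- sort(cl$s0); s1 <- sort(cl$s1)
  ov_lo <- min(s1); ov_hi <- max(s0)   # oriented overlap region
  n0_ov <- sum(s0 >= ov_lo & s0 <= ov_hi)
  n1_ov <- sum(s1 >= ov_lo & s1 <= ov_hi)
  if (ov_hi < ov_lo || n0_ov < 10 || n1_ov < 10) {
    stop("fewer than 10 observations per class in the overlap region; ",
         "consider the bi-normal variant (ui_binormal on fit_binormal(sample))",
         call. = FALSE)
  }
  cand <- sort(unique(s$scores))
  # anchor: centre of the near-maximal plateau of the empirical Se + Sp
  # curve (tolerance 1/sqrt(min class size), the scale of its sampling
  # noise near the maximum), snapped to the closest observed score
  n0 <- length(s0); n1 <- length(s1)
  se_c <- (n1 - count_lt(s1, cand)) / n1
  sp_c <- count_lt(s0, cand) / n0
  J <- se_c + sp_c
  plateau <- range(cand[J >= max(J) - 1 / sqrt(min(n0, n1))])
  anchor <- cand[which.min(abs(cand - mean(plateau)))]
  Ls <- cand[cand <= anchor]
  Us <- cand[cand >= anchor]

  # within-interval counts decompose by side of the anchor:
  #   below-anchor counts depend only on L, at-or-above counts only on U
  n1b <- sum(s1 < anchor) - count_lt(s1, Ls)      # diseased in [L, anchor)
  n0b <- sum(s0 < anchor) - count_lt(s0, Ls)      # non-diseased in [L, anchor)
  n1a <- findInterval(Us, s1) - sum(s1 < anchor)  # diseased in [anchor, U]
  n0a <- findInterval(Us, s0) - sum(s0 < anchor)  # non-diseased in [anchor, U]

  best <- search_pairs(Ls, Us, n1b, n0b, n1a, n0a, ui_se, ui_sp, anchor)
  L <- best$L; U <- best$U
  zones <- unorient_zones(L, U, sample$direction)
  flip <- if (sample$direction == "lower") -1 else 1
  new_interval_solution("Distribution-free", zones, flip * anchor,
                        ui_se, ui_sp, best$wse, best$wsp)
}

# Search over bracketing pairs: maximize width subject to wse <= ui_se and
# wsp <= ui_sp; ties by squared deviation from the targets, then symmetry.
# The count profiles n1b(L), n0b(L) are nonincreasing in L, so for each U
# the widest feasible L is found exactly by rank arithmetic: the sweep is
# O(nU log nL) and needs no grid thinning. Falls back to the least-squares
# pair when no bracketing pair satisfies both constraints.
search_pairs <- function(Ls, Us, n1b, n0b, n1a, n0a, ui_se, ui_sp, anchor) {
  nL <- length(Ls)
  # wse <= t1  <=>  n1b >= n1a (1 - t1) / t1   (with n1 inside >= 1)
  # 1e-9 slack keeps exact-equality boundaries (e.g. 11/20 = 0.55) feasible
  Amin <- pmax(n1a * (1 - ui_se) / ui_se - 1e-9, ifelse(n1a == 0, 0.5, 0))
  # wsp <= t2  <=>  n0b <= n0a t2 / (1 - t2)   (undefined when n0 inside = 0)
  Bmax <- n0a * ui_sp / (1 - ui_sp) + 1e-9
  # n1b, n0b are nonincreasing over Ls; reversed they are nondecreasing
  r1 <- rev(n1b); r0 <- rev(n0b)
  # last index satisfying n1b >= Amin (0 if none)
  i1 <- nL - findInterval(Amin, r1, left.open = TRUE)
  # first index satisfying n0b <= Bmax (nL + 1 if none)
  i0 <- nL - findInterval(Bmax, r0) + 1L
  ok <- n0a >= 1 & i0 <= i1 & i0 >= 1 & i1 <= nL
  if (any(ok)) {
    j <- which(ok)
    li <- i0[j]                       # widest feasible L per U
    width <- Us[j] - Ls[li]
    top <- which(width >= max(width) - 1e-12)
    j <- j[top]; li <- li[top]
    wse <- n1a[j] / (n1a[j] + n1b[li])
    wsp <- n0b[li] / (n0b[li] + n0a[j])
    obj <- (wse - ui_se)^2 + (wsp - ui_sp)^2
    asym <- abs((Us[j] - anchor) - (anchor - Ls[li]))
    k <- order(obj, asym)[1]
    return(list(L = Ls[li[k]], U = Us[j[k]], wse = wse[k], wsp = wsp[k],
                feasible = TRUE))
  }
  # no feasible pair: least-squares over all defined pairs (chunked outer)
  best <- NULL
  for (chunk in split(seq_along(Us), ceiling(seq_along(Us) / 512))) {
    wse <- outer(n1b, n1a[chunk], function(b, a) a / (a + b))
    wsp <- outer(n0b, n0a[chunk], function(b, a) b / (b + a))
    obj <- (wse - ui_se)^2 + (wsp - ui_sp)^2
    obj[!is.finite(obj)] <- Inf
    if (!is.finite(min(obj))) next
    sel <- which(obj <= min(obj) + 1e-12)
    width <- outer(Ls, Us[chunk], function(l, u) u - l)
    asym <- outer(Ls, Us[chunk],
                  function(l, u) abs((u - anchor) - (anchor - l)))
    sel <- sel[order(obj[sel], width[sel], asym[sel])][1]
    ij <- arrayInd(sel, dim(obj))
    cand <- list(L = Ls[ij[1]], U = Us[chunk][ij[2]],
                 wse = wse[sel], wsp = wsp[sel], obj = obj[sel],
                 width = width[sel], feasible = FALSE)
    if (is.null(best) || cand$obj < best$obj - 1e-12 ||
        (cand$obj < best$obj + 1e-12 && cand$width < best$width)) {
      best <- cand
    }
  }
  if (is.null(best)) stop("no candidate interval contains both classes",
                          call. = FALSE)
  best
}
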