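# Test-retest simulation: how consistent are positive/negative decisions
# when the same subject is measured twice with an imperfectly reliable test?

#' Simulate paired test-retest measurements
#'
#' Classical true-score model with class-specific variances: each subject
#' draws a latent true score `T ~ N(mu_k, r * sd_k^2)` from its class `k`,
#' and the two observed measurements add independent errors with variance
#' `(1 - r) * sd_k^2`. Each measurement then marginally follows the class
#' distribution `N(mu_k, sd_k^2)` while the within-class correlation of the
#' two measurements equals the reliability `r`. At `r = 1` the two
#' measurements are identical.
#'
#' @param model A `binormal_model` giving the two class distributions.
#' @param reliability Test-retest reliability coefficient `r`, in `(0, 1]`.
#' @param n_per_class Number of simulated subjects per class.
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame with columns `m1`, `m2` (the two measurements) and
#'   `label` (0/1), carrying the model's score direction as attribute
#'   `direction`.
#' @export
simulate_retest <- function(model, reliability, n_per_class, seed = NULL) {
  stopifnot(inherits(model, "binormal_model"))
  if (!is.numeric(reliability) || length(reliability) != 1 ||
      reliability <= 0 || reliability > 1) {
    stop("reliability must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(n_per_class >= 1)
  if (!is.null(seed)) set.seed(seed)
  r <- reliability
  sim_class <- function(mu, sd, n) {
    tr <- stats::rnorm(n, mu, sd * sqrt(r))
    e1 <- stats::rnorm(n, 0, sd * sqrt(1 - r))
    e2 <- stats::rnorm(n, 0, sd * sqrt(1 - r))
    cbind(tr + e1, tr + e2)
  }
  p0 <- sim_class(model$mu0, model$sd0, n_per_class)
  p1 <- sim_class(model$mu1, model$sd1, n_per_class)
  out <- data.frame(m1 = c(p0[, 1], p1[, 1]),
                    m2 = c(p0[, 2], p1[, 2]),
                    label = rep(c(0L, 1L), each = n_per_class))
  attr(out, "direction") <- model$direction
  out
}

#' Decision consistency inside and outside an inconclusive band
#'
#' Stratifies simulated subjects by whether their first measurement falls
#' inside the closed band `[lower, upper]` and reports, per stratum, the
#' proportion whose two measurements fall on the same side of the decision
#' threshold (raw consistency `a`) together with the chance-corrected
#' decision reliability `2a - 1`, which rescales coin-flip consistency
#' (`a = 0.5`) to 0. Scores inside a well-chosen uncertain band sit close
#' to the threshold, so their decisions flip easily on retest: their
#' chance-corrected reliability is typically far below that of the outside
#' stratum and often below 0.5.
#'
#' @param pairs A data frame from [simulate_retest()] (columns `m1`, `m2`).
#' @param zones A `decision_zones` object defining the band.
#' @param threshold Decision threshold; must lie inside the band. A
#'   measurement at or above the threshold (oriented scale) counts as a
#'   positive decision.
#' @return A list with `inside_consistency`, `outside_consistency`,
#'   `inside_reliability`, `outside_reliability` (the chance-corrected
#'   values) and the stratum sizes. An empty stratum yields `NA` for its
#'   fields.
#' @export
decision_consistency <- function(pairs, zones, threshold) {
  stopifnot(is.data.frame(pairs), all(c("m1", "m2") %in% names(pairs)),
            inherits(zones, "decision_zones"))
  dir <- attr(pairs, "direction")
  if (is.null(dir)) dir <- zones$direction
  if (dir != zones$direction) {
    stop("pairs and zones have conflicting score directions", call. = FALSE)
  }
  flip <- if (dir == "lower") -1 else 1
  m1 <- flip * pairs$m1
  m2 <- flip * pairs$m2
  thr <- flip * threshold
  b <- oriented_bounds(zones)
  if (thr < b[1] || thr > b[2]) {
    stop("threshold must lie inside the inconclusive band", call. = FALSE)
  }
  inside <- m1 >= b[1] & m1 <= b[2]
  same <- (m1 >= thr) == (m2 >= thr)
  cons <- function(idx) if (any(idx)) mean(same[idx]) else NA_real_
  a_in <- cons(inside)
  a_out <- cons(!inside)
  list(inside_consistency = a_in,
       outside_consistency = a_out,
       inside_reliability = 2 * a_in - 1,
       outside_reliability = 2 * a_out - 1,
       n_inside = sum(inside),
       n_outside = sum(!inside))
}
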