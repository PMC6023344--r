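# Synthetic bi-normal data generation and Box-Cox normalization. The two
# named fixtures emulate the shape of published markers (sample sizes, AUC,
# score direction, skewness) without reproducing any real dataset.

#' Draw a labeled sample from a bi-normal model
#'
#' `n0` non-diseased and `n1` diseased scores are drawn from the model's
#' class distributions (non-diseased block first), seed-reproducible.
#'
#' @param model A `binormal_model`.
#' @param n0,n1 Class sizes (non-diseased, diseased).
#' @param seed Optional integer seed.
#' @return A [labeled_sample()] with the model's direction.
#' @export
sample_binormal <- function(model, n0, n1, seed = NULL) {
  stopifnot(inherits(model, "binormal_model"), n0 >= 1, n1 >= 1)
  if (!is.null(seed)) set.seed(seed)
  scores <- c(stats::rnorm(n0, model$mu0, model$sd0),
              stats::rnorm(n1, model$mu1, model$sd1))
  labeled_sample(scores, rep(c(0L, 1L), c(n0, n1)),
                 direction = model$direction)
}

#' Generating models behind the named fixtures
#'
#' Returns the bi-normal model from which [synth_fixture()] draws.
#'
#' `"iron-deficiency"`: a haemoglobin-content-like marker where LOWER
#' scores indicate disease. Scores live on a pg-like scale (non-diseased
#' mean 28, SD 2); the diseased mean is placed so the bi-normal AUC is
#' exactly 0.78 (separation `sqrt(2) * qnorm(AUC)` in SD units, the
#' inverse of the equal-SD bi-normal AUC formula).
#'
#' `"dmd"`: a creatine-kinase-like marker where HIGHER scores indicate
#' disease (carriership). The model describes the LATENT Box-Cox
#' transformed scale (`lambda = -0.34`): non-diseased mean 1.95, SD 0.10;
#' carriers have the wider distribution (SD 0.14, as real carrier CK
#' does) and a mean placed so the latent bi-normal AUC is exactly 0.87.
#' [synth_fixture()] back-transforms latent draws to a right-skewed raw
#' scale.
#'
#' @param name `"iron-deficiency"` or `"dmd"`.
#' @return A `binormal_model` (for `"dmd"`, on the latent transformed
#'   scale).
#' @export
fixture_model <- function(name = c("iron-deficiency", "dmd")) {
  name <- match.arg(name)
  if (name == "iron-deficiency") {
    sep <- sqrt(2) * stats::qnorm(0.78)
    binormal_model(mu0 = 28, sd0 = 2, mu1 = 28 - 2 * sep, sd1 = 2,
                   direction = "lower")
  } else {
    sd0 <- 0.10; sd1 <- 0.14
    sep <- stats::qnorm(0.87) * sqrt(sd0^2 + sd1^2)
    binormal_model(mu0 = 1.95, sd0 = sd0, mu1 = 1.95 + sep, sd1 = sd1,
                   direction = "higher")
  }
}

# Box-Cox exponent of the dmd-like fixture's raw scale.
DMD_LAMBDA <- -0.34

#' Synthetic marker fixtures
#'
#' Seed-reproducible samples emulating two published marker settings:
#'
#' * `"iron-deficiency"`: 43 diseased / 167 non-diseased, lower scores
#'   indicate disease, bi-normal AUC 0.78 — a marker of intermediate
#'   strength with a large overlap.
#' * `"dmd"`: 75 carriers / 134 non-carriers, higher scores indicate
#'   carriership, right-skewed raw scores obtained by inverting a Box-Cox
#'   transform (`lambda = -0.34`) of latent bi-normal draws with AUC 0.87
#'   and a wider carrier distribution.
#'
#' See [fixture_model()] for the exact generating parameters.
#'
#' @param name `"iron-deficiency"` or `"dmd"`.
#' @param seed Optional integer seed.
#' @param n0,n1 Override the default class sizes.
#' @return A [labeled_sample()] on the raw score scale.
#' @export
synth_fixture <- function(name = c("iron-deficiency", "dmd"), seed = NULL,
                          n0 = NULL, n1 = NULL) {
  name <- match.arg(name)
  model <- fixture_model(name)
  if (name == "iron-deficiency") {
    if (is.null(n0)) n0 <- 167L
    if (is.null(n1)) n1 <- 43L
    sample_binormal(model, n0, n1, seed = seed)
  } else {
    if (is.null(n0)) n0 <- 134L
    if (is.null(n1)) n1 <- 75L
    latent <- sample_binormal(model, n0, n1, seed = seed)
    labeled_sample(inv_box_cox(latent$scores, DMD_LAMBDA), latent$labels,
                   direction = "higher")
  }
}

#' Box-Cox transformation
#'
#' `(x^lambda - 1) / lambda` for `lambda != 0`, `log(x)` for `lambda = 0`.
#' Strictly increasing in `x` for every `lambda`, so ranks — and with them
#' the empirical AUC and zone occupancies — are invariant; thresholds map
#' through the transform.
#'
#' @param x Positive numeric vector.
#' @param lambda Transformation exponent.
#' @return Transformed vector.
#' @examples
#' box_cox(100, -0.34) # 2.3268
#' @export
box_cox <- function(x, lambda) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("Box-Cox requires strictly positive, finite scores", call. = FALSE)
  }
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Inverse Box-Cox transformation
#'
#' Maps a transformed value back to the raw scale:
#' `(1 + lambda * y)^(1 / lambda)`, or `exp(y)` for `lambda = 0`. Defined
#' only where `1 + lambda * y > 0`.
#'
#' @param y Numeric vector on the transformed scale.
#' @param lambda Transformation exponent.
#' @return Raw-scale vector.
#' @export
inv_box_cox <- function(y, lambda) {
  if (abs(lambda) < 1e-12) return(exp(y))
  z <- 1 + lambda * y
  if (any(z <= 0)) {
    stop("inverse Box-Cox undefined: 1 + lambda * y must be positive",
         call. = FALSE)
  }
  z^(1 / lambda)
}

#' Estimate a common Box-Cox exponent for a two-class sample
#'
#' Maximizes the sum of the two within-class normal profile log-likelihoods
#' of the transformed scores (common `lambda`, class-specific means and
#' variances), including the Jacobian term `(lambda - 1) * sum(log x)` of
#' the transformation, by bounded one-dimensional optimization.
#'
#' @param sample A `labeled_sample` with strictly positive scores.
#' @param interval Search interval for `lambda` (default `c(-3, 3)`).
#' @return The estimated exponent.
#' @export
estimate_lambda <- function(sample, interval = c(-3, 3)) {
  stopifnot(inherits(sample, "labeled_sample"))
  x <- sample$scores
  if (any(x <= 0)) stop("Box-Cox requires strictly positive scores", call. = FALSE)
  g <- sample$labels
  slx <- sum(log(x))
  prof <- function(l) {
    y <- box_cox(x, l)
    ll <- 0
    for (k in c(0L, 1L)) {
      yk <- y[g == k]
      n <- length(yk)
      v <- mean((yk - mean(yk))^2)
      if (v <= 0) return(-Inf)
      ll <- ll - n / 2 * log(v)
    }
    ll + (l - 1) * slx
  }
  stats::optimize(prof, interval, maximum = TRUE, tol = 1e-6)$maximum
}

#' Fit a bi-normal model to a labeled sample
#'
#' Class-wise means and standard deviations (denominator `n - 1`), on
#' whatever scale the sample is on — apply [box_cox()] first if the raw
#' scores are skewed.
#'
#' @param sample A `labeled_sample` with at least two observations per
#'   class.
#' @return A `binormal_model` with the sample's direction.
#' @export
fit_binormal <- function(sample) {
  cl <- check_both_classes(sample)
  if (length(cl$s0) < 2 || length(cl$s1) < 2) {
    stop("need at least two observations per class", call. = FALSE)
  }
  sd0 <- stats::sd(cl$s0); sd1 <- stats::sd(cl$s1)
  if (sd0 == 0 || sd1 == 0) {
    stop("zero within-class variance: bi-normal model undefined", call. = FALSE)
  }
  binormal_model(mean(cl$s0), sd0, mean(cl$s1), sd1,
                 direction = sample$direction)
}

#' Apply a Box-Cox transform to a labeled sample
#'
#' Convenience wrapper returning a new `labeled_sample` on the transformed
#' scale (direction unchanged: the transform is monotone increasing).
#'
#' @param sample A `labeled_sample` with positive scores.
#' @param lambda Exponent; when `NULL`, estimated by [estimate_lambda()].
#' @return A list with elements `sample` (transformed) and `lambda`.
#' @export
transform_sample <- function(sample, lambda = NULL) {
  if (is.null(lambda)) lambda <- estimate_lambda(sample)
  list(sample = labeled_sample(box_cox(sample$scores, lambda), sample$labels,
                               direction = sample$direction),
       lambda = lambda)
}
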