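# Likelihood-ratio and post-test-probability arithmetic. All inputs and
# outputs are probabilities; odds are used only transiently, so infinities
# can only arise at the stated boundary cases (Sp = 1, post_pos = 1, ...).

odds <- function(p) p / (1 - p)
prob <- function(o) o / (1 + o)

#' Likelihood ratios from sensitivity and specificity
#'
#' `LR+ = Se / (1 - Sp)` and `LR- = (1 - Se) / Sp`. A perfectly specific
#' test (`sp = 1`) with positive sensitivity has an infinite positive
#' likelihood ratio, returned as `Inf`; `sp = 0` leaves `LR-` undefined and
#' is an error.
#'
#' @param se,sp Sensitivity and specificity, each in `[0, 1]`.
#' @return A list with elements `lr_pos` and `lr_neg`.
#' @examples
#' lr_from_se_sp(0.95, 0.95) # LR+ = 19, LR- = 0.0526
#' @export
lr_from_se_sp <- function(se, sp) {
  check_probability(se, "se", open = FALSE)
  check_probability(sp, "sp", open = FALSE)
  if (sp == 0) stop("sp = 0 leaves the negative likelihood ratio undefined",
                    call. = FALSE)
  lr_pos <- if (sp == 1) {
    if (se > 0) Inf else NaN
  } else {
    se / (1 - sp)
  }
  list(lr_pos = lr_pos, lr_neg = (1 - se) / sp)
}

#' Post-test probabilities of disease given a positive or negative decision
#'
#' Bayes' theorem for a dichotomous decision:
#' `P(D | +) = p Se / (p Se + (1 - p)(1 - Sp))` and
#' `P(D | -) = p (1 - Se) / (p (1 - Se) + (1 - p) Sp)`, with `p` the
#' pre-test probability. Equivalently, post-test odds are pre-test odds
#' multiplied by the corresponding likelihood ratio.
#'
#' @param pretest Pre-test probability (prevalence), strictly in `(0, 1)`.
#' @param se,sp Sensitivity and specificity of the decision rule.
#' @return A list with elements `post_pos` and `post_neg`.
#' @examples
#' posttest_probs(0.1, 0.95, 0.95) # 0.6786 and 0.0058
#' @export
posttest_probs <- function(pretest, se, sp) {
  check_probability(pretest, "pretest")
  check_probability(se, "se", open = FALSE)
  check_probability(sp, "sp", open = FALSE)
  dpos <- pretest * se + (1 - pretest) * (1 - sp)
  dneg <- pretest * (1 - se) + (1 - pretest) * sp
  if (dpos == 0 || dneg == 0) {
    stop("degenerate decision rule: a decision arm has zero probability",
         call. = FALSE)
  }
  list(post_pos = pretest * se / dpos,
       post_neg = pretest * (1 - se) / dneg)
}

#' Minimum required likelihood ratios from post-test probability targets
#'
#' Given a pre-test probability and the post-test probabilities required to
#' rule the diagnosis in (`post_pos`) or out (`post_neg`), the odds form of
#' Bayes' theorem gives the minimum acceptable LR+ and maximum acceptable
#' LR-: `LR = post-test odds / pre-test odds` for each arm.
#'
#' @param pretest Pre-test probability, in `(0, 1)`.
#' @param post_pos Required probability of disease given a positive
#'   decision; must exceed `pretest`.
#' @param post_neg Required (residual) probability of disease given a
#'   negative decision; must be below `pretest`.
#' @return A list with `lr_pos` (minimum acceptable) and `lr_neg`
#'   (maximum acceptable).
#' @examples
#' required_lrs(0.10, 0.7, 0.001) # LR+ >= 21, LR- <= 0.009
#' @export
required_lrs <- function(pretest, post_pos, post_neg) {
  check_probability(pretest, "pretest")
  check_probability(post_pos, "post_pos")
  check_probability(post_neg, "post_neg")
  if (!(post_neg < pretest && pretest < post_pos)) {
    stop("requirement must satisfy post_neg < pretest < post_pos; ",
         "otherwise it is unattainable or vacuous", call. = FALSE)
  }
  list(lr_pos = odds(post_pos) / odds(pretest),
       lr_neg = odds(post_neg) / odds(pretest))
}

#' Minimum sensitivity and specificity satisfying both LR constraints
#'
#' Solves `Se / (1 - Sp) = LR+` and `(1 - Se) / Sp = LR-` jointly:
#' `Sp = (LR+ - 1) / (LR+ - LR-)` and `Se = LR+ (1 - LR-) / (LR+ - LR-)`.
#' The returned pair attains both likelihood-ratio requirements with
#' equality; any test at least this sensitive and specific meets them.
#' Admissibility requires an informative requirement, `LR+ > 1 > LR-`.
#'
#' @param lr_pos Minimum required positive likelihood ratio (> 1).
#' @param lr_neg Maximum acceptable negative likelihood ratio (in `[0, 1)`).
#' @return A list with elements `se` and `sp`.
#' @examples
#' min_se_sp_from_lrs(19, 1 / 19)   # se = sp = 0.95
#' min_se_sp_from_lrs(21, 0.009009) # se ~ 0.99, sp ~ 0.95
#' @export
min_se_sp_from_lrs <- function(lr_pos, lr_neg) {
  stopifnot(is.numeric(lr_pos), is.numeric(lr_neg),
            length(lr_pos) == 1, length(lr_neg) == 1)
  if (!(lr_pos > 1 && lr_neg < 1 && lr_neg >= 0)) {
    stop("no admissible (se, sp) pair: requirement needs LR+ > 1 > LR- >= 0",
         call. = FALSE)
  }
  sp <- (lr_pos - 1) / (lr_pos - lr_neg)
  se <- lr_pos * (1 - lr_neg) / (lr_pos - lr_neg)
  list(se = se, sp = sp)
}

# Half-up decimal rounding, as used in printed reference tables (round()
# rounds half to even, which would turn 0.00905 into 0.009 vs 0.0091).
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reference table: post-test probabilities across prevalence
#'
#' For a fixed sensitivity and specificity, tabulates the likelihood ratios
#' and the positive and negative post-test probabilities over a range of
#' prevalences, illustrating how strongly prevalence drives what a fixed
#' Se/Sp pair delivers. Values are rounded half-up to 4 decimals, matching
#' conventional reporting.
#'
#' @param prevalence Vector of prevalences (default 0.1 to 0.9 by 0.1).
#' @param se,sp The fixed sensitivity and specificity (default 0.95 each).
#' @return A data frame with columns `prevalence`, `lr_pos`, `lr_neg`,
#'   `se`, `sp`, `post_pos`, `post_neg`.
#' @seealso [requirements_table()] for the converse: fixed post-test
#'   targets, varying minimum Se/Sp.
#' @export
posttest_table <- function(prevalence = seq(0.1, 0.9, by = 0.1),
                           se = 0.95, sp = 0.95) {
  lrs <- lr_from_se_sp(se, sp)
  rows <- lapply(prevalence, function(p) {
    pt <- posttest_probs(p, se, sp)
    data.frame(prevalence = p,
               lr_pos = round_half_up(lrs$lr_pos),
               lr_neg = round_half_up(lrs$lr_neg),
               se = se, sp = sp,
               post_pos = round_half_up(pt$post_pos),
               post_neg = round_half_up(pt$post_neg))
  })
  do.call(rbind, rows)
}

#' Reference table: minimum Se/Sp needed across prevalence
#'
#' For fixed post-test probability targets, tabulates the required
#' likelihood ratios and the joint minimum sensitivity and specificity over
#' a range of prevalences. At low prevalence the burden falls on
#' specificity; at high prevalence on sensitivity.
#'
#' @param prevalence Vector of prevalences (default 0.1 to 0.9 by 0.1).
#' @param post_pos,post_neg The fixed post-test probability targets
#'   (defaults 0.95 and 0.05).
#' @return A data frame with columns `prevalence`, `post_pos`, `post_neg`,
#'   `lr_pos`, `lr_neg`, `se`, `sp`, rounded half-up to 4 decimals.
#' @export
requirements_table <- function(prevalence = seq(0.1, 0.9, by = 0.1),
                               post_pos = 0.95, post_neg = 0.05) {
  rows <- lapply(prevalence, function(p) {
    req <- required_lrs(p, post_pos, post_neg)
    acc <- min_se_sp_from_lrs(req$lr_pos, req$lr_neg)
    data.frame(prevalence = p, post_pos = post_pos, post_neg = post_neg,
               lr_pos = round_half_up(req$lr_pos),
               lr_neg = round_half_up(req$lr_neg),
               se = round_half_up(acc$se),
               sp = round_half_up(acc$sp))
  })
  do.call(rbind, rows)
}
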