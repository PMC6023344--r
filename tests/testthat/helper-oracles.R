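# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately use naive loops and direct proportions, not
# the package's vectorized internals.

# empirical Se/Sp of the rule "positive iff score >= theta" (oriented scale)
oracle_se_sp <- function(s0, s1, theta) {
  c(se = mean(s1 >= theta), sp = mean(s0 < theta))
}

# exhaustive Youden sweep over observed scores; returns max J and argmaxes
oracle_youden <- function(s0, s1) {
  cand <- sort(unique(c(s0, s1)))
  j <- sapply(cand, function(t) sum(oracle_se_sp(s0, s1, t)))
  list(max_j = max(j), argmax = cand[j >= max(j) - 1e-12])
}

# exhaustive ROC(0,1) sweep over observed scores
oracle_roc01 <- function(s0, s1) {
  cand <- sort(unique(c(s0, s1)))
  d <- sapply(cand, function(t) {
    p <- oracle_se_sp(s0, s1, t)
    sqrt((1 - p["se"])^2 + (1 - p["sp"])^2)
  })
  list(min_d = min(d), argmin = cand[d <= min(d) + 1e-12])
}

# exhaustive search over all bracketing pairs for the distribution-free
# uncertain interval: widest pair with within-interval se/sp at or below
# the targets; ties by squared deviation, then symmetry. Plain loops.
oracle_ui_pairs <- function(s0, s1, anchor, ui_se, ui_sp) {
  cand <- sort(unique(c(s0, s1)))
  rows <- list()
  for (L in cand[cand <= anchor]) for (U in cand[cand >= anchor]) {
    n1a <- sum(s1 >= anchor & s1 <= U)
    n1b <- sum(s1 >= L & s1 < anchor)
    n0a <- sum(s0 >= anchor & s0 <= U)
    n0b <- sum(s0 >= L & s0 < anchor)
    if (n1a + n1b == 0 || n0a + n0b == 0) next
    wse <- n1a / (n1a + n1b)
    wsp <- n0b / (n0a + n0b)
    rows[[length(rows) + 1]] <-
      data.frame(L = L, U = U, wse = wse, wsp = wsp,
                 feasible = wse <= ui_se && wsp <= ui_sp,
                 obj = (wse - ui_se)^2 + (wsp - ui_sp)^2)
  }
  df <- do.call(rbind, rows)
  if (any(df$feasible)) {
    df <- df[df$feasible, ]
    w <- df$U - df$L
    df <- df[w >= max(w) - 1e-12, ]
  } else {
    df <- df[df$obj <= min(df$obj) + 1e-12, ]
  }
  df <- df[order(df$obj, abs((df$U - anchor) - (anchor - df$L))), ]
  df[1, ]
}

# O(n^2) pairwise concordance AUC with ties counted half
oracle_auc <- function(s0, s1) {
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(s0) * length(s1))
}

# half-up rounding as used for printed-value comparisons
round_half_up <- function(x, digits = 4) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

toy_sample_12 <- function() {
  labeled_sample(scores = c(1, 2, 3, 4, 5, 6, 4.5, 5.5, 6.5, 7, 8, 9),
                 labels = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1))
}
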