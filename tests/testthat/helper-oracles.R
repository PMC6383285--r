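# Independent oracles used across the suite.

# Two-sided Fisher p by explicit margin-fixed hypergeometric enumeration
# (point-probability rule), independent of stats::fisher.test.
brute_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  xs <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- dhyper(xs, r1, N - r1, c1)
  p0 <- dhyper(a, r1, N - r1, c1)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Closed-form Pearson chi-squared statistic for a 2x2 table.
pearson_chi2_formula <- function(a, b, c, d) {
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Coarse-to-fine grid-search ML for the collapsed paired binomial model
# logit(p_hypoxia) = b0 + b1, logit(p_normoxia) = b0; returns b1 at the
# maximum. Independent of stats::glm.
grid_ml_log_or <- function(alt_h, ref_h, alt_n, ref_n) {
  loglik <- function(b0, b1) {
    ph <- plogis(b0 + b1); pn <- plogis(b0)
    dbinom(alt_h, alt_h + ref_h, ph, log = TRUE) +
      dbinom(alt_n, alt_n + ref_n, pn, log = TRUE)
  }
  b0s <- seq(-8, 2, length.out = 101)
  b1s <- seq(-8, 8, length.out = 161)
  for (pass in 1:3) {
    ll <- outer(b0s, b1s, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    w0 <- diff(range(b0s)) / 10; w1 <- diff(range(b1s)) / 10
    b0c <- b0s[best[1]]; b1c <- b1s[best[2]]
    b0s <- seq(b0c - w0, b0c + w0, length.out = 101)
    b1s <- seq(b1c - w1, b1c + w1, length.out = 101)
  }
  b1c
}

# Random 31-nt window with the center forced to C.
random_c_window <- function(k = 15L) {
  w <- sample(c("A", "C", "G", "T"), 2L * k + 1L, replace = TRUE)
  w[k + 1L] <- "C"
  paste(w, collapse = "")
}

# Small balanced paired counts fixture: one row per donor x condition.
paired_obs <- function(alt_h, ref_h, alt_n, ref_n, donors = 3L) {
  data.frame(
    donor_id = rep(sprintf("D%d", seq_len(donors)), each = 2L),
    condition = rep(c("hypoxia", "normoxia"), donors),
    alt_count = rep(c(alt_h, alt_n), donors),
    ref_count = rep(c(ref_h, ref_n), donors),
    stringsAsFactors = FALSE)
}
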