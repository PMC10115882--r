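# Shared oracles and fixtures, all built in code.

# Monte-Carlo oracle for first-order error propagation: empirical sd of the
# operation applied to independent normal draws.
mc_propagate <- function(op, a, b, n = 1e5, seed = 424242) {
  set.seed(seed)
  xa <- rnorm(n, a$value, a$sd)
  xb <- rnorm(n, b$value, b$sd)
  sd(op(xa, xb))
}

# Brute-force Hodges-Lehmann: median over the full pairwise-difference set.
hl_brute <- function(x, y) median(as.vector(outer(x, y, "-")))

# Brute-force Benjamini-Hochberg step-up from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(m * p[o[i:m]] / i:m))
  }
  adj
}

# small scenario for fast pipeline tests: reference design, zero noise
zero_noise_scenario <- function(...) {
  default_paper_scenario(cv_amount = 0, sd_atpercent = 0, ...)
}
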