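# Independent oracles used across test files.

# exact two-sided Fisher p by full enumeration over tables with fixed margins
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- dhyper(xs, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# exact Wallenius pmf by dynamic programming over sequential weighted draws
wallenius_dp_pmf <- function(m1, m2, n, omega) {
  # state: after t draws, probability of having drawn x from the in-set group
  p <- matrix(0, nrow = n + 1, ncol = 1)
  probs <- setNames(1, "0")
  for (t in seq_len(n)) {
    nxt <- numeric()
    for (xs in names(probs)) {
      x <- as.integer(xs)
      rem_in <- m1 - x; rem_out <- m2 - (t - 1 - x)
      w_in <- omega * rem_in; w_out <- rem_out
      tot <- w_in + w_out
      if (rem_in > 0) {
        k <- as.character(x + 1)
        nxt[k] <- (nxt[k] %||% 0) + probs[[xs]] * w_in / tot
      }
      if (rem_out > 0) {
        k <- as.character(x)
        nxt[k] <- (nxt[k] %||% 0) + probs[[xs]] * w_out / tot
      }
    }
    probs <- nxt
  }
  out <- numeric(n + 1)
  out[as.integer(names(probs)) + 1] <- probs
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# Poisson 99% central interval
pois_ci99 <- function(mean) qpois(c(0.005, 0.995), mean)

# binomial 99% central interval for a count
binom_ci99 <- function(n, p) qbinom(c(0.005, 0.995), n, p)
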