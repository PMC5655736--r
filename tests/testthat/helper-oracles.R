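# Independent brute-force oracles, kept deliberately naive: everything is a
# direct enumeration with log-choose arithmetic, so the fast implementations
# can be checked against first principles.

# P(X >= k) for X ~ Binomial(n, p), summed term by term
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# two-sided Fisher exact p for the 2x2 table [k1, n1-k1; k2, n2-k2] by full
# enumeration over the conditional distribution of the top-left cell
oracle_fisher2x2 <- function(k1, n1, k2, n2) {
  m <- k1 + k2; u <- (n1 - k1) + (n2 - k2)
  lo <- max(0, n1 - u); hi <- min(n1, m)
  xs <- lo:hi
  lp <- lchoose(m, xs) + lchoose(u, n1 - xs) - lchoose(m + u, n1)
  obs <- lchoose(m, k1) + lchoose(u, n1 - k1) - lchoose(m + u, n1)
  min(1, sum(exp(lp[lp <= obs + 1e-7])))
}

# upper-tail hypergeometric P(X >= a) with K successes in a population of N,
# n draws
oracle_hyper_tail <- function(a, K, N, n) {
  xs <- a:min(K, n)
  xs <- xs[xs >= max(0, n - (N - K))]
  if (!length(xs)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# Benjamini-Hochberg by the definition: find the largest i with
# p_(i) <= i*q/m; reject 1..i. Returns the rejection set as a logical vector.
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

# BH q-values by the step-up definition (cumulative minimum from the top)
oracle_bh_qvalues <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}
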