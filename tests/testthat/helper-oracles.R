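# Brute-force enumeration oracles, written independently of the package
# implementations (explicit enumeration via expand.grid / combn; the
# package uses convolution, pwilcox and closed forms).

# exact two-sided signed-rank p: enumerate every sign pattern
oracle_signed_rank <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  w <- sum(r[d > 0])
  min(1, 2 * min(mean(W_all <= w + 1e-12), mean(W_all >= w - 1e-12)))
}

# exact two-sided Mann-Whitney p: enumerate every group assignment
oracle_mann_whitney <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  combs <- combn(length(r), na)
  U_all <- apply(combs, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  min(1, 2 * min(mean(U_all <= u + 1e-12), mean(U_all >= u - 1e-12)))
}

# exact two-sided McNemar p from the binomial mass function, by
# explicit summation of binomial coefficients
oracle_mcnemar <- function(b, c) {
  m <- b + c
  if (m == 0) return(1)
  k <- min(b, c)
  min(1, 2 * sum(choose(m, 0:k)) / 2^m)
}
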