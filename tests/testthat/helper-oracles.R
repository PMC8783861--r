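# Independent brute-force oracles used to validate the statistical
# machinery.  These deliberately re-derive each quantity from first
# principles (enumeration, permutation, the step-up definition) and
# never call the implementation they check.

# Benjamini-Hochberg step-up by definition: q_(i) = min_{j >= i}
# min(1, m * p_(j) / j), mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, m * ps / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact two-sided Mann-Whitney p by full enumeration of all
# choose(nA + nB, nA) group assignments of the pooled values
# (distinct values assumed).  p = min(1, 2 * min(P(U <= u), P(U >= u))).
oracle_wilcox_exact <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  u_all <- apply(combs, 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Monte-Carlo permutation p for the (tie-corrected) Kruskal-Wallis H.
oracle_kw_perm <- function(x, g, B = 1e5) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  n <- table(g)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h_of <- function(rr, sums_by_group) {
    (12 / (N * (N + 1)) * sum(sums_by_group^2 / n) - 3 * (N + 1)) / C
  }
  h_obs <- h_of(r, tapply(r, g, sum))
  ends <- cumsum(n)
  starts <- c(1, utils::head(ends, -1) + 1)
  h_b <- numeric(B)
  for (b in seq_len(B)) {
    p <- sample(r)
    sums <- vapply(seq_along(n),
                   function(i) sum(p[starts[i]:ends[i]]), 0)
    h_b[b] <- h_of(p, sums)
  }
  list(p = mean(h_b >= h_obs - 1e-12), h = h_obs)
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric
# enumeration: sum the probabilities of all tables (with the observed
# margins) no more probable than the observed one.
oracle_fisher_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  m <- sum(tab[1, ])          # row 1 total
  n <- sum(tab[2, ])          # row 2 total
  k <- sum(tab[, 1])          # column 1 total
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Manhattan distance from the definition.
oracle_manhattan <- function(u, v) sum(abs(u - v))

# Partition agreement between two 2-group labelings: best achievable
# fraction of samples on which they coincide over label swaps.
partition_agreement <- function(a, b) {
  a <- as.integer(factor(a))
  b <- as.integer(factor(b))
  max(mean(a == b), mean(a == 3 - b))
}
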