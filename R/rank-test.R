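# Wilcoxon rank-sum machinery shared by the per-gene DEG test (two-sided,
# normal approximation with tie correction, exact enumeration at small n)
# and the cohort burden comparison (one-sided). W is the rank sum of group A
# under mid-ranks; mu = n1(N+1)/2; sigma^2 = n1 n2/12 [(N+1) - T/(N(N-1))]
# with T = sum(t^3 - t) over tie groups. The normal path applies a 0.5
# continuity correction toward the mean.

rank_sum_moments <- function(x, in_a) {
  r <- rank(x)
  n1 <- sum(in_a)
  n2 <- sum(!in_a)
  N <- n1 + n2
  tie_sizes <- tabulate(match(x, unique(x)))
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  list(W = sum(r[in_a]), mu = n1 * (N + 1) / 2,
       sigma = sqrt(max(sigma2, 0)), n1 = n1, n2 = n2)
}

rank_sum_p_normal <- function(m, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (m$sigma == 0) return(1)
  d <- m$W - m$mu
  switch(alternative,
    greater = pnorm((d - 0.5) / m$sigma, lower.tail = FALSE),
    less = pnorm((d + 0.5) / m$sigma, lower.tail = TRUE),
    two.sided = min(1, 2 * pnorm((abs(d) - 0.5) / m$sigma, lower.tail = FALSE))
  )
}

# Exact null distribution of W by enumerating all C(N, n1) group-A label
# assignments over the observed mid-ranks (ties enumerated as-is).
rank_sum_p_exact <- function(x, in_a, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  r <- rank(x)
  n1 <- sum(in_a)
  W_obs <- sum(r[in_a])
  W_all <- utils::combn(r, n1, FUN = sum)
  p_ge <- mean(W_all >= W_obs)
  p_le <- mean(W_all <= W_obs)
  switch(alternative,
    greater = p_ge,
    less = p_le,
    two.sided = min(1, 2 * min(p_ge, p_le))
  )
}
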