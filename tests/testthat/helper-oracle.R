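# Brute-force oracles, independent of the package's likelihood kernels:
# ordered-sequence enumeration with scalar arithmetic throughout.

oracle_bn <- function(p, m, n, theta) {
  (m * theta + (1 - theta) * p) / (1 + (n - 1) * theta)
}

oracle_count <- function(cond, a) {
  v <- cond[a]
  if (length(v) == 0 || is.na(v)) 0 else unname(v)
}

# Probability of the ORDERED allele pair (a1, a2) given conditioning copy
# counts `cond` among n observed copies.
oracle_ordered_pair <- function(a1, a2, p, cond, n, theta) {
  v1 <- oracle_bn(p[[a1]], oracle_count(cond, a1), n, theta)
  cond[a1] <- oracle_count(cond, a1) + 1
  v1 * oracle_bn(p[[a2]], oracle_count(cond, a2), n + 1, theta)
}

# Unordered genotype probability as a sum over its orderings.
oracle_genotype_prob <- function(g, p, cond, n, theta) {
  if (g[1] == g[2]) return(oracle_ordered_pair(g[1], g[2], p, cond, n, theta))
  oracle_ordered_pair(g[1], g[2], p, cond, n, theta) +
    oracle_ordered_pair(g[2], g[1], p, cond, n, theta)
}

# Adjusted frequencies: +1 per allele copy of Q, then floor count 1 for
# any CSP allele with zero observations.
oracle_freqs <- function(cnt, A, gq) {
  for (a in gq) {
    if (!a %in% names(cnt)) cnt[a] <- 0
    cnt[a] <- cnt[a] + 1
  }
  for (a in A) if (!a %in% names(cnt)) cnt[a] <- 0
  zero <- names(cnt)[cnt == 0 & names(cnt) %in% A]
  cnt[zero] <- 1
  cnt / sum(cnt)
}

oracle_cond_of <- function(g) {
  cond <- numeric(0)
  for (a in g) cond[a] <- oracle_count(cond, a) + 1
  cond
}

# Hd likelihood of the known-K hypothesis pair at one locus: sum over all
# ordered allele pairs for X within the CSP alleles whose union with K's
# alleles recovers the CSP.
oracle_lik_known <- function(p, A, gq, gk, theta) {
  condQ <- oracle_cond_of(gq)
  hd <- 0
  for (a1 in A) for (a2 in A) {
    if (!setequal(union(c(a1, a2), gk), A)) next
    hd <- hd + oracle_ordered_pair(a1, a2, p, condQ, 2, theta)
  }
  hd
}

# Hp and Hd likelihoods of the unknown-U hypothesis pair at one locus,
# enumerating all ordered 4-tuples (x1, x2, u1, u2) over the CSP alleles.
oracle_lik_unknown <- function(p_x, p_u, A, gq, theta_x, theta_u, cross) {
  condQ <- oracle_cond_of(gq)
  hp <- 0
  for (u1 in A) for (u2 in A) {
    if (!setequal(union(gq, c(u1, u2)), A)) next
    hp <- hp + oracle_ordered_pair(u1, u2, p_u, condQ, 2, theta_u)
  }
  hd <- 0
  for (x1 in A) for (x2 in A) {
    px <- oracle_ordered_pair(x1, x2, p_x, condQ, 2, theta_x)
    for (u1 in A) for (u2 in A) {
      if (!setequal(c(x1, x2, u1, u2), A)) next
      if (cross) {
        cond2 <- condQ
        cond2[x1] <- oracle_count(cond2, x1) + 1
        cond2[x2] <- oracle_count(cond2, x2) + 1
        pu <- oracle_ordered_pair(u1, u2, p_u, cond2, 4, theta_u)
      } else {
        pu <- oracle_ordered_pair(u1, u2, p_u, condQ, 2, theta_u)
      }
      hd <- hd + px * pu
    }
  }
  list(hp = hp, hd = hd)
}
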