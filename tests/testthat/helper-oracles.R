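# Independent oracles used across tests. These re-derive quantities by brute
# force (enumeration, per-bp integration, direct dense-matrix solves) and are
# deliberately written without reusing the package's computational paths.

# scalar emission probability of a progeny genotype given the transmitted
# parental allele; the other parent contributes an allele-1 probability pb
emit_prob <- function(g, a, pb) {
  if (is.na(g) || is.na(a)) return(1)
  d <- g - a
  if (d == 1) pb else if (d == 0) 1 - pb else 0
}

# exhaustive posterior over all 2^q transmission sequences
enum_posterior <- function(geno, hap1, hap2, rates, pb) {
  q <- length(geno)
  states <- as.matrix(expand.grid(rep(list(1:2), q)))
  probs <- apply(states, 1L, function(s) {
    p <- 0.5
    for (i in seq_len(q)) {
      a <- if (s[i] == 1L) hap1[i] else hap2[i]
      p <- p * emit_prob(geno[i], a, pb[i])
      if (i < q) p <- p * if (s[i] == s[i + 1L]) 1 - rates[i] else rates[i]
    }
    p
  })
  tot <- sum(probs)
  post1 <- vapply(seq_len(q), function(i)
    sum(probs[states[, i] == 1L]) / tot, 1)
  list(post1 = post1, loglik = log(tot))
}

# per-bp integration of the homolog-1 proportion of a transmission path
bp_proportion_oracle <- function(bp_lo, bp_hi, start_state, midpoints) {
  pos <- seq(bp_lo, bp_hi - 1L)  # left endpoints of unit segments
  state <- start_state
  orig <- numeric(length(pos))
  cuts <- sort(midpoints)
  k <- findInterval(pos + 0.5, cuts)
  orig <- ifelse(k %% 2 == 0, start_state, 3 - start_state)
  mean(orig == 1)
}

# direct GLS / BLUP solve with explicit covariance matrices
direct_gblup_oracle <- function(y, K, w, sg2, se2) {
  n <- length(y)
  V <- sg2 * K + se2 * diag(1 / w, n)
  Vi <- solve(V)
  one <- rep(1, n)
  mu <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
  u <- drop(sg2 * K %*% Vi %*% (y - mu))
  list(mu = mu, u = u)
}

# small deterministic half-sib family with fully informative transmissions:
# sire heterozygous everywhere, dams contribute allele 0 at every marker, so
# the progeny genotype equals the transmitted paternal allele
fully_informative_family <- function(n_progeny, map, seed) {
  q <- nrow(map)
  n_found <- n_progeny + 5L
  H <- matrix(0L, 2L * n_found, q)
  H[1L, ] <- 0L; H[2L, ] <- 1L   # the sire
  sim_half_sib_population(1, n_progeny, map, n_founders = n_found,
                          founder_haplotypes = H, seed = seed)
}
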