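# Joint maximum likelihood for adjacent-pair recombination fractions.
#
# Model per marker pair, pooled over half-sib families with a heterozygous
# phased sire: the paternal gamete carries one of four two-locus haplotypes
# with probabilities (1-theta)/2 for the two parental (non-recombinant)
# haplotypes and theta/2 for the two recombinant ones; which pair is
# parental is the family's phase class (0 = like alleles coupled, 1 =
# repulsion). The maternal gamete carries haplotype m with frequency h_m,
# estimated jointly with theta -- this absorbs any maternal linkage
# disequilibrium (including the finite-dam-pool kind) instead of letting it
# contaminate the recombination estimate. Progeny two-locus genotype
# categories are 3*g1 + g2.

# EM over (theta, h) vectorised across pairs; cnt is [pairs, 2 classes, 9]
em_theta <- function(cnt, f1, f2, tol = 1e-8, max_iter = 500L) {
  np <- length(f1)
  h <- cbind((1 - f1) * (1 - f2), (1 - f1) * f2, f1 * (1 - f2), f1 * f2)
  h <- pmax(h, 1e-6); h <- h / rowSums(h)
  theta <- rep(0.005, np)
  # paternal haplotypes t = (t1, t2) indexed 1..4 as (0,0),(0,1),(1,0),(1,1)
  t1v <- c(0L, 0L, 1L, 1L); t2v <- c(0L, 1L, 0L, 1L)
  m1v <- t1v; m2v <- t2v
  xor_t <- bitwXor(t1v, t2v)
  for (it in seq_len(max_iter)) {
    Tcnt <- matrix(0, np, 4L)   # expected paternal haplotype counts
    Hcnt <- matrix(0, np, 4L)   # expected maternal haplotype counts
    rec_mass <- numeric(np)     # expected recombinant paternal gametes
    for (cls in 0:1) {
      n_cls <- cnt[, cls + 1L, , drop = FALSE]
      dim(n_cls) <- c(np, 9L)
      if (all(n_cls == 0)) next
      wt <- matrix(0, np, 4L)
      for (t in 1:4)
        wt[, t] <- if (xor_t[t] == cls) (1 - theta) / 2 else theta / 2
      joint <- array(0, c(np, 4L, 4L))
      den <- matrix(0, np, 9L)
      for (t in 1:4) for (m in 1:4) {
        cat_idx <- 3L * (t1v[t] + m1v[m]) + (t2v[t] + m2v[m]) + 1L
        jtm <- wt[, t] * h[, m]
        joint[, t, m] <- jtm
        den[, cat_idx] <- den[, cat_idx] + jtm
      }
      den <- pmax(den, 1e-300)
      for (t in 1:4) for (m in 1:4) {
        cat_idx <- 3L * (t1v[t] + m1v[m]) + (t2v[t] + m2v[m]) + 1L
        post_n <- n_cls[, cat_idx] * joint[, t, m] / den[, cat_idx]
        Tcnt[, t] <- Tcnt[, t] + post_n
        Hcnt[, m] <- Hcnt[, m] + post_n
        if (xor_t[t] != cls) rec_mass <- rec_mass + post_n
      }
    }
    tot <- rowSums(Tcnt)
    theta_new <- ifelse(tot > 0, pmin(rec_mass / pmax(tot, 1e-12), 0.5), 0)
    h_new <- Hcnt / pmax(tot, 1e-12)
    h_new <- pmax(h_new, 1e-9); h_new <- h_new / rowSums(h_new)
    delta <- max(abs(theta_new - theta))
    theta <- theta_new; h <- h_new
    if (delta < tol) break
  }
  theta
}

#' Pairwise two-locus maximum-likelihood recombination fraction
#'
#' Maximises, over the recombination fraction in `[0, 0.5]` and the maternal
#' two-locus haplotype frequencies, the mixture likelihood of progeny
#' two-locus genotype counts given the sire's phased haplotypes. When every
#' progeny's paternal gamete is directly classifiable the MLE reduces to the
#' recombinant fraction k/n.
#'
#' @param g1,g2 Progeny genotype vectors (0/1/2/`NA`) at the two markers.
#' @param hap1_alleles Length-2 vector: the alleles carried by sire homolog 1
#'   at the two markers (sire must be heterozygous at both).
#' @param freq Length-2 maternal allele-1 frequencies used to initialise the
#'   maternal haplotype distribution.
#' @return The MLE of the recombination fraction, or `NA` if no informative
#'   progeny are available.
#' @export
pairwise_likelihood_rate <- function(g1, g2, hap1_alleles,
                                     freq = c(0.5, 0.5)) {
  assert_that(length(hap1_alleles) == 2L && all(hap1_alleles %in% 0:1),
              "sire must be heterozygous and phased at both markers")
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) return(NA_real_)
  cls <- bitwXor(hap1_alleles[1L], hap1_alleles[2L])
  cnt <- array(0, c(1L, 2L, 9L))
  code <- 3L * g1[ok] + g2[ok]
  cnt[1L, cls + 1L, ] <- tabulate(code + 1L, nbins = 9L)
  em_theta(cnt, freq[1L], freq[2L])
}

#' Adjacent-interval rates from the pairwise likelihood estimator
#'
#' Applies the two-locus maximum-likelihood estimator to every
#' within-chromosome adjacent marker pair, pooling progeny genotype counts
#' over all families in which the sire is heterozygous (and phased) at both
#' markers. The recombination fraction and the maternal haplotype
#' frequencies are estimated jointly per pair; pairs informative in no
#' family get rate 0 with a warning.
#'
#' @param genotypes Individuals x markers matrix.
#' @param phases An `hs_phase` object for the sires.
#' @param freq Population allele-1 frequencies (initialisation only).
#' @param map Marker map.
#' @return Interval rate tibble as in [deterministic_rates()].
#' @export
pairwise_adjacent_rates <- function(genotypes, phases, freq, map) {
  q <- nrow(map)
  within <- which(map$chr[-q] == map$chr[-1L])
  np <- length(within)
  cnt <- array(0, c(np, 2L, 9L))
  ninf <- numeric(q - 1L)
  gsum <- numeric(q); gn <- numeric(q)
  pos <- integer(q - 1L); pos[within] <- seq_len(np)
  for (fam in phases$families) {
    het <- fam$het & !is.na(fam$hap1)
    P <- genotypes[fam$progeny, , drop = FALSE]
    hcol <- which(het)
    if (length(hcol)) {
      gsum[hcol] <- gsum[hcol] +
        colSums(P[, hcol, drop = FALSE], na.rm = TRUE)
      gn[hcol] <- gn[hcol] + colSums(!is.na(P[, hcol, drop = FALSE]))
    }
    both <- which(het[-q] & het[-1L])
    both <- both[map$chr[both] == map$chr[both + 1L]]
    if (!length(both)) next
    cls <- bitwXor(fam$hap1[both], fam$hap1[both + 1L])
    code <- 3L * P[, both, drop = FALSE] + P[, both + 1L, drop = FALSE]
    for (v in 0:8) {
      add <- colSums(code == v, na.rm = TRUE)
      idx0 <- cls == 0L
      if (any(idx0))
        cnt[cbind(pos[both[idx0]], 1L, v + 1L)] <-
          cnt[cbind(pos[both[idx0]], 1L, v + 1L)] + add[idx0]
      if (any(!idx0))
        cnt[cbind(pos[both[!idx0]], 2L, v + 1L)] <-
          cnt[cbind(pos[both[!idx0]], 2L, v + 1L)] + add[!idx0]
    }
    ninf[both] <- ninf[both] + colSums(!is.na(code))
  }
  # maternal allele frequency at sire-het markers: progeny mean minus the
  # paternal 1/2 contribution (initialises the haplotype frequencies)
  f_use <- ifelse(gn > 0, pmin(pmax(gsum / gn - 0.5, 1e-3), 1 - 1e-3),
                  freq)
  tot <- apply(cnt, 1L, sum)
  theta <- rep(NA_real_, np)
  has <- tot > 0
  if (any(has)) {
    theta[has] <- em_theta(cnt[has, , , drop = FALSE],
                           f_use[within[has]], f_use[within[has] + 1L])
  }
  num <- numeric(q - 1L); den <- numeric(q - 1L)
  num[within] <- ifelse(is.na(theta), 0, theta)
  den[within] <- as.numeric(!is.na(theta))
  if (any(!has)) {
    warning(sum(!has), " interval(s) without informative meioses; rate set 0")
    den[within[!has]] <- 1   # report as defined-zero after the warning
  }
  finish_rates(num, den, map, n_informative = ninf)
}
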