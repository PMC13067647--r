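#' Single-SNP mixed-model association scan
#'
#' Tests each SNP in `y = 1 mu + x m + u + e` with the polygenic covariance
#' fixed at the null-model REML estimates (P3D style): generalised least
#' squares of `m` given `V = K sigma_g^2 + D sigma_e^2`. The test statistic
#' is `T = m_hat / SE(m_hat)` with `P = 2 [1 - Phi(|T|)]`;
#' Benjamini-Hochberg adjusted P values and strong/suggestive flags
#' (defaults 1e-5 / 1e-4) are attached. Individuals missing a SNP's genotype
#' are excluded for that SNP; monomorphic SNPs are skipped. With
#' `per_snp_reml = TRUE` variance components are re-estimated under each
#' SNP's model instead (slower, otherwise identical output columns).
#'
#' @param y Trait vector aligned with rows of `genotypes` and `K`.
#' @param genotypes Candidate-SNP genotype matrix (individuals x markers,
#'   0/1/2/`NA`).
#' @param K Genomic relationship matrix.
#' @param weights Record weights as in [fit_weighted_gblup()].
#' @param map Optional marker map for chromosome/bp columns.
#' @param strong,suggestive P-value thresholds for signal flags.
#' @param per_snp_reml Re-fit variance components per SNP.
#' @return A tibble of class `hs_gwas`: `marker`, `chr`, `bp`, `freq`,
#'   `effect`, `se`, `t`, `p`, `p_bh`, `signal`.
#' @export
gwas_scan <- function(y, genotypes, K, weights = 1, map = NULL,
                      strong = 1e-5, suggestive = 1e-4,
                      per_snp_reml = FALSE) {
  if (is.list(K)) K <- K$K
  n <- length(y)
  assert_that(nrow(genotypes) == n && nrow(K) == n,
              "y, genotypes and K dimensions differ")
  w <- rep_len(weights, n)
  null_fit <- fit_weighted_gblup(y, K, w)
  V <- null_fit$sigma_g2 * K + null_fit$sigma_e2 * diag(1 / w, n)
  Vi <- solve(V)
  q <- ncol(genotypes)
  eff <- se <- fr <- rep(NA_real_, q)
  for (j in seq_len(q)) {
    x <- genotypes[, j]
    ok <- !is.na(x)
    if (!any(ok)) next
    fj <- mean(x[ok]) / 2
    if (fj <= 0 || fj >= 1) next
    fr[j] <- fj
    if (all(ok)) {
      X <- cbind(1, x)
      XtVi <- crossprod(X, Vi)
      B <- solve(XtVi %*% X)
      bhat <- B %*% (XtVi %*% y)
    } else {
      Vs <- solve(V[ok, ok])
      X <- cbind(1, x[ok])
      XtVi <- crossprod(X, Vs)
      B <- solve(XtVi %*% X)
      bhat <- B %*% (XtVi %*% y[ok])
    }
    if (per_snp_reml) {
      f2 <- reml_eigen(y[ok], K[ok, ok], cbind(1, x[ok]), w[ok])
      Vj <- f2$sigma_g2 * K[ok, ok] + f2$sigma_e2 * diag(1 / w[ok],
                                                         sum(ok))
      Vs <- solve(Vj)
      X <- cbind(1, x[ok])
      XtVi <- crossprod(X, Vs)
      B <- solve(XtVi %*% X)
      bhat <- B %*% (XtVi %*% y[ok])
    }
    eff[j] <- bhat[2L]
    se[j] <- sqrt(B[2L, 2L])
  }
  tested <- !is.na(eff)
  tval <- eff / se
  p <- 2 * pnorm(abs(tval), lower.tail = FALSE)
  p_bh <- rep(NA_real_, q)
  p_bh[tested] <- benjamini_hochberg(p[tested])
  out <- tibble::tibble(
    marker = colnames(genotypes) %||% sprintf("snp%d", seq_len(q)),
    chr = if (is.null(map)) NA_integer_ else
      map$chr[match(colnames(genotypes), map$marker)],
    bp = if (is.null(map)) NA_integer_ else
      map$bp[match(colnames(genotypes), map$marker)],
    freq = fr, effect = eff, se = se, t = tval, p = p, p_bh = p_bh,
    signal = dplyr::case_when(
      is.na(p) ~ "untested",
      p < strong ~ "strong",
      p < suggestive ~ "suggestive",
      TRUE ~ "none"))
  attr(out, "null_fit") <- null_fit
  attr(out, "thresholds") <- c(strong = strong, suggestive = suggestive)
  class(out) <- c("hs_gwas", class(out))
  out
}

#' Benjamini-Hochberg adjusted P values
#'
#' Standard step-up false-discovery-rate adjustment (monotone in rank
#' order).
#'
#' @param p Vector of P values in (0, 1].
#' @return Adjusted P values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  assert_that(length(p) > 0, "empty P-value list")
  assert_that(all(p > 0 & p <= 1, na.rm = TRUE), "P values must be in (0,1]")
  p.adjust(p, method = "BH")
}

#' Variance explained by SNPs in a region
#'
#' Roughly approximates the trait variance attributable to a chromosome
#' region as `sigma_x^2 = sum_i 2 f_i (1 - f_i) m_i^2` over the tested SNPs
#' inside it, together with the minimum P value observed.
#'
#' @param gwas An `hs_gwas` result with `chr`/`bp` columns.
#' @param chr Chromosome id.
#' @param begin_mbp,end_mbp Region bounds in Mbp (closed interval).
#' @return One-row tibble `chr`, `begin_mbp`, `end_mbp`, `n_snps`,
#'   `sigma_x2`, `min_p`.
#' @export
region_variance <- function(gwas, chr, begin_mbp, end_mbp) {
  sel <- !is.na(gwas$effect) & gwas$chr == chr &
    gwas$bp >= begin_mbp * 1e6 & gwas$bp <= end_mbp * 1e6
  assert_that(any(sel), "region contains no tested SNP")
  g <- gwas[sel, ]
  tibble::tibble(chr = chr, begin_mbp = begin_mbp, end_mbp = end_mbp,
                 n_snps = nrow(g),
                 sigma_x2 = sum(2 * g$freq * (1 - g$freq) * g$effect^2),
                 min_p = min(g$p))
}

#' Signal-supported regions
#'
#' Groups strong/suggestive SNPs on a chromosome into regions (successive
#' signals at most `max_gap_mbp` apart) and reports regions supported by at
#' least `min_signals` signals, with their explained variance.
#'
#' @param gwas An `hs_gwas` result.
#' @param min_signals Minimum strong+suggestive SNPs per region (default 3).
#' @param max_gap_mbp Maximum gap between successive signals in one region.
#' @return Tibble of regions (possibly empty) in [region_variance()] layout.
#' @export
signal_regions <- function(gwas, min_signals = 3, max_gap_mbp = 5) {
  sig <- gwas[gwas$signal %in% c("strong", "suggestive") &
                !is.na(gwas$bp), ]
  if (nrow(sig) == 0) {
    return(tibble::tibble(chr = integer(), begin_mbp = numeric(),
                          end_mbp = numeric(), n_snps = integer(),
                          sigma_x2 = numeric(), min_p = numeric()))
  }
  sig <- dplyr::arrange(sig, .data$chr, .data$bp)
  new_grp <- c(TRUE, diff(sig$bp) > max_gap_mbp * 1e6 |
                 diff(sig$chr) != 0)
  sig$grp <- cumsum(new_grp)
  spans <- dplyr::summarise(dplyr::group_by(sig, .data$grp),
                            chr = .data$chr[1L],
                            begin_mbp = min(.data$bp) / 1e6,
                            end_mbp = max(.data$bp) / 1e6,
                            n_sig = dplyr::n(), .groups = "drop")
  spans <- spans[spans$n_sig >= min_signals, ]
  dplyr::bind_rows(lapply(seq_len(nrow(spans)), function(i)
    region_variance(gwas, spans$chr[i], spans$begin_mbp[i],
                    spans$end_mbp[i])))
}

#' Genes near GWAS signals
#'
#' Lists genes overlapping a +-`window_bp` interval around each strong or
#' suggestive SNP, nearest first (distance 0 when the gene covers the SNP).
#'
#' @param gwas An `hs_gwas` result.
#' @param genes Gene table with `chr`, `start`, `end`, `name`.
#' @param window_bp Search window (default 500 kb each side).
#' @return Tibble `marker`, `chr`, `bp`, `signal`, `gene`, `distance_bp`.
#' @export
annotate_signals <- function(gwas, genes, window_bp = 5e5) {
  empty <- tibble::tibble(marker = character(), chr = integer(),
                          bp = integer(), signal = character(),
                          gene = character(), distance_bp = numeric())
  if (is.null(genes) || nrow(genes) == 0) {
    message("no gene table supplied; skipping annotation")
    return(empty)
  }
  sig <- gwas[gwas$signal %in% c("strong", "suggestive") &
                !is.na(gwas$bp), ]
  if (nrow(sig) == 0) return(empty)
  out <- lapply(seq_len(nrow(sig)), function(i) {
    g <- genes[genes$chr == sig$chr[i] &
                 genes$end >= sig$bp[i] - window_bp &
                 genes$start <= sig$bp[i] + window_bp, , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    d <- pmax(0, pmax(g$start - sig$bp[i], sig$bp[i] - g$end))
    tibble::tibble(marker = sig$marker[i], chr = sig$chr[i],
                   bp = sig$bp[i], signal = sig$signal[i],
                   gene = g$name[order(d)], distance_bp = sort(d))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) empty else out
}

#' Sex-by-breed analysis of recombination traits
#'
#' Weighted least-squares linear model with fixed effects of sex, breed and
#' their interaction (weights = progeny counts), global F tests per term,
#' least-squares means per sex and per breed, and Tukey-adjusted pairwise
#' differences.
#'
#' @param traits Tibble with the trait column plus `sex`, `breed` and a
#'   weight column.
#' @param trait Name of the trait column.
#' @param weight_col Name of the weight column (default `"n_progeny"`).
#' @return A list with `anova` (tibble of F tests), `lsmeans_sex`,
#'   `lsmeans_breed` and `pairwise_sex`, `pairwise_breed` (Tukey-adjusted).
#' @export
anova_sex_breed <- function(traits, trait, weight_col = "n_progeny") {
  assert_that(length(unique(traits$sex)) >= 2 &&
                length(unique(traits$breed)) >= 2,
              "need at least two levels of sex and breed")
  d <- data.frame(y = traits[[trait]],
                  sex = factor(traits$sex), breed = factor(traits$breed),
                  w = traits[[weight_col]])
  fit <- lm(y ~ sex * breed, data = d, weights = w)
  an <- anova(fit)
  an_tb <- tibble::tibble(term = rownames(an), df = an$Df,
                          f = an$`F value`, p = an$`Pr(>F)`)
  em_sex <- emmeans::emmeans(fit, "sex")
  em_breed <- emmeans::emmeans(fit, "breed")
  list(
    anova = an_tb,
    lsmeans_sex = tibble::as_tibble(as.data.frame(em_sex)),
    lsmeans_breed = tibble::as_tibble(as.data.frame(em_breed)),
    pairwise_sex = tibble::as_tibble(as.data.frame(
      emmeans::contrast(em_sex, method = "pairwise", adjust = "tukey"))),
    pairwise_breed = tibble::as_tibble(as.data.frame(
      emmeans::contrast(em_breed, method = "pairwise", adjust = "tukey"))),
    fit = fit
  )
}
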