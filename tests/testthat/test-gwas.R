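founder_geno2 <- function(n, q, seed) {
  map <- sim_physical_map(q = q, length_morgan = 1, length_bp = 1e8)
  f <- sim_founders(n, map, seed = seed)
  G <- f$haplotypes[seq(1, 2 * n, 2), ] + f$haplotypes[seq(2, 2 * n, 2), ]
  colnames(G) <- map$marker
  list(G = G, map = map)
}

test_that("the scan reports GLS effects with normal-approximation P values", {
  set.seed(131)
  d <- founder_geno2(200, 300, seed = 132)
  K <- build_grm(d$G)$K + diag(1e-6, 200)
  y <- rnorm(200)
  gw <- gwas_scan(y, d$G[, 1:100], K, map = d$map)
  tested <- !is.na(gw$p)
  expect_equal(gw$p[tested],
               2 * pnorm(abs(gw$t[tested]), lower.tail = FALSE))
  expect_true(all(gw$p_bh[tested] >= gw$p[tested]))
  expect_true(all(gw$chr[tested] == 1))
  # missing genotypes exclude individuals, monomorphic SNPs are skipped
  X <- d$G[, 1:5]
  X[1:10, 1] <- NA; X[, 2] <- 2L
  gw2 <- gwas_scan(y, X, K)
  expect_equal(gw2$signal[2], "untested")
  expect_false(is.na(gw2$effect[1]))
})

test_that("a planted SNP effect dominates the scan", {
  set.seed(141)
  d <- founder_geno2(500, 400, seed = 142)
  K <- build_grm(d$G)$K + diag(1e-6, 500)
  hits <- replicate(10, {
    j <- sample(400, 1)
    x <- d$G[, j]
    # scale residual so the SNP explains ~20% of variance
    vx <- stats::var(x)
    y <- x + rnorm(500, sd = sqrt(4 * vx))
    gw <- gwas_scan(y, d$G, K)
    which.min(gw$p) == j
  })
  expect_gte(sum(hits), 8)
})

test_that("per-SNP REML mode agrees with P3D on null data", {
  set.seed(151)
  d <- founder_geno2(120, 200, seed = 152)
  K <- build_grm(d$G)$K + diag(1e-6, 120)
  y <- rnorm(120)
  g1 <- gwas_scan(y, d$G[, 1:20], K)
  g2 <- gwas_scan(y, d$G[, 1:20], K, per_snp_reml = TRUE)
  expect_gt(cor(g1$t, g2$t, use = "complete.obs"), 0.98)
})

test_that("region variance follows the 2f(1-f)m^2 sum", {
  gw <- tibble::tibble(
    marker = c("a", "b", "c"), chr = 1L,
    bp = c(1e6, 2e6, 50e6), freq = c(0.1, 0.25, 0.5),
    effect = c(2, 1, 0), se = 1, t = c(2, 1, 0),
    p = c(0.04, 0.3, 1), p_bh = c(0.12, 0.45, 1),
    signal = c("none", "none", "none"))
  class(gw) <- c("hs_gwas", class(gw))
  rv <- region_variance(gw, chr = 1, begin_mbp = 0, end_mbp = 3)
  expect_equal(rv$sigma_x2, 2 * 0.1 * 0.9 * 4 + 2 * 0.25 * 0.75 * 1)
  expect_equal(rv$sigma_x2, 1.095)
  expect_equal(rv$min_p, 0.04)
  expect_equal(rv$n_snps, 2)
  one <- region_variance(gw, 1, 49, 51)
  expect_equal(one$sigma_x2, 0)
  gw$effect[3] <- 1
  expect_equal(region_variance(gw, 1, 49, 51)$sigma_x2, 0.5)
  expect_error(region_variance(gw, 2, 0, 1), "no tested SNP")
})

test_that("Benjamini-Hochberg adjustment is the textbook step-up", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)),
               c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  p <- runif(50)
  adj <- benjamini_hochberg(p)
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  expect_error(benjamini_hochberg(numeric(0)), "empty")
})

test_that("gene annotation respects the 500 kb window", {
  gw <- tibble::tibble(marker = "s1", chr = 6L, bp = 10e6, freq = 0.3,
                       effect = 1, se = 0.1, t = 10, p = 1e-8,
                       p_bh = 1e-7, signal = "strong")
  class(gw) <- c("hs_gwas", class(gw))
  genes <- tibble::tibble(chr = 6L,
                          start = c(10.4e6, 10.6e6),
                          end = c(10.45e6, 10.7e6),
                          name = c("inside", "outside"))
  ann <- annotate_signals(gw, genes)
  expect_equal(ann$gene, "inside")
  expect_equal(ann$distance_bp, 0.4e6)
  empty <- annotate_signals(gw, genes[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("signal regions require enough supporting SNPs", {
  gw <- tibble::tibble(
    marker = sprintf("s%d", 1:6), chr = c(1L, 1L, 1L, 1L, 2L, 2L),
    bp = c(1e6, 2e6, 3e6, 40e6, 1e6, 2e6), freq = 0.5,
    effect = 1, se = 0.1, t = 10,
    p = c(1e-6, 1e-6, 5e-5, 1e-6, 1e-6, 0.5),
    p_bh = 1e-5,
    signal = c("strong", "strong", "suggestive", "strong", "strong",
               "none"))
  class(gw) <- c("hs_gwas", class(gw))
  reg <- signal_regions(gw, min_signals = 3, max_gap_mbp = 5)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$chr, 1)
  expect_equal(reg$n_snps, 3)
})

test_that("sex-by-breed ANOVA gives cell means and Tukey contrasts", {
  set.seed(161)
  d <- expand.grid(sex = c("male", "female"),
                   breed = c("A", "B"), rep = 1:20)
  d$n_progeny <- 1
  d$nco <- 20 + (d$sex == "male") * 3 + (d$breed == "B") * 1 + rnorm(80)
  out <- anova_sex_breed(tibble::as_tibble(d), "nco")
  cell <- tapply(d$nco, list(d$sex, d$breed), mean)
  ls <- out$lsmeans_sex
  expect_equal(sort(ls$emmean), unname(sort(rowMeans(cell))),
               tolerance = 1e-8)
  expect_lt(out$anova$p[out$anova$term == "sex"], 0.01)
  # two groups: Tukey adjustment leaves the pairwise P value unadjusted
  unadj <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(out$fit, "sex"), method = "pairwise",
    adjust = "none"))
  expect_equal(out$pairwise_sex$p.value, unadj$p.value, tolerance = 1e-10)

  # weights equal record replication for the coefficients
  dw <- tibble::as_tibble(d[1:40, ])
  dw$n_progeny <- 3
  drep <- dw[rep(seq_len(nrow(dw)), 3), ]
  drep$n_progeny <- 1
  cw <- coef(anova_sex_breed(dw, "nco")$fit)
  cr <- coef(anova_sex_breed(drep, "nco")$fit)
  expect_equal(cw, cr, tolerance = 1e-10)
})
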