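# founder-style genotypes for n unrelated individuals
founder_geno <- function(n, q, seed) {
  map <- sim_physical_map(q = q, length_morgan = 1, length_bp = 1e8)
  f <- sim_founders(n, map, seed = seed)
  f$haplotypes[seq(1, 2 * n, 2), ] + f$haplotypes[seq(2, 2 * n, 2), ]
}

test_that("missingness filter applies individual-then-marker order", {
  G <- matrix(0L, 10, 10)
  G[1, 1:3] <- NA            # individual 1: 30% missing -> removed
  G[, 10] <- NA_integer_     # marker 10: all missing -> removed
  G[5:6, 5] <- NA            # marker 5: 2/9 = 22% after removal -> removed
  rownames(G) <- sprintf("i%d", 1:10); colnames(G) <- sprintf("m%d", 1:10)
  out <- filter_missingness(G)
  expect_equal(out$report$individuals_removed, 1)
  expect_equal(sort(setdiff(colnames(G), colnames(out$genotypes))),
               c("m10", "m5"))
})

test_that("the GRM has VanRaden structure", {
  G <- founder_geno(200, 800, seed = 71)
  grm <- build_grm(G)
  expect_equal(grm$K, t(grm$K), tolerance = 1e-12)
  # standardised diagonal averages 1 for unrelated individuals
  expect_lt(abs(mean(diag(grm$K)) - 1), 0.05)
  # duplicated genotype rows are as related to each other as to themselves
  G2 <- rbind(G[1:50, ], G[1, , drop = FALSE])
  grm2 <- build_grm(G2)
  expect_equal(grm2$K[51, 1], grm2$K[1, 1], tolerance = 1e-12)
  # monomorphic markers are excluded
  Gm <- cbind(G, mono = rep(2L, 200))
  expect_equal(build_grm(Gm)$n_markers, grm$n_markers)
})

test_that("GBLUP equals a direct dense-matrix solve on small instances", {
  set.seed(81)
  n <- 50
  G <- founder_geno(n, 400, seed = 82)
  grm <- build_grm(G)
  K <- grm$K + diag(1e-6, n)
  u <- drop(chol(K) %*% rnorm(n)) * sqrt(0.6)
  w <- sample(1:4, n, replace = TRUE)
  y <- 2 + u + rnorm(n, sd = sqrt(0.4 / w))
  fit <- fit_weighted_gblup(y, K, weights = w)
  oracle <- direct_gblup_oracle(y, K, w, fit$sigma_g2, fit$sigma_e2)
  expect_equal(fit$mu, oracle$mu, tolerance = 1e-8)
  expect_equal(fit$blup, oracle$u, tolerance = 1e-8)
})

test_that("weighted GLS equals the replicated-record solve for integer
           weights", {
  set.seed(91)
  n <- 30
  G <- founder_geno(n, 300, seed = 92)
  K <- build_grm(G)$K + diag(1e-6, n)
  w <- sample(1:3, n, replace = TRUE)
  y <- 1 + drop(chol(K) %*% rnorm(n)) + rnorm(n, sd = 1 / sqrt(w))
  sg2 <- 0.8; se2 <- 1.1
  fit_w <- direct_gblup_oracle(y, K, w, sg2, se2)
  # replicate record i w_i times; the duplicated records share the animal
  idx <- rep(seq_len(n), w)
  Z <- matrix(0, length(idx), n); Z[cbind(seq_along(idx), idx)] <- 1
  V_rep <- sg2 * Z %*% K %*% t(Z) + se2 * diag(length(idx))
  Vi <- solve(V_rep)
  one <- rep(1, length(idx)); y_rep <- y[idx]
  mu_rep <- drop(crossprod(one, Vi %*% y_rep) /
                   crossprod(one, Vi %*% one))
  u_rep <- drop(sg2 * K %*% t(Z) %*% Vi %*% (y_rep - mu_rep))
  expect_equal(fit_w$mu, mu_rep, tolerance = 1e-8)
  expect_equal(fit_w$u, u_rep, tolerance = 1e-8)
})

test_that("REML recovers heritability and weights cancel when equal", {
  set.seed(101)
  n <- 500
  G <- founder_geno(n, 1000, seed = 102)
  grm <- build_grm(G)
  K <- grm$K + diag(1e-6, n)
  ch <- chol(K)
  h2_hat <- replicate(8, {
    u <- drop(t(ch) %*% rnorm(n)) * sqrt(0.5)
    y <- u + rnorm(n, sd = sqrt(0.5))
    fit_weighted_gblup(y, K)$h2
  })
  expect_lt(abs(mean(h2_hat) - 0.5), 0.1)

  u <- drop(t(ch) %*% rnorm(n)) * sqrt(0.5)
  y <- u + rnorm(n, sd = sqrt(0.5))
  f1 <- fit_weighted_gblup(y, K)
  f2 <- fit_weighted_gblup(y, K, weights = rep(7, n))
  # constant weights only rescale the residual component: same genetic
  # variance, same marginal covariance, identical predictions
  expect_equal(f2$sigma_g2, f1$sigma_g2, tolerance = 1e-4)
  expect_equal(f2$sigma_e2, 7 * f1$sigma_e2, tolerance = 1e-3)
  expect_equal(f1$blup, f2$blup, tolerance = 1e-4)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-6)
})

test_that("pure-noise traits give near-zero heritability", {
  set.seed(111)
  n <- 300
  K <- build_grm(founder_geno(n, 600, seed = 112))$K + diag(1e-6, n)
  h2_null <- replicate(6, fit_weighted_gblup(rnorm(n), K)$h2)
  expect_lte(mean(h2_null), 0.05)
})

test_that("the restricted LRT uses the boundary mixture", {
  expect_equal(rlrt_genomic_variance(0, 0)$p_value, 0.5)
  expect_equal(rlrt_genomic_variance(2.706 / 2, 0)$p_value, 0.05,
               tolerance = 1e-3)
  expect_warning(out <- rlrt_genomic_variance(0, 1e-3), "negative")
  expect_equal(out$lrt, 0)
})

test_that("bivariate cross-sex model recovers shared and independent
           architectures", {
  set.seed(121)
  n <- 300                       # 150 per sex
  G <- founder_geno(n, 600, seed = 122)
  K <- build_grm(G)$K + diag(1e-6, n)
  ch <- t(chol(K))
  sex <- rep(c("male", "female"), each = n / 2)
  # same genetic effect drives both sexes: correlation near 1
  u <- drop(ch %*% rnorm(n))
  y_shared <- u + rnorm(n, sd = 0.4)
  f_sh <- fit_bivariate_gblup(y_shared, sex, K)
  expect_gt(f_sh$correlation, 0.8)
  # independent effects per sex: correlation near 0
  u2 <- drop(ch %*% rnorm(n))
  y_ind <- ifelse(sex == "male", u, u2) + rnorm(n, sd = 0.4)
  f_in <- fit_bivariate_gblup(y_ind, sex, K)
  expect_lt(abs(f_in$correlation), 0.35)
  expect_true(is.finite(f_in$loglik))
  td <- tidy(f_in)
  expect_equal(td$estimate[td$term == "sigma_sd"],
               f_in$correlation * sqrt(prod(diag(f_in$Sigma))),
               tolerance = 1e-8)
})
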