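test_that("forward-backward posteriors equal exhaustive enumeration", {
  set.seed(55)
  for (rep in 1:4) {
    q <- sample(6:10, 1)
    hap1 <- rbinom(q, 1, 0.5)
    hap2 <- 1L - hap1
    rates <- runif(q - 1, 0, 0.3)
    pb <- runif(q, 0.1, 0.9)
    # progeny genotype consistent with the model, some entries missing
    a <- ifelse(rbinom(q, 1, 0.5) == 1, hap1, hap2)
    g <- a + rbinom(q, 1, pb)
    g[sample(q, 2)] <- NA
    out <- hmm_posterior(g, hap1, hap2, rates, freq = pb)
    oracle <- enum_posterior(g, hap1, hap2, rates, pb)
    expect_equal(unname(out$posterior[, 1]), oracle$post1, tolerance = 1e-10)
    expect_equal(out$loglik, oracle$loglik, tolerance = 1e-10)
    # posteriors sum to one by construction of the two columns
    expect_equal(rowSums(out$posterior), rep(1, q), tolerance = 1e-12)
  }
})

test_that("degenerate chains behave as expected", {
  q <- 8
  hap1 <- rep(0L, q); hap2 <- rep(1L, q)
  # zero rates: absorbing chain, constant origin, no switches
  g <- c(0L, 0L, rep(NA, q - 2))   # transmitted allele 0, maternal 0
  out <- hmm_posterior(g, hap1, hap2, rep(0, q - 1), freq = rep(1e-6, q))
  expect_true(all(out$path == 1L))
  # fully discriminating marker: posterior 1 there
  out2 <- hmm_posterior(c(0L, rep(NA, q - 1)), hap1, hap2,
                        rep(0.01, q - 1), freq = rep(1e-9, q))
  expect_equal(unname(out2$posterior[1, 1]), 1, tolerance = 1e-6)
})

test_that("decoded crossover counts equal simulated truth when every marker
           discriminates", {
  map <- sim_physical_map(q = 80, length_morgan = 0.8, length_bp = 1e7)
  sim <- fully_informative_family(60, map, seed = 77)
  fit <- estimate_map(sim, method = "hmm", two_run = FALSE, min_progeny = 5)
  xo_true <- sim$truth$crossovers[sim$truth$crossovers$side == "paternal", ]
  true_n <- table(factor(xo_true$progeny,
                         levels = fit$n_crossovers$progeny))
  expect_equal(unname(fit$n_crossovers$n), as.vector(true_n))
  # and every recorded interval matches the true flanking markers
  xo_est <- locate_crossovers(fit)
  expect_equal(nrow(xo_est), nrow(xo_true))
  est_key <- paste(xo_est$progeny, xo_est$left_bp, xo_est$right_bp)
  true_key <- paste(xo_true$progeny, xo_true$left_bp, xo_true$right_bp)
  expect_setequal(est_key, true_key)
})

test_that("EM rate estimation counts switches and flags empty intervals", {
  # known paths: 3 switches among 100 meioses in one interval
  q <- 4
  E1 <- matrix(1, 100, q); E2 <- E1
  # meiosis-specific informative emissions at every marker: allele known
  E1[, ] <- 0.999; E2[, ] <- 0.001
  E1[1:3, 3:4] <- 0.001; E2[1:3, 3:4] <- 0.999
  map <- sim_physical_map(q = q, length_morgan = 0.03, length_bp = 1e6)
  stack <- list(E1 = E1, E2 = E2,
                meta = tibble::tibble(progeny = sprintf("p%d", 1:100),
                                      parent = "S"))
  em <- hsmapr:::hmm_em(stack, map)
  expect_equal(em$p[2], 0.03, tolerance = 1e-3)
  expect_lt(em$p[1], 1e-3)

  # total map length recovered within 5% on a simulated scenario
  map2 <- sim_physical_map(q = 400, length_morgan = 1, length_bp = 1e8)
  sim <- sim_half_sib_population(10, 100, map2, n_founders = 300, seed = 13)
  fit <- estimate_map(sim, method = "hmm")
  expect_lt(abs(map_accuracy(fit$map_est, map2) - 1), 0.05)
})

test_that("confidence score is 1 on clean data and exposes planted
           misplacement", {
  # short map: immediate double crossovers (which legitimately lower the
  # local-consistency score) are vanishingly rare
  map <- sim_physical_map(q = 150, length_morgan = 0.2, length_bp = 1e8)
  sim <- sim_half_sib_population(6, 60, map, n_founders = 150, seed = 42)
  fit <- estimate_map(sim, method = "hmm", two_run = FALSE)
  informative <- !is.na(fit$mcs)
  expect_true(all(fit$mcs[informative] == 1))

  # permute one marker's progeny genotypes: planted misplacement
  bad <- 75L
  simp <- sim
  prog <- simp$pedigree$id[!is.na(simp$pedigree$sire)]
  simp$genotypes[prog, bad] <- sample(simp$genotypes[prog, bad])
  fitp <- estimate_map(simp, method = "hmm", two_run = FALSE)
  expect_lt(fitp$mcs[bad], 0.986)
  expect_equal(which.min(fitp$mcs), bad)

  # the two-run filter removes it from the final map
  fit2 <- estimate_map(simp, method = "hmm", two_run = TRUE)
  expect_false(map$marker[bad] %in% fit2$map_est$marker)
  expect_gte(fit2$removed$q_ex, 1)
})

test_that("two-run filtering is idempotent once applied and removes
           high-crossover individuals when the cap binds", {
  map <- sim_physical_map(q = 150, length_morgan = 0.2, length_bp = 1e8)
  sim <- sim_half_sib_population(6, 60, map, n_founders = 150, seed = 42)
  f1 <- estimate_map(sim, method = "hmm", two_run = FALSE)
  f2 <- estimate_map(sim, method = "hmm", two_run = TRUE)
  expect_equal(f2$removed$n_ex, 0)

  # re-running the pipeline on the already-filtered data changes nothing
  keep <- match(f2$map_used$marker, sim$map$marker)
  sim_red <- sim
  sim_red$genotypes <- sim$genotypes[, keep]
  sim_red$map <- sim$map[keep, ]
  f3 <- estimate_map(sim_red, method = "hmm", two_run = TRUE)
  expect_equal(sum(unlist(f3$removed)), 0)
  expect_equal(f3$rates$rate, f2$rates$rate, tolerance = 1e-12)

  # lower the crossover cap: individuals above it disappear from run 2
  many <- f1$n_crossovers$progeny[f1$n_crossovers$n > 1]
  expect_gt(length(many), 0)
  f4 <- estimate_map(sim, method = "hmm", two_run = TRUE,
                     max_crossovers = 1)
  expect_equal(f4$removed$n_ex, length(many))
  expect_false(any(many %in% f4$n_crossovers$progeny))
})

test_that("map length is invariant to a global parent-haplotype swap", {
  map <- sim_physical_map(q = 120, length_morgan = 0.5, length_bp = 1e7)
  sim <- sim_half_sib_population(4, 50, map, n_founders = 100, seed = 3)
  fit <- estimate_map(sim, method = "hmm", phase_source = "truth",
                      two_run = FALSE)
  sim_sw <- sim
  # swap the two homologs of every parent
  idx <- seq_len(nrow(sim$parent_haplotypes))
  swap <- idx + ifelse(idx %% 2 == 1, 1L, -1L)
  sim_sw$parent_haplotypes <- sim$parent_haplotypes[swap, ]
  fit_sw <- estimate_map(sim_sw, method = "hmm", phase_source = "truth",
                         two_run = FALSE)
  expect_equal(map_total_length(fit$map_est),
               map_total_length(fit_sw$map_est), tolerance = 1e-10)
})

test_that("near-double-crossover proportions follow the distance rule", {
  xo <- tibble::tibble(
    progeny = c("p1", "p1", "p2", "p3"),
    parent = "S",
    chr = c(1L, 1L, 1L, 2L),
    midpoint_bp = c(10e6, 11.5e6, 40e6, 5e6))
  out <- near_double_crossover_stats(xo, threshold_bp = 2e6)
  # the 1.5 Mbp pair counts twice on chr 1; the lone crossovers do not
  expect_equal(out$proportion[out$chr == 1], 2 / 3)
  expect_equal(out$proportion[out$chr == 2], 0)
  out0 <- near_double_crossover_stats(xo, threshold_bp = 0)
  expect_true(all(out0$proportion == 0))
})
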