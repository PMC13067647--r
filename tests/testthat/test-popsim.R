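test_that("physical map construction matches the design rules", {
  # even spacing: q markers share the chromosome length equally
  m <- sim_physical_map(q = 4000, length_morgan = 1, length_bp = 1e8)
  expect_equal(nrow(m), 4000)
  expect_equal(m$rate[-4000], rep(1 / 3999, 3999))
  expect_equal(max(m$pos_morgan), 1)

  # zero-length map
  m0 <- sim_physical_map(q = 2, length_morgan = 0, length_bp = 1e6)
  expect_equal(m0$rate[1], 0)
  expect_equal(m0$pos_morgan, c(0, 0))

  # semi-real 1 cM : 1 Mbp transform of supplied positions
  ms <- sim_physical_map(q = 2, length_bp = 2e6,
                         positions_bp = list(c(10L, 1000000L)))
  expect_equal(ms$rate[1], (1000000 - 10) / 1e8)
  expect_equal(ms$rate[1], 0.0099999, tolerance = 1e-12)

  expect_error(sim_physical_map(q = 3, positions_bp = list(c(5L, 4L, 9L))),
               "increasing")
  expect_error(sim_physical_map(q = 1), "at least 2")
})

test_that("founder simulation respects the MAF law and the seed", {
  map <- sim_physical_map(q = 50, length_morgan = 0.5, length_bp = 1e7)
  f <- sim_founders(1000, map, maf = 0.5, seed = 3)
  # empirical allele frequency within 3 binomial SEs of 0.5
  se <- sqrt(0.25 / 2000)
  expect_true(all(abs(colMeans(f$haplotypes) - 0.5) < 3.5 * se))
  expect_error(sim_founders(10, map, maf = 0), "frequencies")
  f2 <- sim_founders(1000, map, maf = 0.5, seed = 3)
  expect_identical(f$haplotypes, f2$haplotypes)
})

test_that("meiosis has Bernoulli crossovers without interference", {
  map <- sim_physical_map(q = 10, length_morgan = 0, length_bp = 1e6)
  haps <- rbind(rep(0L, 10), rep(1L, 10))
  z <- sim_meiosis(haps, map, n = 5, seed = 1)
  expect_equal(nrow(z$crossovers), 0)
  expect_true(all(z$gametes %in% c(0L, 1L)))
  expect_true(all(apply(z$gametes, 1L, function(g)
    all(g == 0L) || all(g == 1L))))

  # theta = 0.5: switch frequency 0.5 within 3 SE over 10,000 gametes
  map2 <- sim_physical_map(q = 2, length_morgan = 0.5, length_bp = 1e6)
  z2 <- sim_meiosis(haps[, 1:2], map2, n = 10000, seed = 2)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(nrow(z2$crossovers) / 10000 - 0.5), 3 * se)

  # expected crossovers per gamete = total map length (1 Morgan)
  map3 <- sim_physical_map(q = 101, length_morgan = 1, length_bp = 1e7)
  z3 <- sim_meiosis(rbind(rep(0L, 101), rep(1L, 101)), map3, n = 10000,
                    seed = 3)
  se3 <- sqrt(1 / 10000)   # variance of the switch count is ~ map length
  expect_lt(abs(nrow(z3$crossovers) / 10000 - 1), 3 * se3)
})

test_that("per-interval switch counts are independent Bernoulli trials", {
  rates <- c(0.05, 0.1, 0.2, 0.3, 0.4)
  map <- sim_physical_map(q = 6, length_morgan = sum(rates),
                          length_bp = 1e6)
  map$rate[1:5] <- rates
  n <- 4000
  z <- sim_meiosis(rbind(rep(0L, 6), rep(1L, 6)), map, n = n, seed = 9)
  obs <- tabulate(z$crossovers$interval, nbins = 5)
  exp_n <- n * rates
  x2 <- sum((obs - exp_n)^2 / (exp_n * (1 - rates)))
  expect_gt(pchisq(x2, df = 5, lower.tail = FALSE), 0.01)
})

test_that("half-sib population has exact structure, truth and determinism", {
  map <- sim_physical_map(q = 60, length_morgan = 1, length_bp = 1e7)
  sim <- sim_half_sib_population(10, 50, map, n_founders = 200, seed = 5)
  prog <- sim$pedigree[!is.na(sim$pedigree$sire), ]
  expect_equal(nrow(prog), 500)
  expect_equal(length(unique(prog$sire)), 10)
  expect_true(all(table(prog$sire) == 50))

  # conservation: progeny genotype = paternal + maternal gamete, exactly
  tg <- true_gametes(sim, "paternal")
  tm <- true_gametes(sim, "maternal")
  expect_identical(unname(sim$genotypes[tg$progeny, ]),
                   unname(tg$gametes + tm$gametes))

  # recorded crossover count equals origin-switch count per gamete
  sw <- rowSums(tg$origin[, -1, drop = FALSE] !=
                  tg$origin[, -ncol(tg$origin), drop = FALSE])
  xo <- sim$truth$crossovers[sim$truth$crossovers$side == "paternal", ]
  expect_equal(unname(sw), as.vector(table(factor(xo$progeny,
                                                  levels = tg$progeny))))

  sim2 <- sim_half_sib_population(10, 50, map, n_founders = 200, seed = 5)
  expect_identical(sim$genotypes, sim2$genotypes)
  expect_identical(sim$truth$crossovers, sim2$truth$crossovers)

  mini <- sim_half_sib_population(1, 1, map, n_founders = 10, seed = 1)
  expect_equal(sum(!is.na(mini$pedigree$sire)), 1)
  expect_equal(nrow(mini$truth$start_origin), 1)
})

test_that("masking hits the requested fraction and keeps truth intact", {
  map <- sim_physical_map(q = 500, length_morgan = 1, length_bp = 1e7)
  sim <- sim_half_sib_population(10, 100, map, n_founders = 300, seed = 6)
  n_entries <- length(sim$genotypes)
  m <- mask_genotypes(sim, fraction = 0.5, seed = 1)
  se <- sqrt(0.25 / n_entries)
  expect_lt(abs(mean(is.na(m$genotypes)) - 0.5), 3 * se)
  expect_false(anyNA(m$genotypes_true))
  expect_identical(m$truth, sim$truth)

  m0 <- mask_genotypes(sim, fraction = 0)
  expect_identical(m0$genotypes, sim$genotypes)

  blk <- data.frame(marker_from = 100L, marker_to = 114L,
                    sample_fraction = 0.27)
  mb <- mask_genotypes(sim, blocks = blk, seed = 2)
  hit_rows <- rowSums(is.na(mb$genotypes[, 100:114])) == 15
  expect_lt(abs(mean(hit_rows) - 0.27), 3 * sqrt(0.27 * 0.73 / nrow(mb$genotypes)))
  expect_error(mask_genotypes(sim, fraction = 1.2), "fraction")
})
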