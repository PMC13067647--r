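#' Build a physical marker map with a known genetic map
#'
#' Creates the marker scaffold used by the simulator: physical positions in bp
#' and a "true" genetic map given as per-interval recombination rates in Morgan
#' units. With `positions_bp = NULL` markers are spread evenly over each
#' chromosome and the chromosome's genetic length is split evenly across
#' intervals. Supplying `positions_bp` switches to the semi-real design where
#' genetic distances are a linear transform of physical distances
#' (`cm_per_mbp`, default 1 cM per Mbp).
#'
#' @param q Markers per chromosome (vectorised over chromosomes).
#' @param length_morgan Genetic length per chromosome in Morgan.
#' @param length_bp Physical length per chromosome in bp.
#' @param chr Chromosome ids (defaults to `seq_along(q)`).
#' @param positions_bp Optional list (one vector per chromosome) of strictly
#'   increasing physical positions; overrides even spacing.
#' @param cm_per_mbp Genetic:physical ratio used when `positions_bp` is given.
#' @return A tibble with columns `marker`, `chr`, `bp`, `rate` (recombination
#'   rate to the next marker on the same chromosome, `NA` at chromosome ends)
#'   and `pos_morgan` (cumulative coordinate, 0 at each chromosome start).
#' @export
#' @examples
#' sim_physical_map(q = 10, length_morgan = 1, length_bp = 1e6)
sim_physical_map <- function(q, length_morgan = 1, length_bp = 1e8,
                             chr = seq_along(q), positions_bp = NULL,
                             cm_per_mbp = 1) {
  n_chr <- length(q)
  length_morgan <- rep_len(length_morgan, n_chr)
  length_bp <- rep_len(length_bp, n_chr)
  assert_that(all(q >= 2), "need at least 2 markers per chromosome")
  assert_that(all(length_morgan >= 0) && all(length_bp > 0),
              "map lengths must be non-negative (bp strictly positive)")
  pieces <- vector("list", n_chr)
  for (k in seq_len(n_chr)) {
    if (is.null(positions_bp)) {
      bp <- round(seq(1, length_bp[k], length.out = q[k]))
      rate <- rep(length_morgan[k] / (q[k] - 1), q[k] - 1)
    } else {
      bp <- positions_bp[[k]]
      assert_that(length(bp) == q[k], "positions_bp length must match q")
      assert_that(all(diff(bp) > 0),
                  "physical positions must be strictly increasing")
      # 1:1-style transform: interval genetic length from physical spacing
      rate <- diff(bp) / 1e6 * cm_per_mbp / 100
    }
    rate <- pmin(rate, 0.5)
    pos <- cumsum(c(0, rate))
    rate_col <- c(rate, NA_real_)
    pieces[[k]] <- tibble::tibble(
      marker = sprintf("chr%s_m%d", chr[k], seq_len(q[k])),
      chr = as.integer(chr[k]),
      bp = as.integer(bp),
      rate = rate_col,
      pos_morgan = pos
    )
  }
  dplyr::bind_rows(pieces)
}

# per-interval transition probabilities over the full marker vector:
# within-chromosome intervals carry the map rate; chromosome boundaries get
# probability 0.5 (independent assortment) and are flagged
transition_table <- function(map) {
  q <- nrow(map)
  boundary <- map$chr[-q] != map$chr[-1]
  p <- ifelse(boundary, 0.5, map$rate[-q])
  assert_that(!anyNA(p), "map rate missing on a within-chromosome interval")
  assert_that(all(p >= 0 & p <= 0.5), "rates must lie in [0, 0.5]")
  list(p = p, boundary = boundary)
}

#' Simulate founder haplotypes in linkage equilibrium
#'
#' Draws one allele frequency per marker from the MAF law, then samples founder
#' alleles independently across markers and haplotypes (linkage-equilibrium
#' baseline; no founder LD).
#'
#' @param n Number of founder individuals.
#' @param map Marker map from [sim_physical_map()].
#' @param maf Either a single fixed minor allele frequency in (0, 0.5] or a
#'   range `c(lo, hi)` for a Uniform(lo, hi) law. Default Uniform(0.05, 0.5).
#' @param seed Optional RNG seed.
#' @return A list with `haplotypes` (integer matrix, `2n` rows = two gametes
#'   per founder in order, `q` columns), `freq` (per-marker allele-1
#'   frequency) and `ids`.
#' @export
sim_founders <- function(n, map, maf = c(0.05, 0.5), seed = NULL) {
  q <- nrow(map)
  assert_that(n >= 1, "need at least one founder")
  assert_that(all(maf > 0) && all(maf <= 0.5),
              "maf law must yield frequencies in (0, 0.5]")
  with_seed(seed, {
    freq <- if (length(maf) == 1L) rep(maf, q) else runif(q, maf[1], maf[2])
    H <- matrix(as.integer(runif(2L * n * q) < rep(freq, each = 2L * n)),
                nrow = 2L * n, ncol = q)
    list(haplotypes = H, freq = freq,
         ids = sprintf("F%d", seq_len(n)))
  })
}

# Sample gamete origin paths for `n` meioses over one transition table.
# Returns origin matrix (n x q, values 1/2) and the switch list (gamete,
# interval index), with chromosome-boundary pseudo-switches excluded from the
# crossover record but applied to the path.
sample_origins <- function(n, trans) {
  q <- length(trans$p) + 1L
  gam <- integer(0); itv <- integer(0)
  for (j in seq_along(trans$p)) {
    pj <- trans$p[j]
    if (pj <= 0) next
    k <- rbinom(1L, n, pj)
    if (k > 0L) {
      gam <- c(gam, sample.int(n, k))
      itv <- c(itv, rep.int(j, k))
    }
  }
  start <- sample.int(2L, n, replace = TRUE)
  origin <- origin_from_switches(n, q, start, gam, itv)
  keep <- if (length(itv)) !trans$boundary[itv] else logical(0)
  list(origin = origin, start = start,
       gamete = gam[keep], interval = itv[keep])
}

# expand a sparse switch list into the full origin-path matrix (values 1/2)
origin_from_switches <- function(n, q, start, gam, itv) {
  cum <- matrix(0L, n, q)
  for (s in seq_along(gam)) {
    cols <- (itv[s] + 1L):q
    cum[gam[s], cols] <- cum[gam[s], cols] + 1L
  }
  ((start - 1L) + cum) %% 2L + 1L
}

alleles_from_origin <- function(origin, H1, H2) {
  # origin: n x q in {1,2}; H1/H2: n x q allele matrices for each homolog
  out <- H1
  sel <- origin == 2L
  out[sel] <- H2[sel]
  out
}

#' Simulate meioses of one parent
#'
#' Crossovers occur independently in each marker interval with probability
#' equal to the interval recombination rate (no interference); the gamete
#' starts on a fair-coin homolog. Chromosome boundaries (if `map` has several
#' chromosomes) assort independently and are not recorded as crossovers.
#'
#' @param haplotypes Integer matrix with 2 rows (the parent's homologs) and
#'   one column per marker.
#' @param map Marker map from [sim_physical_map()] (supplies rates and
#'   chromosome structure).
#' @param n Number of gametes to draw.
#' @param seed Optional RNG seed.
#' @return A list with `gametes` (n x q integer matrix), `crossovers` (tibble
#'   `gamete`, `interval`, `chr`, `left_bp`, `right_bp`) and `start` (initial
#'   homolog per gamete).
#' @export
sim_meiosis <- function(haplotypes, map, n = 1, seed = NULL) {
  assert_that(nrow(haplotypes) == 2L && ncol(haplotypes) == nrow(map),
              "haplotypes must be a 2 x q matrix matching the map")
  trans <- transition_table(map)
  with_seed(seed, {
    o <- sample_origins(n, trans)
    H1 <- matrix(haplotypes[1L, ], n, ncol(haplotypes), byrow = TRUE)
    H2 <- matrix(haplotypes[2L, ], n, ncol(haplotypes), byrow = TRUE)
    g <- alleles_from_origin(o$origin, H1, H2)
    xo <- tibble::tibble(
      gamete = o$gamete, interval = o$interval,
      chr = map$chr[o$interval],
      left_bp = map$bp[o$interval], right_bp = map$bp[o$interval + 1L]
    )
    list(gametes = g, crossovers = dplyr::arrange(xo, .data$gamete,
                                                  .data$interval),
         start = o$start)
  })
}

#' Simulate a paternal half-sib population with known truth
#'
#' Generates `n_families` paternal half-sib families of exactly `n_progeny`
#' progeny each. Sires are the first founders; dams are drawn with replacement
#' from a dam pool (defaulting to `min(n_founders - n_families,
#' ceiling(2 * n_families * n_progeny / 3))` founders, so that dams typically
#' contribute few progeny each). Meioses follow [sim_meiosis()]: Bernoulli
#' crossovers per interval, no interference, no sex difference in rates. All
#' true crossovers and parental haplotypes are recorded for later evaluation.
#'
#' @param n_families Number of half-sib families (sires), `N`.
#' @param n_progeny Progeny per family, `n`.
#' @param map Marker map from [sim_physical_map()].
#' @param n_founders Founder population size (default 1000).
#' @param maf MAF law passed to [sim_founders()].
#' @param n_dams Dam-pool size override.
#' @param founder_haplotypes Optional pre-phased founder haplotype matrix
#'   (`2 * n_founders` rows) for the semi-real design; bypasses
#'   [sim_founders()].
#' @param missing Fraction of genotypes (parents and progeny) masked at
#'   random after simulation.
#' @param seed Optional RNG seed; the full dataset is reproducible from it.
#' @return An object of class `hs_sim`; see Details.
#' @details The returned list carries `genotypes` (individuals x markers,
#'   0/1/2 with `NA` for masked entries), `map`, `pedigree` (id, sire, dam,
#'   sex), `parent_haplotypes` (two rows per parent in pedigree order of
#'   parents), and `truth` with per-gamete crossover intervals and start
#'   origins. When masking is applied, the pre-mask matrix is kept in
#'   `genotypes_true` so that evaluation never reads masked values.
#' @export
sim_half_sib_population <- function(n_families, n_progeny, map,
                                    n_founders = 1000, maf = c(0.05, 0.5),
                                    n_dams = NULL, founder_haplotypes = NULL,
                                    missing = 0, seed = NULL) {
  assert_that(n_families >= 1 && n_progeny >= 1, "need N >= 1 and n >= 1")
  q <- nrow(map)
  with_seed(seed, {
    if (is.null(founder_haplotypes)) {
      fnd <- sim_founders(n_founders, map, maf = maf)
      H <- fnd$haplotypes
      freq <- fnd$freq
    } else {
      H <- founder_haplotypes
      n_founders <- nrow(H) / 2L
      freq <- colMeans(H)
    }
    assert_that(n_founders > n_families,
                "not enough founders for the requested number of sires")
    if (is.null(n_dams))
      n_dams <- min(n_founders - n_families,
                    ceiling(2 * n_families * n_progeny / 3))
    sire_idx <- seq_len(n_families)
    dam_pool <- n_families + seq_len(n_dams)
    trans <- transition_table(map)

    n_tot <- n_families * n_progeny
    dam_of <- sample(dam_pool, n_tot, replace = TRUE)
    sire_of <- rep(sire_idx, each = n_progeny)
    prog_id <- sprintf("P%d_%d", sire_of, rep(seq_len(n_progeny), n_families))
    geno_prog <- matrix(NA_integer_, n_tot, q)
    xo_list <- vector("list", 2L * n_families)
    start_pat <- integer(n_tot); start_mat <- integer(n_tot)
    for (f in seq_len(n_families)) {
      rows <- (f - 1L) * n_progeny + seq_len(n_progeny)
      # paternal gametes
      op <- sample_origins(n_progeny, trans)
      sh <- H[c(2L * f - 1L, 2L * f), , drop = FALSE]
      P1 <- matrix(sh[1L, ], n_progeny, q, byrow = TRUE)
      P2 <- matrix(sh[2L, ], n_progeny, q, byrow = TRUE)
      gp <- alleles_from_origin(op$origin, P1, P2)
      # maternal gametes (each progeny from its own dam)
      om <- sample_origins(n_progeny, trans)
      d <- dam_of[rows]
      M1 <- H[2L * d - 1L, , drop = FALSE]
      M2 <- H[2L * d, , drop = FALSE]
      gm <- alleles_from_origin(om$origin, M1, M2)
      geno_prog[rows, ] <- gp + gm
      start_pat[rows] <- op$start
      start_mat[rows] <- om$start
      xo_list[[2L * f - 1L]] <- tibble::tibble(
        progeny = prog_id[rows][op$gamete],
        parent = sprintf("F%d", f), side = "paternal",
        interval = op$interval)
      xo_list[[2L * f]] <- tibble::tibble(
        progeny = prog_id[rows][om$gamete],
        parent = sprintf("F%d", d[om$gamete]), side = "maternal",
        interval = om$interval)
    }
    dams_used <- sort(unique(dam_of))
    parents <- c(sire_idx, dams_used)
    parent_ids <- sprintf("F%d", parents)
    geno_par <- H[2L * parents - 1L, , drop = FALSE] +
      H[2L * parents, , drop = FALSE]
    genotypes <- rbind(geno_par, geno_prog)
    rownames(genotypes) <- c(parent_ids, prog_id)
    colnames(genotypes) <- map$marker

    crossovers <- dplyr::bind_rows(xo_list)
    crossovers$chr <- map$chr[crossovers$interval]
    crossovers$left_bp <- map$bp[crossovers$interval]
    crossovers$right_bp <- map$bp[crossovers$interval + 1L]

    ped <- tibble::tibble(
      id = c(parent_ids, prog_id),
      sire = c(rep(NA_character_, length(parents)),
               sprintf("F%d", sire_of)),
      dam = c(rep(NA_character_, length(parents)),
              sprintf("F%d", dam_of)),
      sex = c(rep("male", n_families),
              rep("female", length(dams_used)),
              sample(c("male", "female"), n_tot, replace = TRUE))
    )
    hap_rows <- as.vector(rbind(2L * parents - 1L, 2L * parents))
    out <- structure(list(
      genotypes = genotypes,
      genotypes_true = NULL,
      map = map,
      pedigree = ped,
      parents = parent_ids,
      parent_haplotypes = H[hap_rows, , drop = FALSE],
      freq = freq,
      truth = list(crossovers = crossovers,
                   start_origin = tibble::tibble(
                     progeny = prog_id,
                     paternal = start_pat, maternal = start_mat)),
      scenario = list(N = n_families, n = n_progeny, q = q,
                      missing = missing, seed = seed)
    ), class = "hs_sim")
    if (missing > 0) out <- mask_genotypes(out, fraction = missing)
    out
  })
}

#' Mask genotypes at random or in systematic blocks
#'
#' Sets genotype calls (parents and progeny alike) to missing. `fraction`
#' masks entries uniformly at random; `blocks` emulates chip-design
#' missingness: each block row masks a marker range in a random subset of
#' individuals.
#'
#' @param sim An `hs_sim` object.
#' @param fraction Fraction of all genotype entries masked at random.
#' @param blocks Optional data frame with columns `marker_from`, `marker_to`
#'   (column indices) and `sample_fraction`.
#' @param seed Optional RNG seed.
#' @return The `hs_sim` object with `NA`-masked `genotypes`; the original
#'   matrix is preserved in `genotypes_true` (truth is never masked).
#' @export
mask_genotypes <- function(sim, fraction = 0, blocks = NULL, seed = NULL) {
  stopifnot(inherits(sim, "hs_sim"))
  assert_that(fraction >= 0 && fraction <= 1, "fraction must be in [0, 1]")
  if (is.null(sim$genotypes_true)) sim$genotypes_true <- sim$genotypes
  with_seed(seed, {
    G <- sim$genotypes
    if (fraction > 0) {
      hit <- runif(length(G)) < fraction
      G[hit] <- NA_integer_
    }
    if (!is.null(blocks)) {
      for (b in seq_len(nrow(blocks))) {
        rows <- which(runif(nrow(G)) < blocks$sample_fraction[b])
        G[rows, blocks$marker_from[b]:blocks$marker_to[b]] <- NA_integer_
      }
    }
    sim$genotypes <- G
    sim
  })
}

#' @export
print.hs_sim <- function(x, ...) {
  s <- x$scenario
  cat(sprintf(
    "<hs_sim> %d half-sib families x %d progeny, %d markers on %d chromosome(s)\n",
    s$N, s$n, s$q, length(unique(x$map$chr))))
  cat(sprintf("  %d genotyped individuals, %.1f%% missing genotypes\n",
              nrow(x$genotypes), 100 * mean(is.na(x$genotypes))))
  invisible(x)
}

# gametes reconstructed from stored truth; used by tests and evaluation
true_gametes <- function(sim, side = c("paternal", "maternal")) {
  side <- match.arg(side)
  map <- sim$map
  q <- nrow(map)
  ped <- sim$pedigree
  prog <- ped$id[!is.na(ped$sire)]
  n <- length(prog)
  start <- if (side == "paternal") sim$truth$start_origin$paternal else
    sim$truth$start_origin$maternal
  xo <- sim$truth$crossovers
  xo <- xo[xo$side == side, ]
  m <- match(xo$progeny, prog)
  trans <- transition_table(map)
  # rebuild boundary pseudo-switches deterministically is impossible (they
  # were random); instead reconstruct per chromosome: within a chromosome the
  # origin path is start (+ recorded switches). For multi-chromosome truth
  # checks use single-chromosome maps.
  assert_that(length(unique(map$chr)) == 1L,
              "true_gametes supports single-chromosome maps")
  origin <- origin_from_switches(n, q, start, m, xo$interval)
  parent <- if (side == "paternal") ped$sire[!is.na(ped$sire)] else
    ped$dam[!is.na(ped$dam)]
  pidx <- match(parent, sim$parents)
  H1 <- sim$parent_haplotypes[2L * pidx - 1L, , drop = FALSE]
  H2 <- sim$parent_haplotypes[2L * pidx, , drop = FALSE]
  g <- alleles_from_origin(origin, H1, H2)
  rownames(g) <- prog
  list(gametes = g, origin = origin, progeny = prog, parent = parent)
}
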