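#' Phase half-sib parents by sliding-window strand clustering
#'
#' Deterministic multipoint phasing of a common parent from its half-sib
#' progeny. Parent heterozygosity is established from opposing-homozygote
#' progeny (optionally from the parent's own genotype); homozygous progeny
#' reveal the transmitted parental allele, and consecutive heterozygous loci
#' are chained by majority vote over a sliding window of `window`
#' heterozygous loci, yielding two full-length parental haplotypes defined up
#' to a global swap per chromosome. Each progeny receives an origin call
#' wherever its genotype discriminates the two parental strands.
#'
#' @param genotypes Individuals x markers 0/1/2/`NA` matrix.
#' @param pedigree Tibble with `id`, `sire` (progeny rows link to their
#'   shared parent).
#' @param map Marker map (chromosome structure controls chain restarts).
#' @param window Number of heterozygous loci per orientation window
#'   (default 30).
#' @param min_progeny Families with fewer genotyped progeny are skipped
#'   (default 30, the usual half-sib reduction; the transmission HMM caller
#'   lowers this).
#' @param use_parent_genotypes If `TRUE`, the parent's own genotype (where
#'   observed) decides heterozygosity; otherwise only progeny genotypes are
#'   used, as in the purely progeny-driven estimators.
#' @param parent_col Pedigree column naming the shared parent (`"sire"` or
#'   `"dam"`).
#' @return An object of class `hs_phase`: a list of per-family phasings, each
#'   with `parent`, `progeny`, `hap1`, `hap2` (0/1/`NA` allele vectors),
#'   `het` (logical) and `origin` (progeny x markers matrix in 1/2/`NA`).
#' @export
phase_families <- function(genotypes, pedigree, map, window = 30,
                           min_progeny = 30, use_parent_genotypes = FALSE,
                           parent_col = "sire") {
  par_of <- pedigree[[parent_col]]
  prog_all <- pedigree$id[!is.na(par_of)]
  prog_all <- intersect(prog_all, rownames(genotypes))
  par_all <- par_of[match(prog_all, pedigree$id)]
  fams <- split(prog_all, par_all)
  fams <- fams[vapply(fams, length, 1L) >= min_progeny]
  assert_that(length(fams) > 0, "no family meets the progeny threshold")
  out <- lapply(names(fams), function(par) {
    phase_one_family(
      P = genotypes[fams[[par]], , drop = FALSE],
      gs = if (use_parent_genotypes && par %in% rownames(genotypes))
        genotypes[par, ] else NULL,
      map = map, window = window, parent = par, progeny = fams[[par]])
  })
  names(out) <- names(fams)
  structure(list(families = out, map = map, window = window),
            class = "hs_phase")
}

phase_one_family <- function(P, gs, map, window, parent, progeny) {
  q <- ncol(P)
  has0 <- colSums(P == 0L, na.rm = TRUE) > 0
  has2 <- colSums(P == 2L, na.rm = TRUE) > 0
  opp <- has0 & has2
  if (!is.null(gs)) {
    known <- !is.na(gs)
    het <- opp
    het[known] <- gs[known] == 1L
  } else {
    het <- opp
  }
  assert_that(any(het), "no heterozygous locus detected for the parent")
  hetidx <- which(het)
  # transmitted parental allele of homozygous progeny
  A <- P[, hetidx, drop = FALSE] / 2
  A[P[, hetidx, drop = FALSE] == 1L] <- NA
  n_het <- length(hetidx)
  flip <- integer(n_het)
  B <- A
  chr_het <- map$chr[hetidx]
  for (t in seq_len(n_het)) {
    wstart <- t - 1L
    wfirst <- max(1L, t - (window - 1L))
    win <- wfirst:wstart
    if (t == 1L || chr_het[t] != chr_het[t - 1L]) { flip[t] <- 0L; next }
    win <- win[chr_het[win] == chr_het[t]]
    a <- A[, t]
    Bw <- B[, win, drop = FALSE]
    same <- sum(Bw == a, na.rm = TRUE)
    diff <- sum(Bw == (1 - a), na.rm = TRUE)
    flip[t] <- as.integer(diff > same)
    if (flip[t] == 1L) B[, t] <- 1 - a
  }
  hap1 <- rep(NA_integer_, q); hap2 <- hap1
  hap1[hetidx] <- flip
  hap2[hetidx] <- 1L - flip
  hom <- !het
  if (!is.null(gs)) {
    gknown <- hom & !is.na(gs)
    hap1[gknown] <- hap2[gknown] <- as.integer(gs[gknown] / 2)
    rest <- hom & is.na(gs)
  } else rest <- hom
  # homozygous parent allele inferable from progeny extremes
  hap1[rest & has0] <- hap2[rest & has0] <- 0L
  hap1[rest & !has0 & has2] <- hap2[rest & !has0 & has2] <- 1L
  origin <- matrix(NA_integer_, nrow(P), q)
  origin[, hetidx] <- as.integer(B) + 1L
  rownames(origin) <- progeny
  list(parent = parent, progeny = progeny, het = het,
       hap1 = hap1, hap2 = hap2, origin = origin)
}

#' Adjacent-interval recombination rates from deterministic origin calls
#'
#' Pools origin switches over families and progeny: for each progeny, origin
#' calls at consecutive discriminating markers are compared; a switch is
#' allocated evenly over the marker intervals its gap spans. Rates are the
#' pooled switch mass divided by the number of decoded meioses (the family
#' sizes), clamped to `[0, 0.5]`, so the genome-wide map length equals the
#' mean number of detected origin switches per meiosis -- crossovers whose
#' discriminating flanks are lost (chromosome ends, long uninformative gaps)
#' are not re-inflated. Intervals never spanned get rate 0 with a warning.
#'
#' @param phases An `hs_phase` object from [phase_families()].
#' @param map Marker map.
#' @return A tibble with one row per within-chromosome marker interval:
#'   `interval` (index of the left marker), `chr`, `marker_left`,
#'   `marker_right`, `rate`, `n_informative` (meioses whose call gap spans
#'   the interval).
#' @export
deterministic_rates <- function(phases, map) {
  q <- nrow(map)
  num <- numeric(q - 1L); den <- numeric(q - 1L)
  n_meioses <- 0L
  for (fam in phases$families) {
    O <- fam$origin
    n_meioses <- n_meioses + nrow(O)
    for (m in seq_len(nrow(O))) {
      idx <- which(!is.na(O[m, ]))
      if (length(idx) < 2L) next
      i1 <- idx[-length(idx)]; i2 <- idx[-1L]
      ok <- map$chr[i1] == map$chr[i2]
      if (!any(ok)) next
      i1 <- i1[ok]; i2 <- i2[ok]
      sw <- O[m, i1] != O[m, i2]
      lens <- i2 - i1
      js <- sequence(lens, from = i1)
      num[js] <- num[js] + rep(sw / lens, lens)
      den[js] <- den[js] + 1
    }
  }
  finish_rates(num, rep(n_meioses, q - 1L), map, n_informative = den)
}

# shared assembly of the per-interval rate table
finish_rates <- function(num, den, map, n_informative = den) {
  q <- nrow(map)
  within <- which(map$chr[-q] == map$chr[-1L])
  rate <- ifelse(den[within] > 0, num[within] / den[within], NA_real_)
  n_undef <- sum(is.na(rate))
  if (n_undef > 0)
    warning(n_undef, " interval(s) without informative meioses; rate set 0")
  rate[is.na(rate)] <- 0
  rate <- pmin(pmax(rate, 0), 0.5)
  tibble::tibble(
    interval = within,
    chr = map$chr[within],
    marker_left = map$marker[within],
    marker_right = map$marker[within + 1L],
    rate = rate,
    n_informative = n_informative[within]
  )
}
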