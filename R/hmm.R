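# Emission matrices for a set of meioses sharing one phased parent.
# State s = "parental homolog s transmitted". The other parent contributes
# through its genotype where available, else through population allele
# frequencies; missing progeny genotypes emit 1 in both states. Genotypes
# inconsistent with both states (residual conflicts) emit 1 in both states
# and are counted.
family_emissions <- function(P, hap1, hap2, other_geno, freq) {
  n <- nrow(P); q <- ncol(P)
  PB <- matrix(freq, n, q, byrow = TRUE)
  if (!is.null(other_geno)) {
    known <- !is.na(other_geno)
    PB[known] <- other_geno[known] / 2
  }
  emis <- function(hap) {
    D <- sweep(P, 2L, hap, "-")
    E <- matrix(0, n, q)
    E[!is.na(D) & D == 1L] <- PB[!is.na(D) & D == 1L]
    E[!is.na(D) & D == 0L] <- 1 - PB[!is.na(D) & D == 0L]
    E[is.na(D)] <- 1      # missing progeny genotype or unphased parent marker
    E
  }
  E1 <- emis(hap1); E2 <- emis(hap2)
  dead <- E1 == 0 & E2 == 0
  n_conflict <- sum(dead)
  if (n_conflict > 0) { E1[dead] <- 1; E2[dead] <- 1 }
  list(E1 = E1, E2 = E2, n_conflict = n_conflict)
}

# Scaled forward-backward over all meioses at once (rows of E1/E2).
# p: transition (switch) probability per interval. Returns per-marker state-1
# posteriors, per-interval expected switch counts summed over meioses,
# per-meiosis per-interval switch posteriors optionally, and log-likelihood.
forward_backward <- function(E1, E2, p, keep_xi_matrix = FALSE) {
  M <- nrow(E1); q <- ncol(E1)
  A1 <- matrix(0, M, q); A2 <- A1
  Cs <- matrix(0, M, q)
  a1 <- 0.5 * E1[, 1L]; a2 <- 0.5 * E2[, 1L]
  s <- a1 + a2
  A1[, 1L] <- a1 / s; A2[, 1L] <- a2 / s; Cs[, 1L] <- s
  for (i in 2L:q) {
    pj <- p[i - 1L]
    a1 <- ((1 - pj) * A1[, i - 1L] + pj * A2[, i - 1L]) * E1[, i]
    a2 <- ((1 - pj) * A2[, i - 1L] + pj * A1[, i - 1L]) * E2[, i]
    s <- a1 + a2
    A1[, i] <- a1 / s; A2[, i] <- a2 / s; Cs[, i] <- s
  }
  G1 <- matrix(0, M, q)
  xi_sum <- numeric(q - 1L)
  XI <- if (keep_xi_matrix) matrix(0, M, q - 1L) else NULL
  b1 <- rep(1, M); b2 <- rep(1, M)
  G1[, q] <- A1[, q]
  for (i in (q - 1L):1L) {
    pj <- p[i]
    e1 <- E1[, i + 1L] * b1; e2 <- E2[, i + 1L] * b2
    xi <- (A1[, i] * pj * e2 + A2[, i] * pj * e1) / Cs[, i + 1L]
    xi_sum[i] <- sum(xi)
    if (keep_xi_matrix) XI[, i] <- xi
    nb1 <- ((1 - pj) * e1 + pj * e2) / Cs[, i + 1L]
    nb2 <- ((1 - pj) * e2 + pj * e1) / Cs[, i + 1L]
    b1 <- nb1; b2 <- nb2
    G1[, i] <- A1[, i] * b1
  }
  list(gamma1 = G1, xi_sum = xi_sum, xi = XI,
       loglik = sum(log(Cs)))
}

#' Posterior transmission probabilities for one meiosis
#'
#' Forward-backward posteriors of the 2-state transmission chain for a single
#' progeny: which parental homolog was transmitted at each marker. Exposed
#' mainly for inspection and exact small-scale validation; the estimation
#' pipeline runs the same recursion over all meioses jointly.
#'
#' @param progeny_genotype Length-q 0/1/2/`NA` vector.
#' @param hap1,hap2 Phased parental haplotype allele vectors (0/1/`NA`).
#' @param rates Per-interval transition probabilities (length q-1).
#' @param other_genotype Optional other-parent genotype vector.
#' @param freq Population allele-1 frequencies (used where the other parent
#'   is not genotyped).
#' @return A list with `posterior` (q x 2 matrix), `path` (posterior-decoded
#'   states, ties inheriting the previous state) and `loglik`.
#' @export
hmm_posterior <- function(progeny_genotype, hap1, hap2, rates,
                          other_genotype = NULL, freq = rep(0.5,
                            length(progeny_genotype))) {
  P <- matrix(progeny_genotype, 1L)
  em <- family_emissions(P, hap1, hap2,
                         if (is.null(other_genotype)) NULL else
                           matrix(other_genotype, 1L), freq)
  fb <- forward_backward(em$E1, em$E2, rates)
  g1 <- drop(fb$gamma1)
  path <- decode_states(matrix(g1, 1L))[1L, ]
  list(posterior = cbind(state1 = g1, state2 = 1 - g1),
       path = path, loglik = fb$loglik)
}

# posterior decoding with leftward tie inheritance
decode_states <- function(G1) {
  S <- matrix(1L, nrow(G1), ncol(G1))
  S[G1 < 0.5] <- 2L
  ties <- G1 == 0.5
  if (any(ties)) {
    for (i in seq_len(ncol(G1))) {
      t <- ties[, i]
      if (!any(t)) next
      S[t, i] <- if (i == 1L) 1L else S[t, i - 1L]
    }
  }
  S
}

# assemble meioses for one sex: stack family emissions into big matrices
stack_meioses <- function(genotypes, pedigree, phases, freq, map,
                          parent_col = "sire", other_col = "dam") {
  E1l <- list(); E2l <- list(); meta <- list(); conflicts <- 0L
  for (fam in phases$families) {
    prog <- intersect(fam$progeny, rownames(genotypes))
    if (!length(prog)) next
    P <- genotypes[prog, , drop = FALSE]
    ped <- pedigree[match(prog, pedigree$id), ]
    other <- ped[[other_col]]
    OG <- matrix(NA_integer_, length(prog), ncol(genotypes))
    has <- !is.na(other) & other %in% rownames(genotypes)
    if (any(has)) OG[has, ] <- genotypes[other[has], , drop = FALSE]
    em <- family_emissions(P, fam$hap1, fam$hap2, OG, freq)
    E1l[[fam$parent]] <- em$E1
    E2l[[fam$parent]] <- em$E2
    conflicts <- conflicts + em$n_conflict
    meta[[fam$parent]] <- tibble::tibble(progeny = prog, parent = fam$parent)
  }
  list(E1 = do.call(rbind, E1l), E2 = do.call(rbind, E2l),
       meta = dplyr::bind_rows(meta), n_conflict = conflicts)
}

#' EM estimation of per-interval recombination rates from transmission HMMs
#'
#' Iterates forward-backward decoding and rate re-estimation: the new rate of
#' interval j is the posterior-expected switch count in j divided by the
#' number of decoded meioses, clamped to `[1e-6, 0.5]`, until the largest
#' rate change is below `tol` or `max_iter` is reached. Chromosome-boundary
#' transitions are fixed at 0.5 (independent assortment) and never estimated.
#'
#' @param stack Output of the internal meiosis stacker (emission matrices).
#' @param map Marker map.
#' @param init Initial within-chromosome rate.
#' @param tol Convergence tolerance on the maximum absolute rate change.
#' @param max_iter Iteration cap.
#' @return A list with `p` (full transition vector), `fb` (final
#'   forward-backward pass), `iterations` and `converged`.
#' @keywords internal
hmm_em <- function(stack, map, init = 1e-3, tol = 1e-4, max_iter = 20) {
  q <- nrow(map)
  boundary <- map$chr[-q] != map$chr[-1L]
  p <- ifelse(boundary, 0.5, init)
  M <- nrow(stack$E1)
  converged <- FALSE
  it <- 0L
  fb <- NULL
  repeat {
    it <- it + 1L
    fb <- forward_backward(stack$E1, stack$E2, p)
    p_new <- fb$xi_sum / M
    p_new <- pmin(pmax(p_new, 1e-6), 0.5)
    p_new[boundary] <- 0.5
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  list(p = p, fb = fb, iterations = it, converged = converged,
       boundary = boundary)
}

# Decode all meioses: crossover records with informative flanks, per-meiosis
# crossover counts, chromosome start states, and the per-marker confidence
# score (posterior-weighted agreement with the locally smoothed path over a
# window of 5 informative markers).
decode_all <- function(stack, em, map, mcs_window = 5L) {
  E1 <- stack$E1; E2 <- stack$E2
  G1 <- em$fb$gamma1
  M <- nrow(G1); q <- ncol(G1)
  S <- decode_states(G1)
  I <- E1 != E2
  W <- pmax(G1, 1 - G1)
  # running last/next informative marker index per meiosis
  L <- matrix(0L, M, q)
  L[, 1L] <- ifelse(I[, 1L], 1L, 0L)
  for (i in 2L:q) L[, i] <- ifelse(I[, i], i, L[, i - 1L])
  R <- matrix(q + 1L, M, q)
  R[, q] <- ifelse(I[, q], q, q + 1L)
  for (i in (q - 1L):1L) R[, i] <- ifelse(I[, i], i, R[, i + 1L])
  sw <- S[, -1L, drop = FALSE] != S[, -q, drop = FALSE]
  if (any(em$boundary)) sw[, em$boundary] <- FALSE
  hit <- which(sw, arr.ind = TRUE)
  lf <- L[cbind(hit[, 1L], hit[, 2L])]
  rf <- R[cbind(hit[, 1L], hit[, 2L] + 1L)]
  ok <- lf >= 1L & rf <= q & map$chr[pmax(lf, 1L)] == map$chr[pmin(rf, q)]
  xo <- tibble::tibble(
    progeny = stack$meta$progeny[hit[ok, 1L]],
    parent = stack$meta$parent[hit[ok, 1L]],
    meiosis = hit[ok, 1L],
    chr = map$chr[lf[ok]],
    left_marker = map$marker[lf[ok]],
    right_marker = map$marker[rf[ok]],
    left_bp = map$bp[lf[ok]],
    right_bp = map$bp[rf[ok]]
  )
  xo$midpoint_bp <- (xo$left_bp + xo$right_bp) %/% 2L
  xo <- dplyr::arrange(xo, .data$meiosis, .data$left_bp)
  n_xo <- tabulate(hit[ok, 1L], nbins = M)
  # confidence score: a call disagrees with the locally smoothed path when
  # it sits in an isolated run of informative calls flanked on both sides by
  # the other state within the smoothing window (an implied immediate double
  # crossover); runs touching a chromosome end are consistent (a genuine
  # terminal crossover looks like this).
  num <- numeric(q); den <- numeric(q)
  max_blip <- max(1L, mcs_window %/% 4L)
  for (m in seq_len(M)) {
    idx_all <- which(I[m, ])
    if (length(idx_all) < 2L) next
    for (idx in split(idx_all, map$chr[idx_all])) {
      if (length(idx) < 2L) {
        num[idx] <- num[idx] + W[m, idx]
        den[idx] <- den[idx] + W[m, idx]
        next
      }
      s <- S[m, idx]
      r <- rle(s)
      nr <- length(r$lengths)
      blip_run <- r$lengths <= max_blip &
        seq_len(nr) > 1L & seq_len(nr) < nr
      agree <- 1 - rep(as.numeric(blip_run), r$lengths)
      w <- W[m, idx]
      num[idx] <- num[idx] + w * agree
      den[idx] <- den[idx] + w
    }
  }
  mcs <- ifelse(den > 0, num / den, NA_real_)
  chr_first <- match(unique(map$chr), map$chr)
  start_states <- tibble::tibble(
    progeny = rep(stack$meta$progeny, length(chr_first)),
    parent = rep(stack$meta$parent, length(chr_first)),
    chr = rep(map$chr[chr_first], each = M),
    state = as.vector(S[, chr_first])
  )
  list(crossovers = xo, n_crossovers = n_xo, mcs = mcs,
       start_states = start_states)
}

#' Per-marker map confidence score
#'
#' Posterior-weighted fraction of meioses whose decoded origin at a marker
#' agrees with the locally smoothed transmission path (majority over a window
#' of 5 informative markers). 1 when all calls are locally consistent;
#' markers never informative get `NA` (treated as failing by the two-run
#' filter).
#'
#' @param fit An `hs_mapfit` from [estimate_map()] with `method = "hmm"`.
#' @return A tibble with `marker`, `chr`, `bp`, `mcs`.
#' @export
marker_confidence <- function(fit) {
  stopifnot(inherits(fit, "hs_mapfit"))
  assert_that(!is.null(fit$mcs), "confidence scores only exist for HMM fits")
  tibble::tibble(marker = fit$map_used$marker, chr = fit$map_used$chr,
                 bp = fit$map_used$bp, mcs = fit$mcs)
}
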