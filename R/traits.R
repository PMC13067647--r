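#' Transmitted-proportion of each chromosome per meiosis
#'
#' For every decoded meiosis and chromosome, the fraction `p` of the
#' chromosome's physical span (first to last marker bp) inherited from the
#' parent's first homolog. Segment breakpoints sit at crossover midpoints;
#' the origin at the chromosome start is the decoded state at the first
#' marker.
#'
#' @param fit An `hs_mapfit` with `method = "hmm"`.
#' @return Tibble `progeny`, `parent`, `chr`, `p`.
#' @export
transmitted_proportions <- function(fit) {
  stopifnot(inherits(fit, "hs_mapfit"))
  assert_that(!is.null(fit$start_states),
              "transmission paths only exist for HMM fits")
  map <- fit$map_used
  span <- dplyr::summarise(dplyr::group_by(map, .data$chr),
                           bp_lo = min(.data$bp), bp_hi = max(.data$bp),
                           .groups = "drop")
  xo <- fit$crossovers
  st <- dplyr::left_join(fit$start_states, span, by = "chr")
  key <- paste(xo$progeny, xo$parent, xo$chr, sep = "\r")
  mids <- split(xo$midpoint_bp, key)
  skey <- paste(st$progeny, st$parent, st$chr, sep = "\r")
  p <- purrr::pmap_dbl(
    list(skey, st$state, st$bp_lo, st$bp_hi),
    function(k, s0, lo, hi) {
      m <- mids[[k]]
      if (is.null(m)) return(as.numeric(s0 == 1L))
      cuts <- c(lo, sort(m), hi)
      seg <- diff(cuts)
      orig <- rep_len(c(s0, 3L - s0), length(seg))
      sum(seg[orig == 1L]) / (hi - lo)
    })
  tibble::tibble(progeny = st$progeny, parent = st$parent, chr = st$chr,
                 p = p)
}

#' Relative chromosome lengths
#'
#' `L_k` = the chromosome's physical marker span divided by the total span
#' over all chromosomes, so that `sum(L_k) = 1`.
#'
#' @param map Marker map.
#' @return Tibble `chr`, `L`.
#' @export
relative_chr_lengths <- function(map) {
  sp <- dplyr::summarise(dplyr::group_by(map, .data$chr),
                         span = max(.data$bp) - min(.data$bp),
                         .groups = "drop")
  sp$L <- sp$span / sum(sp$span)
  dplyr::select(sp, "chr", "L")
}

#' Mean autosomal crossover count per parent
#'
#' The average number of genome-wide crossovers among a parent's decoded
#' meioses.
#'
#' @param fit An `hs_mapfit` with `method = "hmm"`.
#' @return Tibble `parent`, `n_progeny`, `nco`.
#' @export
crossover_counts <- function(fit) {
  stopifnot(inherits(fit, "hs_mapfit"))
  assert_that(!is.null(fit$n_crossovers),
              "crossover counts only exist for HMM fits")
  dplyr::summarise(dplyr::group_by(fit$n_crossovers, .data$parent),
                   n_progeny = dplyr::n(), nco = mean(.data$n),
                   .groups = "drop")
}

#' Intra-chromosomal allelic shuffling per parent
#'
#' The probability-like measure that a random same-chromosome locus pair
#' recombined in transmission, averaged over a parent's progeny:
#' `r_bar_i = (1/n_i) * sum_j sum_k 2 p_kj (1 - p_kj) L_k^2` with
#' transmitted proportions `p` and relative chromosome lengths `L_k`. The
#' statistic is invariant to homolog labelling since `2p(1-p)` is symmetric.
#'
#' @param proportions Tibble from [transmitted_proportions()].
#' @param map Marker map supplying `L_k`.
#' @return Tibble `parent`, `n_progeny`, `shuffling`.
#' @export
shuffling_index <- function(proportions, map) {
  L <- relative_chr_lengths(map)
  n_chr <- nrow(L)
  pr <- dplyr::left_join(proportions, L, by = "chr")
  per_prog <- dplyr::summarise(
    dplyr::group_by(pr, .data$parent, .data$progeny),
    contrib = sum(2 * .data$p * (1 - .data$p) * .data$L^2),
    n_chr_seen = dplyr::n(), .groups = "drop")
  incomplete <- per_prog$n_chr_seen < n_chr
  if (any(incomplete)) {
    warning(sum(incomplete),
            " progeny lack a decoded chromosome and were skipped")
    per_prog <- per_prog[!incomplete, ]
  }
  dplyr::summarise(dplyr::group_by(per_prog, .data$parent),
                   n_progeny = dplyr::n(),
                   shuffling = mean(.data$contrib), .groups = "drop")
}

#' Parental recombination-trait table
#'
#' Combines mean autosomal crossover count and intra-chromosomal allelic
#' shuffling per parent, with the progeny count used as GBLUP/GWAS weight
#' and a z-scored shuffling column (the scale on which shuffling is
#' analysed).
#'
#' @param fit An `hs_mapfit` with `method = "hmm"`.
#' @param pedigree Optional pedigree to attach parent sex.
#' @return Tibble `parent`, `sex`, `n_progeny`, `nco`, `shuffling`,
#'   `shuffling_z`.
#' @export
parent_traits <- function(fit, pedigree = NULL) {
  nco <- crossover_counts(fit)
  shf <- shuffling_index(transmitted_proportions(fit), fit$map_used)
  out <- dplyr::inner_join(nco, dplyr::select(shf, "parent", "shuffling"),
                           by = "parent")
  out$shuffling_z <- if (nrow(out) > 1L && stats::sd(out$shuffling) > 0)
    as.numeric(scale(out$shuffling)) else 0
  out$sex <- fit$sex
  if (!is.null(pedigree)) {
    m <- match(out$parent, pedigree$id)
    out$sex <- ifelse(is.na(m), out$sex, pedigree$sex[m])
  }
  dplyr::select(out, "parent", "sex", "n_progeny", "nco", "shuffling",
                "shuffling_z")
}
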