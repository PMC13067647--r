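#' Accumulate interval rates into genetic-map coordinates
#'
#' Map coordinates in Morgan are the accumulation of recombination rate
#' between adjacent markers: the first marker of each chromosome sits at 0
#' and each following marker adds the preceding interval's rate.
#'
#' @param rates Interval rate tibble (`interval`, `rate`) as produced by the
#'   estimators.
#' @param map Marker map the intervals refer to.
#' @return A tibble `marker`, `chr`, `bp`, `pos_morgan`.
#' @export
accumulate_map <- function(rates, map) {
  q <- nrow(map)
  assert_that(all(rates$rate >= 0), "negative recombination rate")
  r_full <- rep(0, max(q - 1L, 1L))
  r_full[rates$interval] <- rates$rate
  pos <- numeric(q)
  for (k in unique(map$chr)) {
    idx <- which(map$chr == k)
    if (length(idx) > 1L)
      pos[idx] <- c(0, cumsum(r_full[idx[-length(idx)]]))
  }
  tibble::tibble(marker = map$marker, chr = map$chr, bp = map$bp,
                 pos_morgan = pos)
}

map_total_length <- function(genmap) {
  sum(tapply(genmap$pos_morgan, genmap$chr, max))
}

#' Accuracy of estimated map length
#'
#' The ratio of estimated to true total map length, `acc = d_hat_q / d_q`,
#' summed over chromosomes.
#'
#' @param est,truth Genetic maps (`marker`, `chr`, `pos_morgan`); `truth`
#'   typically comes from [sim_physical_map()].
#' @return A single number; 1 means perfect length recovery.
#' @export
map_accuracy <- function(est, truth) {
  d_true <- map_total_length(truth)
  assert_that(d_true > 0, "true map has zero length")
  map_total_length(est) / d_true
}

#' Mean squared error of estimated map positions
#'
#' `mse = (1/q) * sum_i (d_hat_i - d_i)^2` over the markers shared between
#' the estimated and the true map (in Morgan squared).
#'
#' @inheritParams map_accuracy
#' @return A single non-negative number.
#' @export
map_mse <- function(est, truth) {
  m <- dplyr::inner_join(
    dplyr::select(est, "marker", est_pos = "pos_morgan"),
    dplyr::select(truth, "marker", true_pos = "pos_morgan"),
    by = "marker")
  assert_that(nrow(m) > 0, "maps share no markers")
  mean((m$est_pos - m$true_pos)^2)
}

#' Chromosome-level cM:Mbp ratio
#'
#' @param genmap Genetic map tibble (`chr`, `bp`, `pos_morgan`).
#' @return A tibble `chr`, `length_cm`, `length_mbp`, `cm_per_mbp`.
#' @export
cm_per_mbp <- function(genmap) {
  dplyr::summarise(dplyr::group_by(genmap, .data$chr),
                   length_cm = 100 * max(.data$pos_morgan),
                   length_mbp = (max(.data$bp) - min(.data$bp)) / 1e6,
                   .groups = "drop") |>
    dplyr::mutate(cm_per_mbp = ifelse(.data$length_mbp > 0,
                                      .data$length_cm / .data$length_mbp, 0))
}

#' Principal components of a recombination-rate matrix
#'
#' One row per population (sex x breed), one column per shared marker
#' interval. Rows are centred; no scaling (all entries share Morgan units).
#'
#' @param rate_matrix Numeric matrix, populations x intervals, with row
#'   names.
#' @return A list with `scores` (tibble of PCs per population) and
#'   `var_explained`.
#' @export
map_pca <- function(rate_matrix) {
  assert_that(nrow(rate_matrix) >= 2, "need at least two populations")
  pc <- prcomp(rate_matrix, center = TRUE, scale. = FALSE)
  list(scores = tibble::as_tibble(pc$x, rownames = "population"),
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Hierarchical clustering of genetic maps
#'
#' Average-linkage agglomerative clustering on the Euclidean (L2) distance
#' between genetic-map coordinate vectors, restricted to markers shared by
#' all maps.
#'
#' @param maps Named list of genetic maps (`marker`, `pos_morgan`).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return An `hclust` object (deterministic leaf order).
#' @export
map_hclust <- function(maps, linkage = "average") {
  assert_that(length(maps) >= 2, "need at least two maps")
  shared <- Reduce(intersect, lapply(maps, function(m) m$marker))
  assert_that(length(shared) > 0, "maps share no markers")
  X <- vapply(maps, function(m) m$pos_morgan[match(shared, m$marker)],
              numeric(length(shared)))
  hclust(dist(t(X)), method = linkage)
}

# rebuild an hs_phase object from known parental haplotypes (semi-real mode
# or truth-based decoding of e.g. maternal meioses)
phase_from_truth <- function(sim, parent_col = "sire", min_progeny = 1) {
  ped <- sim$pedigree
  par_of <- ped[[parent_col]]
  prog <- ped$id[!is.na(par_of)]
  fams <- split(prog, par_of[match(prog, ped$id)])
  fams <- fams[vapply(fams, length, 1L) >= min_progeny]
  q <- nrow(sim$map)
  families <- lapply(names(fams), function(par) {
    i <- match(par, sim$parents)
    h1 <- sim$parent_haplotypes[2L * i - 1L, ]
    h2 <- sim$parent_haplotypes[2L * i, ]
    list(parent = par, progeny = fams[[par]],
         het = h1 != h2, hap1 = h1, hap2 = h2,
         origin = NULL)
  })
  names(families) <- names(fams)
  structure(list(families = families, map = sim$map, window = NA),
            class = "hs_phase")
}

#' Estimate a sex-specific genetic map from half-sib genotypes
#'
#' Runs one of the three estimator families on a genotyped half-sib dataset:
#'
#' * `"hmm"` — phase each parent by sliding-window strand clustering (using
#'   the parent's own genotype where observed), decode every meiosis with a
#'   2-state transmission HMM, re-estimate interval rates by EM, and (by
#'   default) apply the two-run confidence filter: markers below the
#'   confidence-score threshold and individuals with more than
#'   `max_crossovers` detected crossovers are dropped and the decoding/EM
#'   pass repeated once.
#' * `"deterministic"` — sliding-window multipoint phasing from progeny
#'   genotypes only, origin-switch counting over discriminating markers.
#' * `"likelihood"` — pairwise two-locus maximum likelihood on adjacent
#'   marker pairs, pooled over families.
#'
#' The deterministic and likelihood estimators use only families with at
#' least `min_progeny` (default 30) genotyped progeny.
#'
#' @param data An `hs_sim` object or any list with `genotypes`, `pedigree`,
#'   `map`.
#' @param method One of `"hmm"`, `"deterministic"`, `"likelihood"`.
#' @param sex Which parental meioses to analyse (`"male"` = sires).
#' @param two_run Apply the confidence-filter second run (HMM only).
#' @param mcs_threshold Marker confidence-score threshold (default 0.986).
#' @param max_crossovers Individual crossover cap between runs (default 58).
#' @param window Phasing window in heterozygous loci.
#' @param min_progeny Family-size threshold (default 30 for the
#'   deterministic/likelihood estimators, 10 for the HMM).
#' @param phase_source `"estimate"` (default) phases parents from the data;
#'   `"truth"` uses the simulated parental haplotypes (semi-real mode, needed
#'   e.g. for maternal maps when dams have 1-2 progeny).
#' @param em_init,em_tol,em_max_iter EM controls for the HMM.
#' @return An `hs_mapfit` object: interval `rates`, the accumulated genetic
#'   `map_est`, the marker set used, removal counts, and (for the HMM)
#'   crossover records, confidence scores and start states.
#' @export
estimate_map <- function(data, method = c("hmm", "deterministic",
                                          "likelihood"),
                         sex = c("male", "female"), two_run = NULL,
                         mcs_threshold = 0.986, max_crossovers = 58,
                         window = 30, min_progeny = NULL,
                         phase_source = c("estimate", "truth"),
                         em_init = 1e-3, em_tol = 1e-4, em_max_iter = 20) {
  method <- match.arg(method)
  sex <- match.arg(sex)
  phase_source <- match.arg(phase_source)
  G <- data$genotypes; ped <- data$pedigree; map <- data$map
  parent_col <- if (sex == "male") "sire" else "dam"
  other_col <- if (sex == "male") "dam" else "sire"
  if (is.null(min_progeny))
    min_progeny <- if (method == "hmm") 10 else 30
  if (is.null(two_run)) two_run <- method == "hmm"
  freq <- colMeans(G, na.rm = TRUE) / 2

  get_phases <- function(G, map) {
    if (phase_source == "truth") {
      dat <- data; dat$map <- map
      ph <- phase_from_truth(dat, parent_col, min_progeny)
      keep <- match(map$marker, data$map$marker)
      ph$families <- lapply(ph$families, function(f) {
        f$het <- f$het[keep]; f$hap1 <- f$hap1[keep]; f$hap2 <- f$hap2[keep]
        f
      })
      ph
    } else {
      phase_families(G, ped, map, window = window,
                     min_progeny = min_progeny,
                     use_parent_genotypes = method == "hmm",
                     parent_col = parent_col)
    }
  }

  if (method == "deterministic") {
    phases <- get_phases(G, map)
    rates <- deterministic_rates(phases, map)
    fit <- new_mapfit(method, sex, rates, map,
                      removed = tibble::tibble(q_ex = 0L, n_ex = 0L))
    return(fit)
  }
  if (method == "likelihood") {
    phases <- get_phases(G, map)
    rates <- pairwise_adjacent_rates(G, phases, freq, map)
    fit <- new_mapfit(method, sex, rates, map,
                      removed = tibble::tibble(q_ex = 0L, n_ex = 0L))
    return(fit)
  }

  run_hmm <- function(G, map) {
    phases <- get_phases(G, map)
    stack <- stack_meioses(G, ped, phases, colMeans(G, na.rm = TRUE) / 2,
                           map, parent_col, other_col)
    em <- hmm_em(stack, map, init = em_init, tol = em_tol,
                 max_iter = em_max_iter)
    dec <- decode_all(stack, em, map)
    list(stack = stack, em = em, dec = dec, map = map, G = G)
  }
  r1 <- run_hmm(G, map)
  q_ex <- 0L; n_ex <- 0L
  if (two_run) {
    keep_marker <- !is.na(r1$dec$mcs) & r1$dec$mcs >= mcs_threshold
    xo_by_prog <- tapply(r1$dec$n_crossovers, r1$stack$meta$progeny, sum)
    bad_prog <- names(xo_by_prog)[xo_by_prog > max_crossovers]
    q_ex <- sum(!keep_marker); n_ex <- length(bad_prog)
    if (q_ex > 0 || n_ex > 0) {
      G2 <- G[setdiff(rownames(G), bad_prog), keep_marker, drop = FALSE]
      map2 <- map[keep_marker, ]
      r1 <- run_hmm(G2, map2)
    }
  }
  map_used <- r1$map
  q2 <- nrow(map_used)
  within <- which(map_used$chr[-q2] == map_used$chr[-1L])
  rates <- tibble::tibble(
    interval = within,
    chr = map_used$chr[within],
    marker_left = map_used$marker[within],
    marker_right = map_used$marker[within + 1L],
    rate = r1$em$p[within],
    n_informative = nrow(r1$stack$E1)
  )
  fit <- new_mapfit("hmm", sex, rates, map_used,
                    removed = tibble::tibble(q_ex = q_ex, n_ex = n_ex))
  fit$mcs <- r1$dec$mcs
  fit$crossovers <- r1$dec$crossovers
  fit$start_states <- r1$dec$start_states
  fit$n_crossovers <- tibble::tibble(progeny = r1$stack$meta$progeny,
                                     parent = r1$stack$meta$parent,
                                     n = r1$dec$n_crossovers)
  fit$em <- list(iterations = r1$em$iterations,
                 converged = r1$em$converged,
                 loglik = r1$em$fb$loglik)
  fit$n_conflict <- r1$stack$n_conflict
  fit
}

new_mapfit <- function(method, sex, rates, map_used, removed) {
  structure(list(method = method, sex = sex, rates = rates,
                 map_used = map_used,
                 map_est = accumulate_map(rates, map_used),
                 removed = removed),
            class = "hs_mapfit")
}

#' @export
print.hs_mapfit <- function(x, ...) {
  cat(sprintf("<hs_mapfit> %s estimator, %s meioses\n", x$method, x$sex))
  cat(sprintf("  %d markers, total map length %.4f M\n",
              nrow(x$map_est), map_total_length(x$map_est)))
  if (any(x$removed > 0))
    cat(sprintf("  two-run filter removed %d marker(s), %d individual(s)\n",
                x$removed$q_ex, x$removed$n_ex))
  invisible(x)
}

#' Crossover records of a fitted transmission HMM
#'
#' One record per decoded origin switch, flanked by the nearest informative
#' markers; the event position is the interval midpoint in bp.
#'
#' @param fit An `hs_mapfit` with `method = "hmm"`.
#' @return Tibble `progeny`, `parent`, `chr`, `left_bp`, `right_bp`,
#'   `midpoint_bp` (plus flanking marker ids).
#' @export
locate_crossovers <- function(fit) {
  stopifnot(inherits(fit, "hs_mapfit"))
  assert_that(!is.null(fit$crossovers),
              "crossover records only exist for HMM fits")
  fit$crossovers
}

#' Near-double-crossover proportion per chromosome
#'
#' The proportion of crossovers that belong to a same-meiosis pair whose
#' midpoints lie closer than `threshold_bp` (default 2 Mbp), a diagnostic
#' for phasing artefacts.
#'
#' @param crossovers Crossover tibble from [locate_crossovers()].
#' @param threshold_bp Distance threshold in bp.
#' @return Tibble `chr`, `n_crossovers`, `n_near_double`, `proportion`.
#' @export
near_double_crossover_stats <- function(crossovers, threshold_bp = 2e6) {
  xo <- dplyr::arrange(crossovers, .data$progeny, .data$parent, .data$chr,
                       .data$midpoint_bp)
  grp <- paste(xo$progeny, xo$parent, xo$chr)
  near <- logical(nrow(xo))
  if (nrow(xo) > 1L) {
    same <- grp[-1L] == grp[-length(grp)]
    close <- diff(xo$midpoint_bp) < threshold_bp
    idx <- which(same & close)
    near[idx] <- TRUE
    near[idx + 1L] <- TRUE
  }
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(chr = xo$chr, near = near), .data$chr),
    n_crossovers = dplyr::n(),
    n_near_double = sum(.data$near),
    proportion = mean(.data$near), .groups = "drop")
}
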