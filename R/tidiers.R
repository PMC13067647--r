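#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a genetic-map fit
#'
#' One row per marker interval with the estimated recombination rate.
#'
#' @param x An `hs_mapfit`.
#' @param ... Unused.
#' @return The interval-rate tibble.
#' @export
tidy.hs_mapfit <- function(x, ...) x$rates

#' One-row summary of a genetic-map fit
#'
#' @param x An `hs_mapfit`.
#' @param ... Unused.
#' @return Tibble with method, sex, marker count, total map length and
#'   removal counts.
#' @export
glance.hs_mapfit <- function(x, ...) {
  tibble::tibble(method = x$method, sex = x$sex,
                 n_markers = nrow(x$map_est),
                 map_length_morgan = map_total_length(x$map_est),
                 q_removed = x$removed$q_ex, n_removed = x$removed$n_ex)
}

#' Tidy a weighted GBLUP fit
#'
#' @param x An `hs_gblup`.
#' @param ... Unused.
#' @return Tibble of variance components and heritability.
#' @export
tidy.hs_gblup <- function(x, ...) {
  tibble::tibble(term = c("sigma_g2", "sigma_e2", "h2", "mu"),
                 estimate = c(x$sigma_g2, x$sigma_e2, x$h2, x$mu))
}

#' One-row summary of a weighted GBLUP fit
#'
#' @param x An `hs_gblup`.
#' @param ... Unused.
#' @return Tibble with h2, components, restricted log-likelihoods and the
#'   genomic-variance RLRT P value.
#' @export
glance.hs_gblup <- function(x, ...) {
  rl <- rlrt_genomic_variance(x)
  tibble::tibble(n = x$n, h2 = x$h2, sigma_g2 = x$sigma_g2,
                 sigma_e2 = x$sigma_e2, loglik = x$loglik,
                 rlrt = rl$lrt, p_genomic = rl$p_value,
                 converged = x$converged)
}

#' Tidy a bivariate cross-sex fit
#'
#' @param x An `hs_bigblup`.
#' @param ... Unused.
#' @return Tibble of covariance components and the cross-sex correlation.
#' @export
tidy.hs_bigblup <- function(x, ...) {
  tibble::tibble(
    term = c("sigma_s2", "sigma_d2", "sigma_sd", "correlation",
             "sigma_e2"),
    estimate = c(x$Sigma[1L, 1L], x$Sigma[2L, 2L], x$Sigma[1L, 2L],
                 x$correlation, x$sigma_e2))
}

#' Plot a genetic map against physical positions
#'
#' Genetic-map coordinate (cM) versus physical position (Mbp), one panel per
#' chromosome.
#'
#' @param object An `hs_mapfit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hs_mapfit <- function(object, ...) {
  d <- object$map_est
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bp / 1e6,
                                  y = 100 * .data$pos_morgan)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~chr, scales = "free") +
    ggplot2::labs(x = "physical position (Mbp)",
                  y = "genetic position (cM)",
                  title = sprintf("%s-based %s genetic map", object$method,
                                  object$sex))
}

#' Manhattan plot of a GWAS scan
#'
#' @param object An `hs_gwas` result with map coordinates.
#' @param ... Unused.
#' @return A ggplot object with the strong/suggestive thresholds drawn.
#' @export
autoplot.hs_gwas <- function(object, ...) {
  thr <- attr(object, "thresholds")
  d <- object[!is.na(object$p), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bp / 1e6,
                                  y = -log10(.data$p))) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_grid(~chr, scales = "free_x", space = "free_x") +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = c(1, 2)) +
    ggplot2::labs(x = "position (Mbp)", y = expression(-log[10](P)))
}
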