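#' Filter individuals and markers on missingness
#'
#' Removes individuals with more than `indiv_max` missing genotypes first,
#' then markers with more than `marker_max` missing calls among the
#' remaining individuals (fixed order, as reported).
#'
#' @param genotypes Individuals x markers matrix.
#' @param indiv_max,marker_max Maximum tolerated missing fractions
#'   (default 20% each).
#' @return List with filtered `genotypes` and a one-row `report`
#'   (`individuals_removed`, `markers_removed`).
#' @export
filter_missingness <- function(genotypes, indiv_max = 0.20,
                               marker_max = 0.20) {
  ind_miss <- rowMeans(is.na(genotypes))
  keep_i <- ind_miss <= indiv_max
  G <- genotypes[keep_i, , drop = FALSE]
  mar_miss <- colMeans(is.na(G))
  keep_m <- mar_miss <= marker_max
  list(genotypes = G[, keep_m, drop = FALSE],
       report = tibble::tibble(individuals_removed = sum(!keep_i),
                               markers_removed = sum(!keep_m)))
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' Standardised genotype cross-products with observed allele frequencies:
#' `K = Z Z' / (2 * sum f (1 - f))` with `Z = M - 2f`. Missing calls are
#' mean-imputed per marker for the relationship matrix only; monomorphic
#' markers are excluded.
#'
#' @param genotypes Individuals x markers 0/1/2/`NA` matrix.
#' @return List with `K` (symmetric relationship matrix), `freq` and
#'   `n_markers`.
#' @export
build_grm <- function(genotypes) {
  f <- colMeans(genotypes, na.rm = TRUE) / 2
  poly <- !is.na(f) & f > 0 & f < 1
  assert_that(any(poly), "no polymorphic marker for the GRM")
  M <- genotypes[, poly, drop = FALSE]
  f <- f[poly]
  Z <- sweep(M, 2L, 2 * f)
  Z[is.na(Z)] <- 0   # mean imputation after centring
  K <- tcrossprod(Z) / (2 * sum(f * (1 - f)))
  K <- (K + t(K)) / 2
  list(K = K, freq = f, n_markers = sum(poly))
}

# eigen-based REML for y = X b + u + e, u ~ N(0, K sg2), e ~ N(0, D se2),
# D = diag(1/w). Profiled over lambda = sg2/se2 on a log grid + optimize.
reml_eigen <- function(y, K, X, w) {
  n <- length(y)
  sw <- sqrt(w)
  yt <- sw * y
  Xt <- sw * X
  Kt <- sw * t(sw * K)       # diag(sw) K diag(sw), keeping symmetry
  ee <- eigen((Kt + t(Kt)) / 2, symmetric = TRUE)
  ev <- ee$values
  ridge_used <- FALSE
  if (min(ev) < -1e-8 * max(abs(ev))) {
    ev <- ev + 1e-8 * max(abs(ev)) + abs(min(ev))
    ridge_used <- TRUE
  }
  ev <- pmax(ev, 0)
  U <- ee$vectors
  z <- drop(crossprod(U, yt))
  W <- crossprod(U, Xt)
  p <- ncol(X)
  reml_ll <- function(log_lambda) {
    lambda <- exp(log_lambda)
    v <- lambda * ev + 1
    WtV <- crossprod(W, W / v)
    WtVz <- crossprod(W, z / v)
    beta <- solve(WtV, WtVz)
    r <- z - W %*% beta
    rss <- sum(r^2 / v)
    se2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * se2) + sum(log(v)) +
                    determinant(WtV, logarithm = TRUE)$modulus + (n - p))
    attr(ll, "beta") <- beta; attr(ll, "se2") <- se2
    as.numeric(ll)
  }
  grid <- seq(-12, 8, length.out = 25)
  ll_grid <- vapply(grid, reml_ll, 1)
  i <- which.max(ll_grid)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- optimize(reml_ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  # boundary (no genomic variance)
  ll0 <- reml_ll(-30)
  if (ll0 >= opt$objective) {
    lambda <- 0; ll <- ll0
  } else {
    lambda <- exp(opt$maximum); ll <- opt$objective
  }
  v <- lambda * ev + 1
  WtV <- crossprod(W, W / v)
  beta <- drop(solve(WtV, crossprod(W, z / v)))
  r <- z - W %*% beta
  se2 <- sum(r^2 / v) / (n - p)
  sg2 <- lambda * se2
  # BLUP on the original scale: u_hat = sg2 K T' Vinv (y_t - X_t beta)
  u <- lambda * drop(K %*% (sw * (U %*% (r / v))))
  list(lambda = lambda, sigma_g2 = sg2, sigma_e2 = se2,
       beta = beta, blup = u, loglik = ll, loglik0 = reml_ll(-30),
       ridge_used = ridge_used, n = n)
}

#' Weighted genomic BLUP with REML variance components
#'
#' Fits `y = 1 mu + u + e` with `u ~ N(0, K sigma_g^2)` and
#' `e ~ N(0, D sigma_e^2)`, `D = diag(1/w)` (reciprocal weights, e.g.
#' progeny counts). Variance components by restricted maximum likelihood on
#' the eigendecomposition of the weight-transformed relationship matrix;
#' genomic heritability `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`.
#'
#' @param y Trait vector aligned with the rows of `K`.
#' @param K Genomic relationship matrix (from [build_grm()]).
#' @param weights Per-record weights `w` (default 1); residual variance of
#'   record i is `sigma_e^2 / w_i`.
#' @return An object of class `hs_gblup` with variance components, `h2`,
#'   `mu`, BLUPs, restricted log-likelihoods of the full and no-genomic-
#'   variance fits, and a ridge flag.
#' @export
fit_weighted_gblup <- function(y, K, weights = 1) {
  if (is.list(K)) K <- K$K
  n <- length(y)
  assert_that(nrow(K) == n, "y and K dimensions differ")
  w <- rep_len(weights, n)
  assert_that(all(w > 0), "weights must be positive")
  fit <- reml_eigen(y, K, matrix(1, n, 1L), w)
  structure(list(
    sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
    h2 = fit$sigma_g2 / (fit$sigma_g2 + fit$sigma_e2),
    mu = fit$beta[1L], blup = fit$blup,
    loglik = fit$loglik, loglik0 = fit$loglik0,
    ridge_used = fit$ridge_used, converged = TRUE,
    n = n, weights = w, K = K, y = y
  ), class = "hs_gblup")
}

#' @export
print.hs_gblup <- function(x, ...) {
  cat(sprintf(
    "<hs_gblup> n = %d  sigma_g2 = %.4g  sigma_e2 = %.4g  h2 = %.3f\n",
    x$n, x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

#' Restricted likelihood-ratio test for the genomic variance
#'
#' Tests `sigma_g^2 = 0` against `> 0` with the boundary-corrected null
#' distribution: a 50:50 mixture of a point mass at zero and chi-square with
#' 1 df, so `P = 0.5 * Pr(chi2_1 > LRT)` for positive LRT and `P = 0.5` at
#' `LRT = 0`.
#'
#' @param fit_full An `hs_gblup` fit (carries the boundary log-likelihood),
#'   or the restricted log-likelihood of the full model.
#' @param fit_null Optional: the no-genomic-variance fit or its restricted
#'   log-likelihood; defaults to the boundary likelihood stored in
#'   `fit_full`.
#' @return A list with `lrt` and `p_value`.
#' @export
rlrt_genomic_variance <- function(fit_full, fit_null = NULL) {
  ll1 <- if (inherits(fit_full, "hs_gblup")) fit_full$loglik else fit_full
  ll0 <- if (is.null(fit_null)) {
    assert_that(inherits(fit_full, "hs_gblup"),
                "fit_null needed when fit_full is a bare log-likelihood")
    fit_full$loglik0
  } else if (inherits(fit_null, "hs_gblup")) fit_null$loglik else fit_null
  lrt <- 2 * (ll1 - ll0)
  if (lrt < 0) {
    if (lrt < -1e-6) warning("negative restricted LRT set to 0")
    lrt <- 0
  }
  p <- if (lrt > 0) 0.5 * pchisq(lrt, df = 1L, lower.tail = FALSE) else 0.5
  list(lrt = lrt, p_value = p)
}

#' Bivariate cross-sex genomic model
#'
#' Fits `y = W b + u + e` jointly over sires and dams with sex as fixed
#' effect, `u ~ N(0, Sigma (x) G)` restricted to the observed parents
#' (`Sigma` the 2x2 sire/dam genetic covariance matrix) and
#' `e ~ N(0, D sigma_e^2)`. The restricted likelihood is maximised directly
#' over (`sigma_s^2`, `sigma_d^2`, cross-sex covariance, `sigma_e^2`) with
#' an iteration cap of 100; non-convergence is reported, not hidden.
#'
#' @param y Trait vector over all parents (both sexes).
#' @param sex Character/factor vector, `"male"`/`"female"`, aligned with
#'   `y`.
#' @param K Genomic relationship matrix over the same parents.
#' @param weights Per-record weights (progeny counts).
#' @param max_iter Optimiser iteration cap (default 100).
#' @return An object of class `hs_bigblup` with `Sigma`, the cross-sex
#'   genetic `correlation`, `sigma_e2`, fixed effects `b`, restricted
#'   log-likelihood and `converged`.
#' @export
fit_bivariate_gblup <- function(y, sex, K, weights = 1, max_iter = 100) {
  if (is.list(K)) K <- K$K
  n <- length(y)
  assert_that(nrow(K) == n, "y and K dimensions differ")
  is_m <- sex %in% c("male", "M", "1")
  assert_that(any(is_m) && any(!is_m), "both sexes must be present")
  w <- rep_len(weights, n)
  D <- diag(1 / w, n)
  X <- cbind(1, as.numeric(is_m))
  p <- ncol(X)
  # class pattern: entry (i,j) multiplies sigma_s2, sigma_d2 or sigma_sd
  MM <- outer(is_m, is_m); FF <- outer(!is_m, !is_m)
  nll <- function(par) {
    ss <- exp(par[1L]); sd2 <- exp(par[2L]); rho <- tanh(par[3L])
    se2 <- exp(par[4L])
    ssd <- rho * sqrt(ss * sd2)
    C <- ssd + (ss - ssd) * MM + (sd2 - ssd) * FF
    V <- C * K + se2 * D
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ldV <- 2 * sum(log(diag(ch)))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(X, Vi_y))
    r <- y - X %*% beta
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    0.5 * (ldV + determinant(XtViX, logarithm = TRUE)$modulus +
             sum(r * Vi_r))
  }
  v0 <- stats::var(y)
  par0 <- c(log(v0 / 4), log(v0 / 4), atanh(0.2), log(v0 / 2))
  opt <- optim(par0, nll, method = "L-BFGS-B",
               lower = c(log(v0 * 1e-8), log(v0 * 1e-8), -5,
                         log(v0 * 1e-8)),
               upper = c(log(v0 * 1e3), log(v0 * 1e3), 5, log(v0 * 1e3)),
               control = list(maxit = max_iter))
  ss <- exp(opt$par[1L]); sd2 <- exp(opt$par[2L]); rho <- tanh(opt$par[3L])
  se2 <- exp(opt$par[4L])
  ssd <- rho * sqrt(ss * sd2)
  C <- ssd + (ss - ssd) * MM + (sd2 - ssd) * FF
  V <- C * K + se2 * D
  Vi_X <- solve(V, X)
  beta <- drop(solve(crossprod(X, Vi_X), crossprod(Vi_X, y)))
  if (opt$convergence != 0)
    warning("bivariate REML did not converge within ", max_iter,
            " iterations")
  structure(list(
    Sigma = matrix(c(ss, ssd, ssd, sd2), 2L,
                   dimnames = list(c("sire", "dam"), c("sire", "dam"))),
    correlation = rho, sigma_e2 = se2, b = beta,
    loglik = -opt$value, converged = opt$convergence == 0,
    iterations = opt$counts[["function"]], n = n
  ), class = "hs_bigblup")
}

#' @export
print.hs_bigblup <- function(x, ...) {
  cat(sprintf(
    "<hs_bigblup> n = %d  cross-sex genetic correlation = %.3f%s\n",
    x$n, x$correlation,
    if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}
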