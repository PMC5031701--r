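#' Constrained three-component Gaussian mixture for donor-signal fractions
#'
#' At recipient-homozygous loci of an (unrelated) two-contributor mixture
#' with donor fraction x, the per-locus minor-allele fraction falls into
#' three classes: donor shares both alleles (signal = sequencing error
#' rate), donor shares one allele (signal about x/2), donor shares neither
#' (signal about x). Because the panel loci are independent and evenly
#' biallelic, these classes occur in 1:2:1 proportion, so the mixture is
#' fit with fixed weights (0.25, 0.5, 0.25) and with the no-shared-allele
#' component's mean and SD tied to exactly twice the one-shared-allele
#' values. EM re-estimates (mu_err, mu_osa, sigma_err, sigma_osa); the
#' tied component never has free parameters.
#'
#' The donor estimate from one fit is the no-shared-allele mean minus the
#' fitted error mean: `mu_nsa - mu_err`.
#'
#' @name admixture_model
NULL

.WEIGHTS <- c(0.25, 0.50, 0.25)

# Batch EM over R independent restarts on the same data. Parameters are
# length-R vectors; each column of the internal matrices is one restart.
# M-step for the tied pair (mu_osa, mu_nsa = 2*mu_osa) is the
# responsibility-weighted least-squares solution of y_i ~ c_i * mu_osa
# with c = 1 (OSA) and 2 (NSA) and per-class variances (sigma_osa^2,
# 4*sigma_osa^2), which gives closed forms:
#   mu_osa  = (S2y + S3y/2) / (S2 + S3)
#   s_osa^2 = (S2d2 + S3d3/4) / (S2 + S3)
# where Sk* are responsibility-weighted sums for components 2 and 3.
.em_batch <- function(y, mu_err, mu_osa, sigma_err, sigma_osa,
                      tol = 1e-8, max_iter = 500, variance_floor = 1e-5,
                      trace = FALSE) {
  n <- length(y)
  R <- length(mu_err)
  stopifnot(length(mu_osa) == R, length(sigma_err) == R,
            length(sigma_osa) == R)
  sigma_err <- pmax(sigma_err, variance_floor)
  sigma_osa <- pmax(sigma_osa, variance_floor)
  Y <- matrix(y, nrow = n, ncol = R)
  ll <- rep(-Inf, R)
  n_iter <- rep(0L, R)
  converged <- rep(FALSE, R)
  ll_trace <- if (trace) matrix(NA_real_, nrow = max_iter, ncol = R) else NULL
  expand <- function(v) matrix(v, nrow = n, ncol = R, byrow = TRUE)

  for (it in seq_len(max_iter)) {
    # E-step in log space (values can sit many sigmas from a component)
    A1 <- log(.WEIGHTS[1]) + dnorm(Y, expand(mu_err), expand(sigma_err),
                                   log = TRUE)
    A2 <- log(.WEIGHTS[2]) + dnorm(Y, expand(mu_osa), expand(sigma_osa),
                                   log = TRUE)
    A3 <- log(.WEIGHTS[3]) + dnorm(Y, expand(2 * mu_osa),
                                   expand(2 * sigma_osa), log = TRUE)
    M <- pmax(A1, A2, A3)
    E1 <- exp(A1 - M); E2 <- exp(A2 - M); E3 <- exp(A3 - M)
    S <- E1 + E2 + E3
    ll_new <- colSums(M + log(S))
    R1 <- E1 / S; R2 <- E2 / S; R3 <- E3 / S

    newly <- !converged & (ll_new - ll < tol) & it > 1L
    n_iter[!converged] <- it
    converged <- converged | newly
    ll <- ll_new
    if (trace) ll_trace[it, ] <- ll_new
    if (all(converged)) break

    # M-step
    s1 <- colSums(R1)
    s23 <- colSums(R2) + colSums(R3)
    mu_err_new <- colSums(R1 * Y) / s1
    mu_osa_new <- (colSums(R2 * Y) + 0.5 * colSums(R3 * Y)) / s23
    ok1 <- is.finite(mu_err_new) & s1 > 1e-12
    ok23 <- is.finite(mu_osa_new) & s23 > 1e-12
    mu_err <- ifelse(ok1, mu_err_new, mu_err)
    mu_osa <- ifelse(ok23, mu_osa_new, mu_osa)
    D1 <- Y - expand(mu_err)
    D2 <- Y - expand(mu_osa)
    D3 <- Y - expand(2 * mu_osa)
    v_err <- colSums(R1 * D1^2) / s1
    v_osa <- (colSums(R2 * D2^2) + 0.25 * colSums(R3 * D3^2)) / s23
    sigma_err <- pmax(ifelse(ok1 & is.finite(v_err), sqrt(v_err), sigma_err),
                      variance_floor)
    sigma_osa <- pmax(ifelse(ok23 & is.finite(v_osa), sqrt(v_osa), sigma_osa),
                      variance_floor)
  }
  if (trace) ll_trace <- ll_trace[seq_len(max(n_iter)), , drop = FALSE]
  list(mu_err = mu_err, mu_osa = mu_osa,
       sigma_err = sigma_err, sigma_osa = sigma_osa,
       loglik = ll, n_iter = n_iter, converged = converged,
       loglik_trace = ll_trace)
}

.check_fractions <- function(fractions) {
  if (!is.numeric(fractions) || any(!is.finite(fractions)))
    stop("fractions must be finite numbers in [0, 1]", call. = FALSE)
  if (any(fractions < 0) || any(fractions > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (length(fractions) < 6L)
    stop("insufficient data: need at least 6 donor-signal fractions, got ",
         length(fractions), call. = FALSE)
  as.numeric(fractions)
}

#' Fit the constrained three-component mixture by EM
#'
#' Runs EM with mixing weights fixed at (0.25, 0.5, 0.25) and the
#' equality constraints `mu_nsa = 2 * mu_osa`, `sigma_nsa = 2 * sigma_osa`
#' imposed exactly in every M-step. Component SDs are floored at
#' `variance_floor` to prevent degenerate spikes on near-constant data.
#' The log-likelihood is non-decreasing across iterations; convergence is
#' declared when its improvement falls below `tol`.
#'
#' @param fractions numeric vector of donor-signal fractions in \[0, 1\];
#'   at least 6 are required.
#' @param init optional named list with `mu_err`, `mu_osa`, `sigma_err`,
#'   `sigma_osa` starting values. Defaults: `mu_err = 0.001` (the Q30
#'   theoretical error rate), `mu_osa = median(fractions) / 2` (bounded
#'   below by the floor), sigmas at half the corresponding means.
#' @param tol convergence tolerance on the log-likelihood change
#'   (default 1e-8).
#' @param max_iter maximum EM iterations (default 500).
#' @param variance_floor minimum component SD in fraction units
#'   (default 1e-5).
#' @return An object of class `mixture_fit`: a list with `mu_err`,
#'   `mu_osa`, `mu_nsa`, `sigma_err`, `sigma_osa`, `sigma_nsa`, `weights`,
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `estimate`
#'   (`max(0, mu_nsa - mu_err)`).
#' @export
fit_constrained_mixture <- function(fractions, init = NULL, tol = 1e-8,
                                    max_iter = 500, variance_floor = 1e-5) {
  y <- .check_fractions(fractions)
  stopifnot(tol > 0, max_iter >= 1)
  if (is.null(init)) {
    m <- max(median(y) / 2, variance_floor)
    init <- list(mu_err = 0.001, mu_osa = m,
                 sigma_err = 0.0005, sigma_osa = m / 2)
  }
  fit <- .em_batch(y, init$mu_err, init$mu_osa, init$sigma_err,
                   init$sigma_osa, tol = tol, max_iter = max_iter,
                   variance_floor = variance_floor, trace = TRUE)
  out <- list(
    mu_err = fit$mu_err[1], mu_osa = fit$mu_osa[1],
    mu_nsa = 2 * fit$mu_osa[1],
    sigma_err = fit$sigma_err[1], sigma_osa = fit$sigma_osa[1],
    sigma_nsa = 2 * fit$sigma_osa[1],
    weights = .WEIGHTS,
    loglik = fit$loglik[1],
    loglik_trace = as.numeric(fit$loglik_trace[, 1]),
    n_iter = fit$n_iter[1],
    converged = fit$converged[1],
    estimate = max(0, 2 * fit$mu_osa[1] - fit$mu_err[1]),
    variance_floor = variance_floor
  )
  class(out) <- "mixture_fit"
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Constrained 3-component Gaussian mixture fit\n")
  cat(sprintf("  mu_err  = %.6f  sigma_err = %.6f\n", x$mu_err, x$sigma_err))
  cat(sprintf("  mu_osa  = %.6f  sigma_osa = %.6f\n", x$mu_osa, x$sigma_osa))
  cat(sprintf("  mu_nsa  = %.6f  sigma_nsa = %.6f  (tied at 2x OSA)\n",
              x$mu_nsa, x$sigma_nsa))
  cat(sprintf("  weights fixed at %s\n", paste(x$weights, collapse = ":")))
  cat(sprintf("  loglik = %.4f after %d iteration(s); converged: %s\n",
              x$loglik, x$n_iter, x$converged))
  cat(sprintf("  donor estimate (mu_nsa - mu_err, clamped) = %.6f\n",
              x$estimate))
  invisible(x)
}

#' Log-likelihood of fractions under a mixture fit
#'
#' Deterministic evaluation of
#' `sum_i log sum_k w_k Normal(y_i; mu_k, sigma_k)` for the three
#' components of a `mixture_fit`.
#'
#' @param fractions numeric vector of values in \[0, 1\].
#' @param params a `mixture_fit` object (or list with the same fields).
#' @return The total log-likelihood (a single number).
#' @export
mixture_loglikelihood <- function(fractions, params) {
  if (any(!is.finite(fractions)))
    stop("fractions must be finite", call. = FALSE)
  floor_ <- if (!is.null(params$variance_floor)) params$variance_floor else 1e-5
  sig <- c(params$sigma_err, params$sigma_osa, params$sigma_nsa)
  if (any(sig < floor_ - 1e-15))
    stop("component SD below variance floor", call. = FALSE)
  mu <- c(params$mu_err, params$mu_osa, params$mu_nsa)
  w <- params$weights
  ll <- vapply(fractions, function(yi) {
    a <- log(w) + dnorm(yi, mu, sig, log = TRUE)
    m <- max(a)
    m + log(sum(exp(a - m)))
  }, numeric(1))
  sum(ll)
}

#' Pool fitted error rates across co-sequenced samples
#'
#' Samples run on the same sequencing chip share a platform noise level;
#' the pooled rate is the locus-count-weighted mean of each sample's
#' fitted error-component mean.
#'
#' @param fits list of `mixture_fit` objects (or anything with `$mu_err`),
#'   one per sample.
#' @param locus_counts integer vector of selected-locus counts, one per
#'   sample; all positive.
#' @return The pooled error rate (fraction units).
#' @export
pool_error_rate <- function(fits, locus_counts) {
  if (length(fits) == 0L)
    stop("pool_error_rate: no fits supplied", call. = FALSE)
  if (length(fits) != length(locus_counts))
    stop("pool_error_rate: one locus count per fit required", call. = FALSE)
  if (any(locus_counts <= 0))
    stop("pool_error_rate: locus counts must be positive", call. = FALSE)
  mu <- vapply(fits, function(f) f$mu_err, numeric(1))
  weighted.mean(mu, locus_counts)
}
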