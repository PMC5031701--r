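#' Donor-fraction estimation by replicated randomized EM
#'
#' A single constrained-mixture fit depends on its starting point, so the
#' estimator aggregates many fits: each replicate starts the EM from a
#' randomized initialization (or, in bootstrap mode, additionally
#' resamples the loci with replacement), and the reported donor
#' percentage is the mean of the per-replicate clamped estimates, with
#' its SD as the reproducibility measure.
#'
#' @name estimate
NULL

#' Model and aggregation settings for the estimator
#'
#' @param tol EM convergence tolerance on the log-likelihood change
#'   (default 1e-8).
#' @param max_iter maximum EM iterations per replicate (default 500).
#' @param variance_floor minimum component SD, fraction units
#'   (default 1e-5).
#' @param bootstrap if `TRUE`, each replicate resamples the loci with
#'   replacement in addition to randomizing the EM start (default
#'   `FALSE`: randomized restarts on the full locus set).
#' @param error_floor the platform noise floor in fraction units used for
#'   the detectability call; defaults to 0.001, the theoretical error
#'   rate at the Q30 base-quality cutoff.
#' @param pooled_error optional pooled across-sample error rate (from
#'   [pool_error_rate()]); when supplied it participates in the noise
#'   floor, and with `subtract_pooled = TRUE` it replaces the per-replicate
#'   fitted error in the subtraction step.
#' @param subtract_pooled see `pooled_error` (default `FALSE`: each
#'   replicate subtracts its own fitted error mean).
#' @return A named list of settings.
#' @export
estimate_config <- function(tol = 1e-8, max_iter = 500,
                            variance_floor = 1e-5, bootstrap = FALSE,
                            error_floor = 0.001, pooled_error = NULL,
                            subtract_pooled = FALSE) {
  stopifnot(tol > 0, max_iter >= 1, variance_floor > 0,
            is.logical(bootstrap), error_floor >= 0)
  if (subtract_pooled && is.null(pooled_error))
    stop("subtract_pooled requires pooled_error", call. = FALSE)
  list(tol = tol, max_iter = max_iter, variance_floor = variance_floor,
       bootstrap = bootstrap, error_floor = error_floor,
       pooled_error = pooled_error, subtract_pooled = subtract_pooled)
}

#' Estimate the donor cfDNA percentage from selected loci
#'
#' Runs [fit_constrained_mixture()] `n_replicates` times from randomized
#' initializations: the error-mean start is drawn log-uniformly in
#' \[0.0005, 0.002\] around the Q30 theoretical rate, the one-shared-allele
#' mean start log-uniformly within a factor \[0.25, 4\] of half the median
#' fraction, and starting SDs are half the corresponding means. A single
#' master seed drives all draws, so identical inputs and seed reproduce
#' the estimate exactly. Per replicate the donor estimate is
#' `max(0, mu_nsa - mu_err)`; non-converged replicates are excluded and
#' counted.
#'
#' The estimate is `detectable` when the mean percentage exceeds the
#' noise floor: the largest of the mean fitted error rate, the pooled
#' error rate (if supplied) and `config$error_floor`, on the percent
#' scale.
#'
#' @param loci a `selected_loci` data frame from [select_loci()], or a
#'   numeric vector of donor-signal fractions.
#' @param n_replicates number of randomized EM replicates (default
#'   10000; a few hundred give stable means in practice).
#' @param seed integer master seed.
#' @param config an [estimate_config()] list.
#' @return An object of class `donor_estimate`: `percent_mean`,
#'   `percent_sd` (both on the 0-100 scale), `n_replicates` (converged
#'   replicates used), `n_nonconverged`, `n_loci_used`, `detectable`,
#'   `error_rate_fitted` (mean fitted `mu_err`), `noise_floor_percent`,
#'   `pooled_error_rate` (if supplied), `seed`.
#' @export
estimate_donor_fraction <- function(loci, n_replicates = 10000, seed = 1,
                                    config = estimate_config()) {
  y <- if (inherits(loci, "selected_loci")) loci$donor_signal_fraction
       else as.numeric(loci)
  y <- .check_fractions(y)
  stopifnot(n_replicates >= 1)
  if (n_replicates == 1L)
    warning("single replicate: percent_sd is 0 by convention", call. = FALSE)
  n <- length(y)
  R <- as.integer(n_replicates)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  lu <- function(R, lo, hi) exp(runif(R, log(lo), log(hi)))
  med_half <- max(median(y) / 2, config$variance_floor)
  mu_err0 <- 0.001 * lu(R, 0.5, 2)
  mu_osa0 <- med_half * lu(R, 0.25, 4)
  boot_idx <- if (config$bootstrap)
    matrix(sample.int(n, n * R, replace = TRUE), nrow = n) else NULL

  if (config$bootstrap) {
    # resampled data differ per replicate; fit column-by-column
    res <- lapply(seq_len(R), function(r) {
      .em_batch(y[boot_idx[, r]], mu_err0[r], mu_osa0[r],
                mu_err0[r] / 2, mu_osa0[r] / 2,
                tol = config$tol, max_iter = config$max_iter,
                variance_floor = config$variance_floor)
    })
    fit <- list(
      mu_err = vapply(res, function(f) f$mu_err, numeric(1)),
      mu_osa = vapply(res, function(f) f$mu_osa, numeric(1)),
      converged = vapply(res, function(f) f$converged, logical(1))
    )
  } else {
    fit <- .em_batch(y, mu_err0, mu_osa0, mu_err0 / 2, mu_osa0 / 2,
                     tol = config$tol, max_iter = config$max_iter,
                     variance_floor = config$variance_floor)
  }

  use <- fit$converged
  if (!any(use))
    stop("estimation failure: no EM replicate converged in ",
         config$max_iter, " iterations (n_loci = ", n, ", tol = ",
         config$tol, ")", call. = FALSE)
  err_used <- if (config$subtract_pooled) config$pooled_error
              else fit$mu_err[use]
  est <- pmax(0, 2 * fit$mu_osa[use] - err_used)
  err_fit <- mean(fit$mu_err[use])
  noise_floor <- max(err_fit, config$error_floor,
                     if (is.null(config$pooled_error)) 0 else config$pooled_error)
  pm <- mean(est) * 100
  ps <- if (length(est) > 1L) sd(est) * 100 else 0

  out <- list(
    percent_mean = pm, percent_sd = ps,
    n_replicates = sum(use), n_nonconverged = sum(!use),
    n_loci_used = n,
    detectable = pm > noise_floor * 100,
    error_rate_fitted = err_fit,
    noise_floor_percent = noise_floor * 100,
    pooled_error_rate = config$pooled_error,
    seed = as.integer(seed)
  )
  class(out) <- "donor_estimate"
  out
}

#' @export
print.donor_estimate <- function(x, ...) {
  cat("Donor cfDNA estimate\n")
  cat(sprintf("  %.3f%% (SD %.3f%%) from %d loci, %d EM replicate(s)\n",
              x$percent_mean, x$percent_sd, x$n_loci_used, x$n_replicates))
  if (x$n_nonconverged > 0)
    cat(sprintf("  %d non-converged replicate(s) excluded\n",
                x$n_nonconverged))
  cat(sprintf("  fitted error rate %.5f; noise floor %.3f%%; detectable: %s\n",
              x$error_rate_fitted, x$noise_floor_percent,
              ifelse(x$detectable, "yes", "no")))
  invisible(x)
}

#' Write a donor estimate as JSON and TSV
#'
#' Deterministic field order; numbers written at full precision. The
#' optional `drop_counts` (from the selection stage) are included so a
#' run's locus accounting travels with its estimate.
#'
#' @param estimate a `donor_estimate` object.
#' @param path_json,path_tsv output paths (either may be `NULL` to skip).
#' @param drop_counts optional named vector from
#'   `attr(selected, "drop_counts")`.
#' @return Invisibly, the list that was serialized.
#' @export
write_estimate <- function(estimate, path_json = NULL, path_tsv = NULL,
                           drop_counts = NULL) {
  stopifnot(inherits(estimate, "donor_estimate"))
  x <- list(
    percent_mean = estimate$percent_mean,
    percent_sd = estimate$percent_sd,
    n_replicates = estimate$n_replicates,
    n_nonconverged = estimate$n_nonconverged,
    n_loci_used = estimate$n_loci_used,
    detectable = estimate$detectable,
    error_rate_fitted = estimate$error_rate_fitted,
    noise_floor_percent = estimate$noise_floor_percent,
    pooled_error_rate = estimate$pooled_error_rate,
    seed = estimate$seed
  )
  if (!is.null(drop_counts)) x$locus_drop_counts <- as.list(drop_counts)
  if (!is.null(path_json))
    jsonlite::write_json(x, path_json, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (!is.null(path_tsv)) {
    flat <- x
    flat$locus_drop_counts <- NULL
    flat$pooled_error_rate <- if (is.null(x$pooled_error_rate)) NA
                              else x$pooled_error_rate
    write.table(as.data.frame(flat), path_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(x)
}
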