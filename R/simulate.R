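#' Two-contributor panel sequencing simulator
#'
#' Generates recipient/donor genotypes under Hardy-Weinberg equilibrium
#' at a common allele frequency, then draws reads per locus from the
#' admixed template pool: each read comes from the donor with probability
#' `donor_fraction`, carries a uniformly chosen allele of its
#' contributor's genotype, and is miscalled to a uniformly random other
#' base with probability `error_rate` (so an expected `e/3` of errors
#' lands on the other panel allele and `2e/3` is ambiguous). Depth is
#' negative-binomial, reflecting the overdispersion of amplicon panels
#' relative to Poisson.
#'
#' Contributors are unrelated (independent genotypes); relatedness is
#' deliberately not modelled, matching the method's unrelated-pair
#' assumption.
#'
#' @name simulate
NULL

#' Simulation settings
#'
#' Defaults emulate the validation conditions of a deep amplicon run on
#' a forensic identity SNP panel: about 90 autosomal biallelic loci with
#' evenly common alleles (frequency 0.5, so about half the loci are
#' recipient-homozygous and usable), mean depth 1500, base error 0.001
#' (the Q30 rate).
#'
#' @param n_loci number of autosomal panel loci (default 90).
#' @param allele_freq panel allele frequency, in (0, 1) exclusive
#'   (default 0.5).
#' @param donor_fraction true donor fraction, in \[0, 0.14): beyond 14%
#'   the recipient-homozygosity call itself starts to fail at
#'   no-shared-allele loci, which is the method's validity bound.
#' @param depth_mean mean per-locus read depth (default 1500).
#' @param depth_dispersion negative-binomial size parameter (default 5;
#'   larger is closer to Poisson).
#' @param error_rate per-base miscall probability, in \[0, 0.25)
#'   (default 0.001).
#' @param seed integer seed.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_loci = 90, allele_freq = 0.5,
                              donor_fraction = 0, depth_mean = 1500,
                              depth_dispersion = 5, error_rate = 0.001,
                              seed = 1) {
  if (!(n_loci >= 1)) stop("n_loci must be >= 1", call. = FALSE)
  if (!(allele_freq > 0 && allele_freq < 1))
    stop("allele_freq must lie strictly inside (0, 1)", call. = FALSE)
  if (!(donor_fraction >= 0 && donor_fraction < 0.14))
    stop("donor_fraction must lie in [0, 0.14): above 14% the ",
         "homozygosity call fails at no-shared-allele loci", call. = FALSE)
  if (!(error_rate >= 0 && error_rate < 0.25))
    stop("error_rate must lie in [0, 0.25)", call. = FALSE)
  if (!(depth_mean >= 1)) stop("depth_mean must be >= 1", call. = FALSE)
  if (!(depth_dispersion > 0))
    stop("depth_dispersion must be positive", call. = FALSE)
  out <- list(n_loci = as.integer(n_loci), allele_freq = allele_freq,
              donor_fraction = donor_fraction,
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              error_rate = error_rate, seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

.genotype_string <- function(a1, a2) paste(pmin(a1, a2), pmax(a1, a2), sep = "")

.shared_class <- function(r1, r2, d1, d2) {
  # multiset intersection size between recipient and donor genotypes
  shared <- mapply(function(ra, rb, da, db) {
    rec <- c(ra, rb)
    n <- 0L
    for (x in c(da, db)) {
      hit <- match(x, rec)
      if (!is.na(hit)) { rec <- rec[-hit]; n <- n + 1L }
    }
    n
  }, r1, r2, d1, d2)
  c("none-shared", "one-shared", "both-shared")[shared + 1L]
}

#' Simulate recipient and donor genotypes at panel loci
#'
#' Draws both contributors' genotypes independently per locus under
#' Hardy-Weinberg at `allele_freq`, and also returns the matching
#' [panel_loci] definition (autosomal loci on chromosomes 1-22, alleles
#' alternating over A/G, C/T, A/C, G/T pairs).
#'
#' At allele frequency 0.5, among recipient-homozygous loci the donor
#' shares both alleles 25% of the time, one allele 50% and neither 25% —
#' the 1:2:1 class structure the mixture model encodes.
#'
#' @param config a [simulation_config()] list.
#' @return A list with `panel` (a [panel_loci] data frame) and `truth`
#'   (data frame: `locus_id`, `recipient_genotype`, `donor_genotype`,
#'   `shared_class`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_loci
  pairs <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  pick <- pairs[((seq_len(n) - 1L) %% length(pairs)) + 1L]
  allele_a <- vapply(pick, `[`, character(1), 1)
  allele_b <- vapply(pick, `[`, character(1), 2)
  panel <- panel_loci(
    locus_id = sprintf("sim%03d", seq_len(n)),
    chrom = as.character(((seq_len(n) - 1L) %% 22L) + 1L),
    pos = 1000L + 10L * seq_len(n),
    allele_a = allele_a, allele_b = allele_b
  )
  draw <- function() ifelse(runif(n) < config$allele_freq, allele_a, allele_b)
  r1 <- draw(); r2 <- draw(); d1 <- draw(); d2 <- draw()
  truth <- data.frame(
    locus_id = panel$locus_id,
    recipient_genotype = .genotype_string(r1, r2),
    donor_genotype = .genotype_string(d1, d2),
    shared_class = .shared_class(r1, r2, d1, d2),
    stringsAsFactors = FALSE
  )
  list(panel = panel, truth = truth)
}

#' Simulate per-locus base counts from genotypes
#'
#' Per locus: depth ~ NegBin(mean `depth_mean`, size `depth_dispersion`,
#' floored at 1); reads split binomially between donor
#' (`donor_fraction`) and recipient; within a contributor each read
#' carries either genotype allele with equal probability; each read is
#' miscalled to one of the three other bases with probability
#' `error_rate`. Calls of a panel allele are tallied in that base's
#' count; all other calls are ambiguous. Tallied counts always sum to
#' the drawn depth.
#'
#' @param sim output of [simulate_genotypes()] (list with `panel` and
#'   `truth`).
#' @param config a [simulation_config()] list.
#' @return A `locus_counts` data frame.
#' @export
simulate_counts <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- sim$panel
  truth <- sim$truth
  if (nrow(truth) == 0L) stop("empty truth table", call. = FALSE)
  set.seed(config$seed + 1L)
  n <- nrow(panel)
  depth <- pmax(1L, rnbinom(n, mu = config$depth_mean,
                            size = config$depth_dispersion))
  res <- matrix(0L, nrow = n, ncol = 5,
                dimnames = list(NULL, c("A", "C", "G", "T", "amb")))
  e <- config$error_rate
  for (i in seq_len(n)) {
    gt_r <- strsplit(truth$recipient_genotype[i], "")[[1]]
    gt_d <- strsplit(truth$donor_genotype[i], "")[[1]]
    n_donor <- rbinom(1, depth[i], config$donor_fraction)
    templates <- c(sample(gt_d, n_donor, replace = TRUE),
                   sample(gt_r, depth[i] - n_donor, replace = TRUE))
    err <- runif(depth[i]) < e
    if (any(err)) {
      templates[err] <- vapply(templates[err], function(b)
        sample(setdiff(.BASES, b), 1), character(1))
    }
    a <- panel$allele_a[i]; b <- panel$allele_b[i]
    res[i, a] <- sum(templates == a)
    res[i, b] <- sum(templates == b)
    res[i, "amb"] <- depth[i] - res[i, a] - res[i, b]
  }
  .counts_df(panel$locus_id, res[, "A"], res[, "C"], res[, "G"], res[, "T"],
             res[, "amb"])
}

#' Zero-intercept coefficient of determination
#'
#' Fits `y = b x` through the origin by least squares and returns
#' `1 - sum((y - b x)^2) / sum(y^2)` — the fraction of the (uncentred)
#' variation in `y` captured by proportionality to `x`.
#'
#' @param expected numeric vector of true values (not all zero).
#' @param estimated numeric vector of estimates, same length.
#' @return The zero-intercept R-squared.
#' @export
zero_intercept_r2 <- function(expected, estimated) {
  if (length(expected) != length(estimated) || length(expected) < 2L)
    stop("need two vectors of equal length >= 2", call. = FALSE)
  if (all(expected == 0))
    stop("zero-intercept R2 undefined: all expected values are zero",
         call. = FALSE)
  b <- sum(expected * estimated) / sum(expected^2)
  1 - sum((estimated - b * expected)^2) / sum(estimated^2)
}

#' Simulated titration series through the full pipeline
#'
#' Emulates an in-vitro genomic-DNA admixture titration: one pair of
#' unrelated contributors is drawn once (as when mixing two cell-line
#' DNAs), then for each donor fraction and replicate an independent
#' sequencing run is simulated, loci are selected, and the donor
#' percentage estimated. Defaults follow the six-mixture triplicate
#' design at 0, 0.5, 1, 2, 4 and 8% donor.
#'
#' @param fractions donor fractions to titrate (each in \[0, 0.14)).
#' @param replicates sequencing replicates per fraction (default 3).
#' @param config a [simulation_config()] list giving panel size, depth
#'   and error rate; its `donor_fraction` and `seed` are overridden per
#'   run.
#' @param seed master seed for the whole series.
#' @param n_replicates EM replicates per estimate (default 200).
#' @param selection a [selection_config()] list.
#' @return A data frame of class `titration` with columns `fraction`,
#'   `replicate`, `expected_percent`, `estimated_percent`, `percent_sd`,
#'   `n_loci_used`, `detectable`; attribute `r2` holds the zero-intercept
#'   R-squared of estimated on expected percent (`NA` if every expected
#'   value is zero).
#' @export
run_titration <- function(fractions = c(0, 0.005, 0.01, 0.02, 0.04, 0.08),
                          replicates = 3,
                          config = simulation_config(),
                          seed = 1,
                          n_replicates = 200,
                          selection = selection_config()) {
  stopifnot(inherits(config, "sim_config"),
            all(fractions >= 0), all(fractions < 0.14), replicates >= 1)
  seed <- as.integer(seed)
  base_cfg <- config
  base_cfg$seed <- seed
  sim <- simulate_genotypes(base_cfg)  # one contributor pair per series
  grid <- expand.grid(replicate = seq_len(replicates), fraction = fractions)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    cfg <- config
    cfg$donor_fraction <- grid$fraction[k]
    cfg$seed <- seed + 1000L * k
    counts <- simulate_counts(sim, cfg)
    sel <- suppressWarnings(select_loci(counts, sim$panel, selection))
    est <- suppressWarnings(estimate_donor_fraction(
      sel, n_replicates = n_replicates, seed = seed + 1000L * k + 1L))
    data.frame(
      fraction = grid$fraction[k], replicate = grid$replicate[k],
      expected_percent = 100 * grid$fraction[k],
      estimated_percent = est$percent_mean,
      percent_sd = est$percent_sd,
      n_loci_used = est$n_loci_used,
      detectable = est$detectable
    )
  })
  out <- do.call(rbind, rows)
  r2 <- if (all(out$expected_percent == 0)) NA_real_
        else zero_intercept_r2(out$expected_percent, out$estimated_percent)
  class(out) <- c("titration", "data.frame")
  attr(out, "r2") <- r2
  out
}

#' Write simulator outputs for consumption by the pipeline commands
#'
#' @param sim output of [simulate_genotypes()].
#' @param counts output of [simulate_counts()].
#' @param dir output directory (created if needed). Writes `panel.bed`,
#'   `counts.tsv` and `truth.tsv`.
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel_bed(sim$panel, file.path(dir, "panel.bed"))
  write_counts_table(counts, file.path(dir, "counts.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
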