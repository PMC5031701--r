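# Independent oracles and fixture builders shared across tests.
# The oracle code deliberately avoids the package's EM internals: it
# evaluates the constrained mixture likelihood by direct summation and
# maximizes it by brute-force grid search.

# direct density summation (no log-sum-exp, no shared code with the EM)
oracle_mixture_loglik <- function(y, mu_err, mu_osa, sigma_err, sigma_osa) {
  sum(log(0.25 * dnorm(y, mu_err, sigma_err) +
          0.50 * dnorm(y, mu_osa, sigma_osa) +
          0.25 * dnorm(y, 2 * mu_osa, 2 * sigma_osa)))
}

# brute-force maximization over a data-anchored grid of the four free
# parameters; returns the grid maximum and the best parameter row
oracle_grid_search <- function(y, floor = 1e-5) {
  me <- seq(0, max(quantile(y, 0.6), 2 * floor), length.out = 15)
  mo <- seq(max(min(y) / 2, floor),
            max(max(y) * 0.6, 2 * floor), length.out = 20)
  smax <- max(sd(y), 2 * floor)
  se <- exp(seq(log(floor), log(2 * smax), length.out = 10))
  so <- exp(seq(log(floor), log(2 * smax), length.out = 10))
  g <- expand.grid(mu_err = me, mu_osa = mo, sigma_err = se, sigma_osa = so)
  n <- length(y)
  m <- nrow(g)
  Y <- matrix(y, nrow = n, ncol = m)
  ex <- function(v) matrix(v, nrow = n, ncol = m, byrow = TRUE)
  dens <- 0.25 * dnorm(Y, ex(g$mu_err), ex(g$sigma_err)) +
          0.50 * dnorm(Y, ex(g$mu_osa), ex(g$sigma_osa)) +
          0.25 * dnorm(Y, ex(2 * g$mu_osa), ex(2 * g$sigma_osa))
  ll <- colSums(log(dens))
  i <- which.max(ll)
  list(loglik = ll[i], params = g[i, ])
}

# reference sample for the oracle comparisons: three bands at the error
# rate, x/2 and x for x = 0.02, in roughly 1:2:1 proportion
idealized_fractions <- function() {
  set.seed(101)
  y <- c(rnorm(10, 0.001, 0.0004),
         rnorm(21, 0.011, 0.0010),
         rnorm(11, 0.021, 0.0015))
  pmin(pmax(y, 0), 1)
}

# a small mixed-chromosome panel used across IO and selection tests
make_test_panel <- function() {
  panel_loci(
    locus_id = c("rs1", "rs2", "rs3", "rsY"),
    chrom = c("1", "chr2", "10", "chrY"),
    pos = c(1000L, 2000L, 3000L, 500L),
    allele_a = c("A", "C", "G", "C"),
    allele_b = c("G", "T", "A", "T")
  )
}

write_min_vcf <- function(path, records) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    records
  ), path)
}

# one pileup line; qualities given as a Phred integer vector
pileup_line <- function(chrom, pos, ref, bases, quals) {
  paste(chrom, pos, ref, length(quals), bases,
        intToUtf8(quals + 33L), sep = "\t")
}

counts_row <- function(locus_id, n_A = 0, n_C = 0, n_G = 0, n_T = 0,
                       n_ambiguous = 0) {
  df <- data.frame(locus_id = locus_id, n_A = n_A, n_C = n_C, n_G = n_G,
                   n_T = n_T, n_ambiguous = n_ambiguous,
                   stringsAsFactors = FALSE)
  df$depth_qualified <- df$n_A + df$n_C + df$n_G + df$n_T + df$n_ambiguous
  df$absent <- FALSE
  class(df) <- c("locus_counts", "data.frame")
  df
}
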