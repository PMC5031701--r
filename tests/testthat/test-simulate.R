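test_that("simulation configs validate their parameter ranges", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(allele_freq = 1.0), "\\(0, 1\\)")
  expect_error(simulation_config(allele_freq = 0), "\\(0, 1\\)")
  expect_error(simulation_config(donor_fraction = 0.14), "14%")
  expect_error(simulation_config(donor_fraction = -0.01), "0.14")
  expect_error(simulation_config(error_rate = 0.3), "0.25")
  expect_error(simulation_config(depth_mean = 0), ">= 1")
})

test_that("shared-allele classes follow the 1:2:1 admixture structure", {
  cfg <- simulation_config(n_loci = 4000, allele_freq = 0.5, seed = 21)
  sim <- simulate_genotypes(cfg)
  gt <- sim$truth
  hom <- substr(gt$recipient_genotype, 1, 1) ==
         substr(gt$recipient_genotype, 2, 2)
  p <- prop.table(table(gt$shared_class[hom]))
  # donor shares both alleles 25%, one 50%, neither 25% of the time
  expect_equal(unname(p[["both-shared"]]), 0.25, tolerance = 0.2)
  expect_equal(unname(p[["one-shared"]]), 0.50, tolerance = 0.1)
  expect_equal(unname(p[["none-shared"]]), 0.25, tolerance = 0.2)
  # shared_class is consistent with the genotypes it was derived from
  osa <- gt[hom & gt$shared_class == "one-shared", ]
  rec_allele <- substr(osa$recipient_genotype, 1, 1)
  hits <- mapply(function(a, d) sum(strsplit(d, "")[[1]] == a),
                 rec_allele, osa$donor_genotype)
  expect_true(all(hits == 1))
})

test_that("genotype and count simulation are deterministic under a seed", {
  cfg <- simulation_config(n_loci = 50, donor_fraction = 0.02, seed = 33)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1, s2)
  expect_identical(simulate_counts(s1, cfg), simulate_counts(s2, cfg))
})

test_that("counts conserve depth and respect the no-signal limit", {
  cfg <- simulation_config(n_loci = 40, donor_fraction = 0, error_rate = 0,
                           seed = 3)
  sim <- simulate_genotypes(cfg)
  counts <- simulate_counts(sim, cfg)
  expect_true(all(counts$depth_qualified ==
                  counts$n_A + counts$n_C + counts$n_G + counts$n_T +
                  counts$n_ambiguous))
  expect_true(all(counts$n_ambiguous == 0))
  # recipient-homozygous loci have every read on the recipient allele
  hom <- substr(sim$truth$recipient_genotype, 1, 1) ==
         substr(sim$truth$recipient_genotype, 2, 2)
  mat <- as.matrix(counts[hom, c("n_A", "n_C", "n_G", "n_T")])
  expect_true(all(apply(mat, 1, function(r) sum(r > 0)) == 1))
})

# Direct construction of one locus with known genotypes, deep enough that
# the minor fraction concentrates on its expectation.
deep_locus <- function(recipient, donor, donor_fraction, error_rate, seed) {
  panel <- panel_loci("L1", "1", 100L, "A", "G")
  truth <- data.frame(locus_id = "L1", recipient_genotype = recipient,
                      donor_genotype = donor, shared_class = NA,
                      stringsAsFactors = FALSE)
  cfg <- simulation_config(n_loci = 1, donor_fraction = donor_fraction,
                           depth_mean = 1e5, depth_dispersion = 1e6,
                           error_rate = error_rate, seed = seed)
  counts <- simulate_counts(list(panel = panel, truth = truth), cfg)
  counts$n_G / (counts$n_A + counts$n_G)
}

test_that("minor fractions match the admixture expectations per class", {
  # no shared allele: minor fraction converges to x
  expect_equal(deep_locus("AA", "GG", 0.08, 0, seed = 1), 0.08,
               tolerance = 0.05)
  # one shared allele: minor fraction converges to x/2
  expect_equal(deep_locus("AA", "AG", 0.08, 0, seed = 2), 0.04,
               tolerance = 0.08)
  # with errors, the panel-allele fraction at NSA loci is
  # (x(1-e) + (1-x)e/3) / (1 - 2e/3): errors add e/3 on-panel and
  # remove 2e/3 of reads to the ambiguous bucket
  e <- 0.01; x <- 0.08
  expected <- (x * (1 - e) + (1 - x) * e / 3) / (1 - 2 * e / 3)
  expect_equal(deep_locus("AA", "GG", x, e, seed = 4), expected,
               tolerance = 0.05)
})

test_that("zero-intercept R2 follows its closed form", {
  expect_equal(zero_intercept_r2(c(1, 2, 3), c(1, 2, 3)), 1.0)
  # slope absorbs scale; the statistic measures linearity through 0
  expect_equal(zero_intercept_r2(c(1, 2, 3), c(2, 4, 6)), 1.0)
  # frozen independent hand calculation: b = 14.5/14,
  # R2 = 1 - 0.0421428.../15.06
  expect_equal(zero_intercept_r2(c(1, 2, 3), c(1.1, 1.9, 3.2)),
               0.9972016695, tolerance = 1e-9)
  expect_error(zero_intercept_r2(c(0, 0), c(1, 2)), "all expected")
  expect_error(zero_intercept_r2(1, c(1, 2)), "equal length")
})

test_that("titration tables are deterministic and carry their R2", {
  cfg <- simulation_config(n_loci = 60, depth_mean = 800)
  t1 <- run_titration(fractions = c(0.01, 0.04), replicates = 2,
                      config = cfg, seed = 5, n_replicates = 40)
  t2 <- run_titration(fractions = c(0.01, 0.04), replicates = 2,
                      config = cfg, seed = 5, n_replicates = 40)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 4L)
  expect_true(is.numeric(attr(t1, "r2")))
  expect_equal(t1$expected_percent, c(1, 1, 4, 4))
})

test_that("an all-zero titration reports R2 as not applicable", {
  cfg <- simulation_config(n_loci = 60, depth_mean = 800)
  t0 <- run_titration(fractions = 0, replicates = 2, config = cfg,
                      seed = 6, n_replicates = 30)
  expect_true(is.na(attr(t0, "r2")))
})

test_that("simulation outputs round-trip through the pipeline file formats", {
  cfg <- simulation_config(n_loci = 30, donor_fraction = 0.02, seed = 17)
  sim <- simulate_genotypes(cfg)
  counts <- simulate_counts(sim, cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, counts, dir)
  panel <- read_panel_bed(file.path(dir, "panel.bed"))
  expect_equal(panel, sim$panel, ignore_attr = TRUE)
  back <- load_counts_table(file.path(dir, "counts.tsv"), panel)
  expect_equal(back$depth_qualified, counts$depth_qualified)
})
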