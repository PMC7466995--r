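test_that("flank trimming keeps the central window and flags short loci", {
  expect_identical(trim_flanks(rep(10, 300), 75), rep(10, 150))
  expect_equal(mean(trim_flanks(rep(10, 300), 75)), 10)
  expect_null(trim_flanks(rep(10, 150), 75))      # length == 2t
  expect_identical(trim_flanks(5:1, 0), 5:1)
})

test_that("trimming a ramped profile recovers the plateau mean", {
  ramp <- seq(0, 50, length.out = 100)
  profile <- c(ramp, rep(50, 400), rev(ramp))
  trimmed <- trim_flanks(profile, 100)
  expect_equal(mean(trimmed), mean(ref_trim(profile, 100)))
  expect_equal(mean(trimmed), 50)
  # trimming flanks whose depths are below the interior never lowers the mean
  expect_gte(mean(trim_flanks(profile, 75)), mean(profile))
})

test_that("IQR filter keeps degenerate input and matches the brute force", {
  expect_identical(iqr_filter(c(5, 5, 5, 5)), 1:4)
  expect_warning(kept <- iqr_filter(c(1, 100, 5)), "fewer than 4")
  expect_identical(kept, 1:3)
  set.seed(31)
  for (i in 1:100) {
    v <- switch(1 + i %% 4,
                rnorm(sample(4:60, 1), 50, 20),
                rpois(sample(4:60, 1), 8),
                c(runif(20, 0, 10), runif(3, 100, 200)),
                rep(runif(1), 7))
    m <- sample(c(1, 1.5, 3, Inf), 1)
    expect_identical(iqr_filter(v, m), ref_iqr_keep(v, m))
  }
})

test_that("loci with extreme coverage are excluded exactly", {
  # 71 single-copy loci between 2.10x and 9.27x plus 3 loci above 160x:
  # the 3x IQR rule must remove exactly the three inflated loci
  set.seed(32)
  vals <- c(runif(71, 2.10, 9.27), runif(3, 160, 200))
  kept <- iqr_filter(vals, 3)
  expect_identical(kept, 1:71)
  expect_identical(kept, ref_iqr_keep(vals, 3))
})

test_that("coverage estimation follows trim -> filter -> average", {
  cov <- coverage_set(list(a = rep(10L, 300), b = rep(20L, 300)))
  # two loci: the IQR filter warns that quartiles are not meaningful
  cs <- suppressWarnings(estimate_coverage(cov, trim_bases = 75))
  expect_equal(cs$mean_coverage, 15)
  expect_equal(cs$n_kept, 2)

  # locus too short to trim is rejected, not fatal
  cov2 <- coverage_set(list(a = rep(10L, 300), b = rep(20L, 300),
                            short = rep(9L, 100)))
  cs2 <- suppressWarnings(estimate_coverage(cov2, trim_bases = 75))
  expect_equal(cs2$mean_coverage, 15)
  expect_identical(cs2$loci$rejection_reason[3], "too_short")

  # all loci rejected is an explicit failure naming reasons
  cov3 <- coverage_set(list(a = rep(1L, 10), b = rep(1L, 12)))
  expect_error(suppressWarnings(estimate_coverage(cov3, trim_bases = 75)),
               "too_short=2")
})

test_that("length outliers are rejected, coverage reason takes priority", {
  set.seed(33)
  loci <- lapply(1:12, function(i) as.integer(rpois(400, 20)))
  names(loci) <- sprintf("L%02d", 1:12)
  loci$long <- as.integer(rpois(5000, 20))        # length outlier
  loci$both <- as.integer(rpois(5000, 500))       # length + coverage outlier
  cs <- estimate_coverage(coverage_set(loci), trim_bases = 75)
  expect_identical(cs$loci$rejection_reason[cs$loci$locus_id == "long"],
                   "length_outlier")
  expect_identical(cs$loci$rejection_reason[cs$loci$locus_id == "both"],
                   "coverage_outlier")
  expect_equal(cs$n_kept, 12)
})

test_that("coverage estimation is invariant to locus order and ids", {
  set.seed(34)
  cov <- random_coverage_set(10)
  cs <- estimate_coverage(cov, trim_bases = 5)
  perm <- sample(length(cov))
  shuffled <- unclass(cov)[perm]
  names(shuffled) <- sprintf("renamed_%02d", seq_along(shuffled))
  cs2 <- estimate_coverage(coverage_set(shuffled), trim_bases = 5)
  expect_equal(cs2$mean_coverage, cs$mean_coverage)
  expect_equal(sort(cs2$loci$trimmed_mean_coverage),
               sort(cs$loci$trimmed_mean_coverage))
})

test_that("untrimmed, unfiltered pooled averaging is the naive estimator", {
  set.seed(35)
  cov <- random_coverage_set(8)
  cs <- estimate_coverage(cov, trim_bases = 0, iqr_multiplier = Inf,
                          averaging = "pooled")
  naive <- sum(as.numeric(unlist(cov))) / sum(lengths(cov))
  expect_equal(cs$mean_coverage, naive)
})

test_that("full pipeline matches the brute-force reference on random sets", {
  set.seed(36)
  for (i in 1:30) {
    cov <- random_coverage_set()
    t <- sample(c(0, 3, 10), 1)
    m <- sample(c(1.5, 3, Inf), 1)
    avg <- sample(c("locus_mean", "pooled"), 1)
    got <- suppressWarnings(
      estimate_coverage(cov, trim_bases = t, iqr_multiplier = m,
                        averaging = avg)$mean_coverage)
    expect_equal(got, suppressWarnings(ref_estimate_coverage(
      unclass(cov), t, m, avg)))
  }
})

test_that("Lander-Waterman converts coverage to genome size", {
  st <- library_stats(n_reads = 100, total_bases = 10000)
  est <- lander_waterman(st, coverage = 1)
  expect_equal(est$genome_size, 10000)            # G = LN/C identity
  expect_equal(est$genome_size * est$coverage, st$total_bases)

  # G * C = B holds for arbitrary coverages
  for (C in c(0.5, 7.3, 96.18)) {
    e <- lander_waterman(st, C)
    expect_equal(e$genome_size * C, st$total_bases)
  }
  expect_error(lander_waterman(st, 0), "positive")

  # mitochondrial subtraction acts on B
  stm <- library_stats(100, 10000, n_mito_reads = 2, mito_bases = 200)
  expect_equal(lander_waterman(stm, 1, exclude_mito = TRUE)$genome_size,
               9800)
})

test_that("genome size recovers the simulated truth on ideal libraries", {
  sim <- simulate_library(sim_config(genome_size = 2e5, n_loci = 12,
                                     depth = 25, seed = 21))
  cs <- estimate_coverage(sim$coverage, trim_bases = 75)
  est <- lander_waterman(sim$stats, cs)
  # 12 loci give a ~1.5% standard error on C, hence the 4% bound here;
  # recovery at the reference scale (40 loci) is checked elsewhere at 3%
  expect_lt(abs(est$genome_size - 2e5) / 2e5, 0.04)
})

test_that("mito screen flags by shared canonical k-mers", {
  set.seed(37)
  mito <- random_dna(2000)
  verbatim <- substr(mito, 501, 600)              # read copied from the ref
  random_read <- random_dna(100)
  scr <- mito_screen(c(verbatim, random_read), mito, k = 21)
  expect_identical(scr$flagged, c(TRUE, FALSE))
  expect_equal(scr$stats$n_mito_reads, 1)
  expect_equal(scr$stats$mito_bases, 100)
  expect_identical(scr$kept, random_read)
})

test_that("mito screen recovers a simulated contamination fraction", {
  sim <- simulate_library(sim_config(genome_size = 2e5, n_loci = 10,
                                     depth = 20, mito_fraction = 0.02,
                                     seed = 22))
  scr <- mito_screen(sim$reads$reads, sim$mito, k = 21)
  frac <- scr$stats$n_mito_reads / scr$stats$n_reads
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.03)

  # excluding mito bases corrects the inflated estimate downward by ~2%
  cs <- estimate_coverage(sim$coverage)
  g_in <- lander_waterman(sim$stats, cs, exclude_mito = FALSE)$genome_size
  g_ex <- lander_waterman(sim$stats, cs, exclude_mito = TRUE)$genome_size
  expect_gt(g_in, g_ex)
  expect_equal(g_in / g_ex, 1 / (1 - 0.02), tolerance = 0.01)
})
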