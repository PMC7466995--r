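test_that("background genomes hit the requested size and GC", {
  cfg <- sim_config(genome_size = 1e5, n_loci = 0, locus_length = 0,
                    seed = 51)
  g <- make_genome(cfg)
  expect_equal(nchar(g$sequence), 1e5)
  gc <- sum(strsplit(g$sequence, "")[[1]] %in% c("G", "C")) / 1e5
  expect_lt(abs(gc - cfg$gc), 0.01)
  # determinism: same seed, byte-identical sequence
  expect_identical(make_genome(cfg)$sequence, g$sequence)
  expect_false(identical(
    make_genome(sim_config(genome_size = 1e5, n_loci = 0, locus_length = 0,
                           seed = 52))$sequence, g$sequence))
})

test_that("repeat families are inserted as findable copies", {
  cfg <- sim_config(genome_size = 1e5, n_loci = 0, locus_length = 0,
                    repeat_spec = list(list(unit_length = 200,
                                            copy_number = 20,
                                            divergence = 0)),
                    seed = 53)
  g <- make_genome(cfg)
  unit <- substr(g$sequence, g$repeats$start[1] + 1, g$repeats$end[1])
  hits <- gregexpr(unit, g$sequence, fixed = TRUE)[[1]]
  expect_equal(length(hits), 20)
  expect_setequal(as.integer(hits) - 1L, g$repeats$start)
})

test_that("locus placement respects bounds, spacing and feasibility", {
  cfg <- sim_config(genome_size = 1e5, n_loci = 20, locus_length = 1500,
                    seed = 54)
  g <- make_genome(cfg)
  bed <- g$loci
  expect_equal(nrow(bed), 20)
  expect_true(all(bed$start >= 100 & bed$end <= 1e5 - 100))
  o <- order(bed$start)
  expect_true(all(bed$start[o][-1] >= bed$end[o][-20]))  # non-overlapping
  expect_error(make_genome(sim_config(genome_size = 2e4, n_loci = 13,
                                      locus_length = 1500, seed = 54)),
               "infeasible|genome_size")
})

test_that("diploid haplotypes differ at the binomial het sites", {
  hap <- random_dna(1e5)
  same <- make_diploid(hap, 0, seed = 55)
  expect_identical(same$hapA, same$hapB)

  dip <- make_diploid(hap, 0.01, seed = 55)
  a <- strsplit(dip$hapA, "")[[1]]; b <- strsplit(dip$hapB, "")[[1]]
  diff <- which(a != b)
  expect_identical(diff, dip$het_positions)
  expect_gt(length(diff), 850)     # ~N(1000, 31.5), +-4.7 sigma
  expect_lt(length(diff), 1150)
})

test_that("reads are faithful substrings with uniform coverage", {
  cfg <- sim_config(genome_size = 1e5, n_loci = 5, depth = 20, seed = 56)
  sim <- simulate_library(cfg)
  expect_equal(length(sim$reads$reads), round(20 * 1e5 / 100))

  # error-free reads equal the reference substring (or reverse complement)
  ori <- sim$reads$origins
  for (i in c(1, 500, 20000)) {
    ref_sub <- substr(sim$genome$sequence, ori$start[i] + 1,
                      ori$start[i] + 100)
    got <- sim$reads$reads[[ori$read[i]]]
    expect_identical(got,
                     if (ori$strand[i] == "+") ref_sub
                     else ref_revcomp(ref_sub))
  }

  # realized genome-wide depth has the configured mean
  depth <- cumsum(tabulate(ori$start + 1, nbins = 1e5) -
                    tabulate(ori$start + 101, nbins = 1e5))
  expect_lt(abs(mean(depth) - 20) / 20, 0.02)
})

test_that("substitution errors appear at the configured rate", {
  cfg <- sim_config(genome_size = 5e4, n_loci = 0, locus_length = 0,
                    depth = 10, error_rate = 0.02, seed = 57)
  g <- make_genome(cfg)
  rd <- simulate_reads(c(hapA = g$sequence), cfg)
  ori <- rd$origins
  mism <- vapply(seq_len(200), function(i) {
    ref_sub <- substr(g$sequence, ori$start[i] + 1, ori$start[i] + 100)
    if (ori$strand[i] == "-") ref_sub <- ref_revcomp(ref_sub)
    sum(strsplit(rd$reads[[i]], "")[[1]] != strsplit(ref_sub, "")[[1]])
  }, numeric(1))
  expect_equal(mean(mism) / 100, 0.02, tolerance = 0.25)
})

test_that("the overlap contract shapes locus coverage", {
  cfg <- sim_config(genome_size = 1e5, n_loci = 5, depth = 30, seed = 58)
  sim <- simulate_library(cfg)
  ori <- sim$reads$origins
  genome_depth <- cumsum(tabulate(ori$start + 1, nbins = 1e5) -
                           tabulate(ori$start + 101, nbins = 1e5))

  # f = 0: locus profile equals the genome-wide depth restricted to the locus
  cov0 <- project_locus_coverage(ori, sim$genome$loci, 100,
                                 min_overlap_frac = 0)
  for (i in seq_len(5)) {
    s <- sim$genome$loci$start[i]; e <- sim$genome$loci$end[i]
    expect_identical(cov0[[i]], genome_depth[(s + 1):e])
  }

  # f = 1: flanks are depressed, trimmed mean recovers genome-wide depth
  cov1 <- sim$coverage
  for (i in seq_len(5)) {
    prof <- cov1[[i]]
    flank_mean <- mean(c(prof[1:75], prof[(length(prof) - 74):length(prof)]))
    inner <- trim_flanks(prof, 75)
    expect_lt(flank_mean, mean(inner))
  }
  cs <- estimate_coverage(cov1, trim_bases = 75)
  expect_lt(abs(cs$mean_coverage - mean(genome_depth)) / 30, 0.05)

  # a single fully contained read adds +1 over exactly its span
  one <- data.frame(read = "r1", source = "hapA", start = 150, strand = "+")
  loci <- data.frame(chrom = "g", start = 100, end = 400, name = "loc")
  cv <- project_locus_coverage(one, loci, 100, min_overlap_frac = 1)
  expect_identical(cv$loc, c(rep(0L, 50), rep(1L, 100), rep(0L, 150)))
  # a read straddling the boundary is dropped at f = 1, kept at f = 0.5
  straddle <- data.frame(read = "r1", source = "hapA", start = 60,
                         strand = "+")
  expect_identical(sum(project_locus_coverage(straddle, loci, 100, 1)$loc), 0L)
  expect_identical(sum(project_locus_coverage(straddle, loci, 100, 0.5)$loc),
                   60L)
})

test_that("written simulations round-trip through the standard formats", {
  sim <- simulate_library(sim_config(genome_size = 5e4, n_loci = 4,
                                     locus_length = 800, depth = 15,
                                     het_rate = 0.005, mito_fraction = 0.02,
                                     seed = 59))
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  expect_true(all(file.exists(paths)))

  expect_identical(read_basecov(paths["basecov"], "bbmap"), sim$coverage)
  bed <- read_bed(paths["loci"])
  expect_equal(bed$start, sim$genome$loci$start)
  st <- scan_reads(paths["reads"])
  expect_equal(st$n_reads, sim$stats$n_reads)
  expect_equal(st$total_bases, sim$stats$total_bases)
  fa <- Biostrings::readDNAStringSet(paths["genome"])
  expect_identical(as.character(fa[[1]]), sim$genome$sequence)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$genome_size, 5e4)
  expect_equal(truth$n_mito_reads, sim$truth$n_mito_reads)
})

test_that("stage substreams keep stages independent", {
  cfg1 <- sim_config(genome_size = 5e4, n_loci = 3, locus_length = 500,
                     seed = 60)
  cfg2 <- sim_config(genome_size = 5e4, n_loci = 3, locus_length = 500,
                     het_rate = 0.01, seed = 60)
  # turning on heterozygosity must not change the haploid genome
  expect_identical(make_genome(cfg1)$sequence, make_genome(cfg2)$sequence)
})
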