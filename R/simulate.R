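# Seeded shotgun simulator: genomes with repeat families and single-copy
# loci, diploid variants, uniform reads with substitution errors,
# mitochondrial contamination, and locus coverage under a minimum-overlap
# mapping contract. Every stage draws from its own substream of one global
# seed, so regenerating one stage never perturbs another.

#' Simulation configuration
#'
#' Defaults describe the reference recovery scenario used throughout the
#' package's tests: a 1 Mb homozygous, repeat-free haploid genome carrying
#' 40 single-copy loci of 1.5 kb, sequenced error-free to 30x with 100 b
#' reads, with a full-overlap mapping contract (`min_overlap_frac = 1`) that
#' reproduces locus flank-coverage ramps.
#'
#' @param genome_size Haploid genome size G* in bases.
#' @param gc GC fraction of the background sequence (default 0.40, typical
#'   of insect nuclear genomes).
#' @param n_loci Number of single-copy loci to place.
#' @param locus_length Length of each locus in bases.
#' @param repeat_spec List of repeat families, each
#'   `list(unit_length =, copy_number =, divergence =)`; copies are
#'   near-identical with per-copy substitution divergence.
#' @param het_rate Per-base heterozygous SNP probability for the diploid
#'   second haplotype (0 = homozygous).
#' @param mito_size Mitochondrial genome size in bases (default 16 kb, the
#'   typical insect mitogenome).
#' @param mito_fraction Fraction of reads drawn from the mitochondrial
#'   sequence.
#' @param depth Target base coverage C*.
#' @param read_length Read length L in bases.
#' @param error_rate Per-base substitution error probability.
#' @param min_overlap_frac Fraction f of a read that must lie inside a locus
#'   for the read to count toward locus coverage (the mapper contract; f = 1
#'   requires full containment and yields flank ramps of width L - 1).
#' @param seed Integer seed; expanded internally into per-stage substreams.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_size = 1e6, gc = 0.40, n_loci = 40,
                       locus_length = 1500, repeat_spec = NULL,
                       het_rate = 0, mito_size = 16000, mito_fraction = 0,
                       depth = 30, read_length = 100, error_rate = 0,
                       min_overlap_frac = 1, seed = 1) {
  fr <- c(gc = gc, het_rate = het_rate, error_rate = error_rate,
          mito_fraction = mito_fraction, min_overlap_frac = min_overlap_frac)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  if (genome_size < n_loci * locus_length)
    stop("genome_size must be >= n_loci * locus_length")
  if (!is.null(repeat_spec)) {
    stopifnot(is.list(repeat_spec))
    for (f in repeat_spec)
      stopifnot(all(c("unit_length", "copy_number", "divergence") %in%
                      names(f)))
  }
  structure(list(genome_size = as.numeric(genome_size), gc = gc,
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 repeat_spec = repeat_spec, het_rate = het_rate,
                 mito_size = as.integer(mito_size),
                 mito_fraction = mito_fraction, depth = depth,
                 read_length = as.integer(read_length),
                 error_rate = error_rate,
                 min_overlap_frac = min_overlap_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Run expr under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Expand one global seed into named per-stage substream seeds.
derive_seeds <- function(seed) {
  with_seed(seed, {
    s <- sample.int(2147483646L, 8)
    names(s) <- c("genome", "repeats", "loci", "diploid", "mito", "reads",
                  "errors", "spare")
    s
  })
}

BASES <- c("A", "C", "G", "T")

rand_chars <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# Substitute positions (1-based) with a uniformly chosen different base.
substitute_bases <- function(chars, positions) {
  if (length(positions) == 0) return(chars)
  cur <- chars[positions]
  pick <- sample.int(3L, length(positions), replace = TRUE)
  alt <- matrix(c("C", "G", "T",  # alternatives to A
                  "A", "G", "T",  # to C
                  "A", "C", "T",  # to G
                  "A", "C", "G"), # to T
                nrow = 4, byrow = TRUE,
                dimnames = list(BASES, NULL))
  chars[positions] <- alt[cbind(match(cur, BASES), pick)]
  chars
}

# Place n intervals of length len in [0, G) avoiding 'occupied' (two-column
# matrix start,end, 0-based half-open) with the given margin. Rejection
# sampling; errors out as infeasible after max_tries per interval.
place_intervals <- function(n, len, G, occupied, margin = 0,
                            max_tries = 1000) {
  placed <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(G - len + 1, 1) - 1
      e <- s + len
      all_iv <- rbind(occupied, placed)
      if (nrow(all_iv) == 0 ||
          !any(s < all_iv[, 2] + margin & e > all_iv[, 1] - margin)) {
        placed <- rbind(placed, c(s, e))
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("infeasible packing: could not place interval ", i, " of ", n,
           " (length ", len, ") in genome of size ", G)
  }
  placed
}

#' Generate a haploid genome with repeat families and single-copy loci
#'
#' Background sequence is i.i.d. with the configured GC; each repeat family
#' is inserted as near-identical copies (per-copy substitution divergence) at
#' non-overlapping positions; single-copy loci are then placed at least one
#' read length away from every repeat copy and from the genome ends, so
#' locus coverage is not confounded by repeats or edge effects. Deterministic
#' given the seed.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_genome`: list with `sequence` (character
#'   string), `loci` (BED-style data frame), `repeats` (data frame of placed
#'   copies), `config`.
#' @export
make_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- derive_seeds(cfg$seed)
  G <- cfg$genome_size
  margin <- cfg$read_length
  rep_total <- if (is.null(cfg$repeat_spec)) 0 else
    sum(vapply(cfg$repeat_spec,
               function(f) f$unit_length * f$copy_number, numeric(1)))
  if (rep_total + cfg$n_loci * (cfg$locus_length + 2 * margin) > G)
    stop("infeasible packing: loci + repeats exceed the genome size")

  chars <- with_seed(seeds[["genome"]], rand_chars(G, cfg$gc))

  rep_iv <- matrix(numeric(0), ncol = 2)
  rep_df <- data.frame(family = integer(0), start = numeric(0),
                       end = numeric(0))
  if (!is.null(cfg$repeat_spec)) {
    with_seed(seeds[["repeats"]], {
      for (fi in seq_along(cfg$repeat_spec)) {
        fam <- cfg$repeat_spec[[fi]]
        unit <- rand_chars(fam$unit_length, cfg$gc)
        iv <- place_intervals(fam$copy_number, fam$unit_length, G, rep_iv)
        for (j in seq_len(nrow(iv))) {
          copy <- unit
          if (fam$divergence > 0) {
            pos <- which(runif(fam$unit_length) < fam$divergence)
            copy <- substitute_bases(copy, pos)
          }
          chars[(iv[j, 1] + 1):iv[j, 2]] <- copy
        }
        rep_iv <- rbind(rep_iv, iv)
        rep_df <- rbind(rep_df, data.frame(family = fi, start = iv[, 1],
                                           end = iv[, 2]))
      }
    })
  }

  loci_iv <- with_seed(seeds[["loci"]], {
    edge <- matrix(c(-margin, margin, G - margin, G + margin),
                   ncol = 2, byrow = TRUE)
    place_intervals(cfg$n_loci, cfg$locus_length, G,
                    rbind(rep_iv, edge), margin = margin)
  })
  o <- order(loci_iv[, 1])
  loci <- data.frame(chrom = rep("genome", cfg$n_loci),
                     start = loci_iv[o, 1], end = loci_iv[o, 2],
                     name = sprintf("locus_%03d", seq_len(cfg$n_loci)),
                     stringsAsFactors = FALSE)

  structure(list(sequence = paste(chars, collapse = ""), loci = loci,
                 repeats = rep_df, config = cfg),
            class = "sim_genome")
}

#' Derive a diploid pair of haplotypes
#'
#' Haplotype B differs from haplotype A at Binomial(G, het_rate) positions
#' with substitutions uniform over the three alternative bases.
#'
#' @param haploid Haploid sequence (character string).
#' @param het_rate Per-base heterozygous SNP probability.
#' @param seed Integer seed.
#' @return List with `hapA`, `hapB` (character strings) and `het_positions`
#'   (1-based positions where the haplotypes differ).
#' @export
make_diploid <- function(haploid, het_rate, seed = 1) {
  stopifnot(het_rate >= 0, het_rate <= 1)
  if (het_rate == 0)
    return(list(hapA = haploid, hapB = haploid, het_positions = integer(0)))
  with_seed(seed, {
    chars <- strsplit(haploid, "", fixed = TRUE)[[1]]
    pos <- which(runif(length(chars)) < het_rate)
    hapB <- substitute_bases(chars, pos)
    list(hapA = haploid, hapB = paste(hapB, collapse = ""),
         het_positions = pos)
  })
}

#' Simulate uniform shotgun reads
#'
#' Draws `N = round(depth * genome_size / read_length)` single-end reads.
#' Each read comes from the mitochondrial sequence with probability
#' `mito_fraction`, otherwise from one of the nuclear haplotypes chosen
#' equally; start positions are uniform over valid positions, strand is
#' uniform, and substitution errors are applied at `error_rate` per base.
#' Read origins (source, 0-based start, strand) are logged for coverage
#' projection and truth checks.
#'
#' @param sequences Named character vector or list of source sequences;
#'   the element named `"mito"` (if any) is the mitochondrial contaminant,
#'   all others are nuclear haplotypes sharing one coordinate system.
#' @param cfg A [sim_config()].
#' @return An object of class `sim_reads`: list with `reads` (named
#'   character vector), `origins` (data frame: read, source, start, strand),
#'   `config`.
#' @export
simulate_reads <- function(sequences, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sequences <- unlist(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named")
  L <- cfg$read_length
  if (any(nchar(sequences) < L))
    stop("read length exceeds the shortest source sequence")
  seeds <- derive_seeds(cfg$seed)
  N <- round(cfg$depth * cfg$genome_size / L)
  nuclear <- setdiff(names(sequences), "mito")
  if (length(nuclear) == 0) stop("at least one nuclear sequence is required")

  origins <- with_seed(seeds[["reads"]], {
    src <- if ("mito" %in% names(sequences) && cfg$mito_fraction > 0) {
      ifelse(runif(N) < cfg$mito_fraction, "mito",
             sample(nuclear, N, replace = TRUE))
    } else {
      sample(nuclear, N, replace = TRUE)
    }
    slen <- nchar(sequences)[src]
    start <- floor(runif(N) * (slen - L + 1))  # 0-based
    strand <- sample(c("+", "-"), N, replace = TRUE)
    data.frame(read = sprintf("read_%07d", seq_len(N)), source = src,
               start = start, strand = strand, stringsAsFactors = FALSE)
  })

  reads <- substring(sequences[origins$source], origins$start + 1,
                     origins$start + L)
  neg <- origins$strand == "-"
  if (any(neg))
    reads[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[neg])))

  if (cfg$error_rate > 0)
    reads <- with_seed(seeds[["errors"]], inject_errors(reads, L,
                                                        cfg$error_rate))
  names(reads) <- origins$read
  structure(list(reads = reads, origins = origins, config = cfg),
            class = "sim_reads")
}

# Substitution errors over the concatenated read bytes (uniform-length reads).
inject_errors <- function(reads, L, rate) {
  big <- charToRaw(paste(reads, collapse = ""))
  nb <- length(big)
  n_err <- rbinom(1, nb, rate)
  if (n_err > 0) {
    pos <- sample.int(nb, n_err)
    raw_bases <- charToRaw("ACGT")
    alt <- matrix(c(2L, 3L, 4L, 1L, 3L, 4L, 1L, 2L, 4L, 1L, 2L, 3L),
                  nrow = 4, byrow = TRUE)
    cur <- match(big[pos], raw_bases)
    pick <- sample.int(3L, n_err, replace = TRUE)
    big[pos] <- raw_bases[alt[cbind(cur, pick)]]
  }
  s <- rawToChar(big)
  starts <- seq(1, nb, by = L)
  substring(s, starts, starts + L - 1)
}

#' Project read origins onto locus coverage under a mapping contract
#'
#' A read contributes +1 depth to the bases it overlaps within a locus iff
#' its overlap with the locus is at least `min_overlap_frac * read_length`
#' (ties kept). With f = 1 only fully contained reads count, producing the
#' flank coverage ramps of width L - 1 that motivate flank trimming; with
#' f = 0 the profile equals the genome-wide depth restricted to the locus.
#' Mitochondrial reads never contribute.
#'
#' @param origins Read-origin data frame from [simulate_reads()].
#' @param loci BED-style data frame (`start`, `end`, `name`; 0-based
#'   half-open) on the same coordinate system as the nuclear sources.
#' @param read_length Read length L.
#' @param min_overlap_frac Minimum overlap fraction f in `[0, 1]`.
#' @return A [coverage_set()] with one profile per locus.
#' @export
project_locus_coverage <- function(origins, loci, read_length,
                                   min_overlap_frac = 1) {
  stopifnot(is.data.frame(origins), all(c("source", "start") %in%
                                          names(origins)))
  L <- read_length
  r <- origins$start[origins$source != "mito"]
  out <- vector("list", nrow(loci))
  names(out) <- loci$name
  for (i in seq_len(nrow(loci))) {
    s <- loci$start[i]; e <- loci$end[i]
    len <- e - s
    cand <- r[r > s - L & r < e]
    ov <- pmin(e, cand + L) - pmax(s, cand)
    cand <- cand[ov >= min_overlap_frac * L & ov > 0]
    a <- pmax(cand, s) - s          # 0-based within-locus start
    b <- pmin(cand + L, e) - s      # exclusive end
    out[[i]] <- cumsum(tabulate(a + 1, nbins = len) -
                         tabulate(b + 1, nbins = len))
  }
  coverage_set(out)
}

#' Simulate a complete sequencing library with ground truth
#'
#' Orchestrates [make_genome()], [make_diploid()] (when `het_rate > 0`), a
#' random mitochondrial contaminant (when `mito_fraction > 0`),
#' [simulate_reads()] and [project_locus_coverage()], returning everything a
#' recovery test needs.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `sim_library`: list with `genome`
#'   (`sim_genome`), `haplotypes`, `mito` (sequence or NULL), `reads`
#'   (`sim_reads`), `coverage` (locus [coverage_set()]), `stats`
#'   ([library_stats()] with realized mito accounting), and `truth` (the
#'   configured ground-truth values plus realized mitochondrial read count).
#' @examples
#' \donttest{
#' sim <- simulate_library(sim_config(genome_size = 1e5, n_loci = 10,
#'                                    depth = 10, seed = 42))
#' sim$truth$genome_size
#' }
#' @export
simulate_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- derive_seeds(cfg$seed)
  g <- make_genome(cfg)
  dip <- make_diploid(g$sequence, cfg$het_rate, seed = seeds[["diploid"]])
  sources <- if (cfg$het_rate > 0)
    c(hapA = dip$hapA, hapB = dip$hapB) else c(hapA = g$sequence)
  mito <- NULL
  if (cfg$mito_fraction > 0) {
    mito <- with_seed(seeds[["mito"]],
                      paste(rand_chars(cfg$mito_size, cfg$gc), collapse = ""))
    sources <- c(sources, mito = mito)
  }
  reads <- simulate_reads(sources, cfg)
  cov <- project_locus_coverage(reads$origins, g$loci, cfg$read_length,
                                cfg$min_overlap_frac)
  n_mito <- sum(reads$origins$source == "mito")
  stats <- library_stats(n_reads = length(reads$reads),
                         total_bases = sum(as.numeric(nchar(reads$reads))),
                         n_mito_reads = n_mito,
                         mito_bases = n_mito * cfg$read_length)
  truth <- list(genome_size = cfg$genome_size, depth = cfg$depth,
                read_length = cfg$read_length, het_rate = cfg$het_rate,
                error_rate = cfg$error_rate,
                mito_fraction = cfg$mito_fraction,
                n_mito_reads = n_mito, het_positions = dip$het_positions,
                seed = cfg$seed)
  structure(list(genome = g, haplotypes = dip, mito = mito, reads = reads,
                 coverage = cov, stats = stats, truth = truth, config = cfg),
            class = "sim_library")
}

#' Write a simulated library to disk
#'
#' Emits `genome.fa`, `haplotypes.fa` (diploid runs), `mito.fa` (when
#' contaminated), `loci.bed`, `reads.fastq`, `basecov.txt` (BBMap dialect)
#' and `truth.json` under `outdir`.
#'
#' @param sim A `sim_library` from [simulate_library()].
#' @param outdir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "sim_library"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             loci = file.path(outdir, "loci.bed"),
             reads = file.path(outdir, "reads.fastq"),
             basecov = file.path(outdir, "basecov.txt"),
             truth = file.path(outdir, "truth.json"))
  write_fasta(c(genome = sim$genome$sequence), paths["genome"])
  if (sim$config$het_rate > 0) {
    paths["haplotypes"] <- file.path(outdir, "haplotypes.fa")
    write_fasta(c(hapA = sim$haplotypes$hapA, hapB = sim$haplotypes$hapB),
                paths["haplotypes"])
  }
  if (!is.null(sim$mito)) {
    paths["mito"] <- file.path(outdir, "mito.fa")
    write_fasta(c(mito = sim$mito), paths["mito"])
  }
  write_bed(sim$genome$loci, paths["loci"])
  write_fastq(sim$reads$reads, paths["reads"])
  write_basecov(sim$coverage, paths["basecov"], dialect = "bbmap")
  truth <- sim$truth
  truth$het_positions <- NULL  # bulky; haplotypes.fa carries the variants
  jsonlite::write_json(c(truth, sim$config[setdiff(names(sim$config),
                                                   "repeat_spec")]),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

write_fastq <- function(reads, path) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%07d", seq_along(reads))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n",
                    strrep("I", nchar(reads))), con)
  invisible(path)
}
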