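# k-mer spectrum genome size estimation: canonical counting, error cutoff,
# coverage peak detection, retained-mass estimator, k sweep.

#' Count canonical k-mers from reads
#'
#' Counts canonical k-mers (the lexicographically smaller of a k-mer and its
#' reverse complement) over every window of k consecutive ACGT bases; windows
#' containing any other character are skipped. Exact in-memory counting with
#' 2-bit encoded k-mers, intended for desk-scale inputs (up to ~1e8 windows).
#' Output semantics match a Jellyfish multiplicity histogram.
#'
#' @param reads FASTQ path(s) (plain or gzip), a `DNAStringSet`, or a
#'   character vector of read sequences.
#' @param k Odd k-mer length, 3..31 (default 21, the conventional compromise
#'   between specificity and counting cost).
#' @return A [kmer_histogram()] with attributes `n_windows` (k-mer tokens
#'   counted) and `n_skipped` (windows lost to non-ACGT characters).
#' @examples
#' count_kmers("ACGTA", k = 3)  # {ACG, CGT, GTA} -> canonical {ACG, ACG, GTA}
#' @export
count_kmers <- function(reads, k = 21) {
  k <- as.integer(k)
  if (is.na(k) || k %% 2 == 0)
    stop("k must be odd (even k makes a k-mer and its reverse complement ",
         "ambiguous under canonicalization)")
  if (k < 3 || k > 31) stop("k must be between 3 and 31")
  seqs <- as_sequences(reads, format = "fastq")
  if (length(seqs) == 0) stop("no reads supplied")
  if (all(nchar(seqs) < k)) {
    warning("k exceeds every read length: zero k-mer windows")
    h <- kmer_histogram(k, integer(0), numeric(0))
    attr(h, "n_windows") <- 0; attr(h, "n_skipped") <- 0
    return(h)
  }
  if (any(nchar(seqs) < k))
    warning("some reads are shorter than k and contribute zero windows")
  res <- kmer_histogram_cpp(seqs, k)
  h <- kmer_histogram(k, res$multiplicity, res$count)
  attr(h, "n_windows") <- res$n_windows
  attr(h, "n_skipped") <- res$n_skipped
  h
}

# Dense count vector over multiplicities 1..max(h$multiplicity).
dense_counts <- function(h) {
  d <- numeric(max(h$multiplicity))
  d[h$multiplicity] <- h$count
  d
}

#' Error-multiplicity cutoff for a k-mer spectrum
#'
#' Sequencing errors produce a spike of low-multiplicity k-mers to the left
#' of the coverage peak. The cutoff is the smallest multiplicity i >= 2 with
#' h_i <= h_{i+1} (the first local minimum) occurring before the global
#' maximum of the spectrum; if no such valley exists, 1 is returned with a
#' warning and no mass is excluded.
#'
#' @param h A [kmer_histogram()].
#' @return Integer cutoff c0 (smallest retained multiplicity).
#' @examples
#' h <- kmer_histogram(21, 1:7, c(100, 10, 1, 5, 20, 30, 20))
#' error_cutoff(h)  # 3
#' @export
error_cutoff <- function(h) {
  stopifnot(inherits(h, "kmer_histogram"))
  if (length(h$multiplicity) == 0) stop("empty histogram")
  d <- dense_counts(h)
  len <- length(d)
  if (len >= 3) {
    for (i in 2:(len - 1)) {
      # first valley, provided a genuine coverage peak rises beyond it
      if (d[i] <= d[i + 1] && max(d[(i + 1):len]) > d[i]) return(i)
    }
  }
  warning("no local minimum before the spectrum maximum; cutoff set to 1 ",
          "(error and genomic k-mers not separable)")
  1L
}

#' Locate the coverage peak of a k-mer spectrum
#'
#' The peak multiplicity lambda is the modal multiplicity at or above the
#' error cutoff (ties broken toward the smaller multiplicity); it estimates
#' the k-mer-level sequencing depth. Two refinements are reported alongside:
#'
#' * `lambda_refined`: the mass centroid of the spectrum within ±25% of the
#'   mode — a sub-bin peak position that removes the integer-granularity
#'   error of the mode (e.g. the tied 23/24 modes of a Poisson spectrum at
#'   depth 24).
#' * `secondary_peak`: a second local maximum near twice or half the primary
#'   peak (searched within ±20% of 2*lambda and of lambda/2), the signature
#'   of a heterozygous diploid spectrum. With
#'   `ploidy_peak = "homozygous"` the larger-multiplicity peak of such a
#'   pair is used as the working peak, attributing the lower peak to
#'   heterozygous k-mers.
#'
#' @param h A [kmer_histogram()].
#' @param cutoff Error cutoff c0 (default: [error_cutoff()]).
#' @param ploidy_peak `"primary"` (use the global mode) or `"homozygous"`
#'   (prefer the larger-multiplicity peak of a detected pair).
#' @return An object of class `kmer_peak`: list with `lambda`,
#'   `secondary_peak` (NA if none), `lambda_used`, `lambda_refined`.
#' @export
find_peak <- function(h, cutoff = NULL,
                      ploidy_peak = c("primary", "homozygous")) {
  stopifnot(inherits(h, "kmer_histogram"))
  ploidy_peak <- match.arg(ploidy_peak)
  if (is.null(cutoff)) cutoff <- suppressWarnings(error_cutoff(h))
  d <- dense_counts(h)
  if (cutoff > length(d) || all(d[cutoff:length(d)] == 0))
    stop("empty retained spectrum at cutoff ", cutoff)
  dr <- d
  if (cutoff > 1) dr[1:(cutoff - 1)] <- 0
  lambda <- which.max(dr)  # which.max ties -> smallest index

  secondary <- find_secondary(dr, lambda)
  lambda_used <- lambda
  if (ploidy_peak == "homozygous" && !is.na(secondary))
    lambda_used <- max(lambda, secondary)

  structure(list(lambda = lambda, secondary_peak = secondary,
                 lambda_used = lambda_used,
                 lambda_refined = refine_peak(d, lambda_used, cutoff),
                 cutoff = cutoff, ploidy_peak = ploidy_peak),
            class = "kmer_peak")
}

# Local maximum search near 2*lambda and lambda/2; a candidate must be a
# genuine local max separated from lambda by a dip (>= 5% prominence).
find_secondary <- function(d, lambda) {
  windows <- list(c(round(1.6 * lambda), round(2.4 * lambda)),
                  c(round(0.4 * lambda), round(0.6 * lambda)))
  best <- NA_integer_; best_h <- 0
  for (wdw in windows) {
    lo <- max(2, wdw[1]); hi <- min(length(d), wdw[2])
    if (lo > hi) next
    j <- (lo:hi)[which.max(d[lo:hi])]
    if (abs(j - lambda) <= 1) next
    left <- if (j > 1) d[j - 1] else 0
    right <- if (j < length(d)) d[j + 1] else 0
    if (d[j] < left || d[j] < right || d[j] == 0) next
    valley <- min(d[min(j, lambda):max(j, lambda)])
    if (d[j] < 1.05 * valley) next
    if (d[j] > best_h) { best <- j; best_h <- d[j] }
  }
  best
}

# Sub-bin peak position. For a Poisson-shaped peak at depth lambda the
# identity lambda = (i + 1) * h_{i+1} / h_i holds at every multiplicity, so
# a count-weighted average of these ratios over bins adjacent to the mode
# estimates the continuous peak position without the integer-granularity
# error of the mode (a spectrum at depth 24.0 has tied modes 23/24). The
# result is clamped to mode ± 1, where the true peak of a unimodal spectrum
# must lie.
refine_peak <- function(d, lambda, cutoff) {
  lo <- max(cutoff, lambda - 2L, 1L)
  hi <- min(length(d) - 1L, lambda + 2L)
  if (lo > hi) return(as.numeric(lambda))
  i <- lo:hi
  ok <- d[i] > 0 & d[i + 1] > 0
  if (!any(ok)) return(as.numeric(lambda))
  i <- i[ok]
  est <- (i + 1) * d[i + 1] / d[i]
  lam <- sum(d[i] * est) / sum(d[i])
  min(max(lam, lambda - 1), lambda + 1)
}

#' @export
print.kmer_peak <- function(x, ...) {
  cat(sprintf("<kmer_peak> lambda = %d (refined %.2f), cutoff = %d",
              x$lambda, x$lambda_refined, x$cutoff))
  if (!is.na(x$secondary_peak))
    cat(sprintf(", secondary peak at %d", x$secondary_peak))
  cat("\n")
  invisible(x)
}

#' k-mer spectrum genome size estimate
#'
#' The classic estimator: haploid genome size is the retained k-mer mass
#' divided by the coverage-peak depth, G = (sum over i >= c0 of i * h_i) /
#' lambda. By default the sub-bin refined peak position is used as the
#' divisor (see [find_peak()]); `refine = FALSE` divides by the integer
#' modal multiplicity instead. When the read length is known the peak is
#' also converted to base-level coverage C_b = lambda * L / (L - k + 1).
#'
#' @param h A [kmer_histogram()].
#' @param cutoff Error cutoff (default: [error_cutoff()]).
#' @param peak A `kmer_peak`, a numeric peak multiplicity, or `NULL` to
#'   detect via [find_peak()].
#' @param read_length Mean read length L, for base-coverage conversion.
#' @param refine Use the sub-bin refined peak as divisor? (default TRUE)
#' @inheritParams find_peak
#' @return A `genome_size_estimate` (method `"kmer"`) whose `params` record
#'   k, cutoff, peak, refined peak, secondary peak and retained mass.
#' @examples
#' h <- kmer_histogram(21, 20, 500)
#' kmer_genome_size(h, cutoff = 1)$genome_size  # 10000 / 20 = 500
#' @export
kmer_genome_size <- function(h, cutoff = NULL, peak = NULL, read_length = NULL,
                             refine = TRUE,
                             ploidy_peak = c("primary", "homozygous")) {
  stopifnot(inherits(h, "kmer_histogram"))
  ploidy_peak <- match.arg(ploidy_peak)
  if (is.null(cutoff)) cutoff <- error_cutoff(h)
  cutoff <- as.integer(cutoff)
  if (cutoff < 1) stop("cutoff must be >= 1")
  if (is.numeric(peak)) {
    peak <- structure(list(lambda = as.integer(peak), secondary_peak = NA,
                           lambda_used = as.integer(peak),
                           lambda_refined = as.numeric(peak),
                           cutoff = cutoff, ploidy_peak = ploidy_peak),
                      class = "kmer_peak")
  } else if (is.null(peak)) {
    peak <- find_peak(h, cutoff = cutoff, ploidy_peak = ploidy_peak)
  }
  stopifnot(inherits(peak, "kmer_peak"))
  if (peak$lambda_used == 0) stop("zero peak multiplicity")
  if (cutoff > peak$lambda_used)
    stop("cutoff exceeds the peak multiplicity (1 <= c0 <= lambda required)")
  keep <- h$multiplicity >= cutoff
  t_r <- sum(as.numeric(h$multiplicity[keep]) * h$count[keep])
  if (t_r <= 0) stop("no retained k-mer mass at cutoff ", cutoff)
  divisor <- if (refine) peak$lambda_refined else peak$lambda_used
  base_cov <- if (!is.null(read_length)) {
    peak$lambda_used * read_length / (read_length - h$k + 1)
  } else NA_real_
  genome_size_estimate(
    method = "kmer", genome_size = t_r / divisor, coverage = base_cov,
    params = list(k = h$k, cutoff = cutoff, peak = peak$lambda,
                  peak_used = peak$lambda_used,
                  peak_refined = peak$lambda_refined,
                  secondary_peak = peak$secondary_peak,
                  retained_mass = t_r, refine = refine,
                  ploidy_peak = ploidy_peak, read_length = read_length))
}

#' Genome size estimates across a range of k
#'
#' Runs [count_kmers()] and [kmer_genome_size()] once per k; a failure at one
#' k is recorded in the table without aborting the sweep. Duplicate k values
#' are deduplicated with a warning.
#'
#' @inheritParams count_kmers
#' @param ks Odd k values (default `seq(13, 31, by = 2)`).
#' @param ... Passed to [kmer_genome_size()].
#' @return Data frame with one row per k: `k`, `cutoff`, `peak`,
#'   `peak_refined`, `secondary_peak`, `retained_mass`, `genome_size`,
#'   `error` (NA on success).
#' @export
k_sweep <- function(reads, ks = seq(13, 31, by = 2), ...) {
  if (anyDuplicated(ks)) {
    warning("duplicate k values removed from sweep")
    ks <- unique(ks)
  }
  seqs <- tryCatch(as_sequences(reads, format = "fastq"),
                   error = function(e) character(0))
  rows <- lapply(ks, function(k) {
    est <- tryCatch({
      h <- count_kmers(seqs, k = k)
      kmer_genome_size(h, ...)
    }, error = function(e) e)
    if (inherits(est, "error")) {
      data.frame(k = k, cutoff = NA_integer_, peak = NA_integer_,
                 peak_refined = NA_real_, secondary_peak = NA_integer_,
                 retained_mass = NA_real_, genome_size = NA_real_,
                 error = conditionMessage(est), stringsAsFactors = FALSE)
    } else {
      p <- est$params
      data.frame(k = k, cutoff = p$cutoff, peak = p$peak,
                 peak_refined = p$peak_refined,
                 secondary_peak = as.integer(p$secondary_peak),
                 retained_mass = p$retained_mass,
                 genome_size = est$genome_size,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
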