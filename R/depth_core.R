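# Read-depth genome size estimation over single-copy loci: flank trimming,
# 3xIQR locus filtering, mean coverage, Lander-Waterman conversion.

#' Trim flanking positions from a coverage profile
#'
#' Read mappers that require a minimum overlap between read and reference
#' depress coverage at locus ends; excluding a fixed number of terminal
#' positions removes that ramp. Returns `NULL` when the profile is too short
#' to trim (length <= 2 * trim_bases); callers treat that locus as rejected
#' rather than failing.
#'
#' @param profile Numeric vector of per-base depths.
#' @param trim_bases Number of positions to drop from each end (default 75,
#'   matching the observed width of mapper flank ramps for ~100-150 b reads).
#' @return The central `length(profile) - 2 * trim_bases` positions, or
#'   `NULL` if the profile is untrimmable.
#' @examples
#' trim_flanks(rep(10, 300), 75)   # 150 central positions
#' trim_flanks(rep(10, 150), 75)   # NULL: too short
#' @export
trim_flanks <- function(profile, trim_bases = 75) {
  stopifnot(is.numeric(profile), trim_bases >= 0)
  n <- length(profile)
  if (n <= 2 * trim_bases) return(NULL)
  if (trim_bases == 0) return(profile)
  profile[(trim_bases + 1):(n - trim_bases)]
}

#' Interquartile-range outlier filter
#'
#' Keeps indices whose value lies within `multiplier` interquartile ranges of
#' the median: |x - median| <= multiplier * (Q3 - Q1), with quartiles by
#' linear interpolation between order statistics ([stats::quantile()] type 7).
#' With fewer than 4 values quartiles are not meaningful and everything is
#' kept (with a warning). A degenerate all-equal input has IQR 0 and zero
#' deviations, so everything is kept. `multiplier = Inf` disables the filter.
#'
#' @param values Numeric vector.
#' @param multiplier Positive IQR multiplier (default 3).
#' @return Integer vector of kept indices.
#' @examples
#' iqr_filter(c(5, 5, 5, 5))            # all kept
#' iqr_filter(c(1:10, 1000))            # drops the outlier
#' @export
iqr_filter <- function(values, multiplier = 3) {
  stopifnot(is.numeric(values), multiplier > 0)
  if (length(values) < 4) {
    warning("fewer than 4 values: quartiles not meaningful, keeping all")
    return(seq_along(values))
  }
  if (!is.finite(multiplier)) return(seq_along(values))
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  med <- median(values)
  which(abs(values - med) <= multiplier * (q[2] - q[1]))
}

#' Estimate mean genome coverage from single-copy locus depth profiles
#'
#' Pipeline: (1) trim every locus with [trim_flanks()], rejecting loci too
#' short to trim; (2) compute per-locus trimmed mean coverages and trimmed
#' lengths; (3) apply [iqr_filter()] independently to the coverage vector and
#' the length vector, rejecting loci failing either (a locus failing both is
#' reported once as a coverage outlier); (4) average the kept loci:
#' `locus_mean` takes the unweighted mean of per-locus means, `pooled` takes
#' total kept depth over total kept bases (length-weighted).
#'
#' @param cov A [coverage_set()].
#' @param trim_bases Flank trim per end (default 75).
#' @param iqr_multiplier IQR multiplier for the outlier filter (default 3;
#'   `Inf` disables filtering).
#' @param averaging `"locus_mean"` (default) or `"pooled"`.
#' @return An object of class `coverage_summary`: list with `loci` (a data
#'   frame of locus_id, raw_length, trimmed_length, trimmed_mean_coverage,
#'   kept, rejection_reason), `mean_coverage`, `n_kept` and the parameters.
#' @examples
#' cov <- coverage_set(list(a = rep(10L, 300), b = rep(20L, 300)))
#' estimate_coverage(cov, trim_bases = 75)$mean_coverage  # 15
#' @export
estimate_coverage <- function(cov, trim_bases = 75, iqr_multiplier = 3,
                              averaging = c("locus_mean", "pooled")) {
  stopifnot(inherits(cov, "coverage_set"))
  averaging <- match.arg(averaging)
  ids <- names(cov)
  raw_len <- lengths(cov)
  trimmed <- lapply(cov, trim_flanks, trim_bases = trim_bases)
  trimmable <- !vapply(trimmed, is.null, logical(1))
  tlen <- ifelse(trimmable, lengths(trimmed), NA_integer_)
  tmean <- rep(NA_real_, length(cov))
  tmean[trimmable] <- vapply(trimmed[trimmable], mean, numeric(1))

  reason <- rep("none", length(cov))
  reason[!trimmable] <- "too_short"
  cand <- which(trimmable)
  if (length(cand) > 0) {
    keep_cov <- cand[iqr_filter(tmean[cand], iqr_multiplier)]
    keep_len <- cand[iqr_filter(tlen[cand], iqr_multiplier)]
    reason[setdiff(cand, keep_len)] <- "length_outlier"
    reason[setdiff(cand, keep_cov)] <- "coverage_outlier"  # priority cov > len
    kept <- intersect(keep_cov, keep_len)
  } else {
    kept <- integer(0)
  }

  loci <- data.frame(locus_id = ids, raw_length = as.integer(raw_len),
                     trimmed_length = as.integer(tlen),
                     trimmed_mean_coverage = tmean,
                     kept = seq_along(cov) %in% kept,
                     rejection_reason = reason,
                     stringsAsFactors = FALSE, row.names = NULL)
  if (length(kept) == 0) {
    tab <- table(reason)
    stop("no loci kept: ",
         paste(sprintf("%s=%d", names(tab), as.integer(tab)),
               collapse = ", "))
  }
  C <- if (averaging == "locus_mean") {
    mean(tmean[kept])
  } else {
    sum(vapply(trimmed[kept], function(v) sum(as.numeric(v)), numeric(1))) /
      sum(as.numeric(tlen[kept]))
  }
  structure(list(loci = loci, mean_coverage = C, n_kept = length(kept),
                 params = list(trim_bases = trim_bases,
                               iqr_multiplier = iqr_multiplier,
                               averaging = averaging)),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  tab <- table(x$loci$rejection_reason[!x$loci$kept])
  cat(sprintf("<coverage_summary> C = %.3fx from %d/%d loci",
              x$mean_coverage, x$n_kept, nrow(x$loci)))
  if (length(tab) > 0)
    cat(" (rejected: ",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        ")", sep = "")
  cat(sprintf("\n  trim_bases = %d, iqr_multiplier = %s, averaging = %s\n",
              x$params$trim_bases, format(x$params$iqr_multiplier),
              x$params$averaging))
  invisible(x)
}

#' Lander-Waterman genome size
#'
#' Converts mean coverage to haploid genome size via G = LN/C, implemented on
#' total bases as G = B/C (identical for uniform read length, and exact for
#' variable-length libraries). With `exclude_mito = TRUE` the mitochondrial
#' bases recorded in `stats` are subtracted from B first.
#'
#' @param stats A [library_stats()].
#' @param coverage Mean genome coverage C (> 0), e.g. from
#'   [estimate_coverage()].
#' @param exclude_mito Subtract recorded mitochondrial bases from B?
#' @return An object of class `genome_size_estimate` with fields `method`
#'   (`"read_depth"`), `genome_size` (bases), `coverage`, `library`, `params`.
#' @examples
#' lander_waterman(library_stats(100, 10000), coverage = 1)$genome_size
#' @export
lander_waterman <- function(stats, coverage, exclude_mito = FALSE) {
  stopifnot(inherits(stats, "library_stats"))
  if (inherits(coverage, "coverage_summary")) coverage <- coverage$mean_coverage
  if (!is.numeric(coverage) || length(coverage) != 1 || coverage <= 0)
    stop("coverage must be a single positive number")
  b_eff <- stats$total_bases - if (exclude_mito) stats$mito_bases else 0
  if (b_eff <= 0) stop("effective base count is non-positive")
  genome_size_estimate(method = "read_depth", genome_size = b_eff / coverage,
                       coverage = coverage, library = stats,
                       params = list(exclude_mito = exclude_mito,
                                     effective_bases = b_eff))
}

# Shared container for both estimators.
genome_size_estimate <- function(method, genome_size, coverage, library = NULL,
                                 params = list()) {
  stopifnot(method %in% c("read_depth", "kmer"), genome_size > 0)
  structure(list(method = method, genome_size = genome_size,
                 coverage = coverage, library = library, params = params),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("<genome_size_estimate> method = %s\n  G = %s bases (%.1f Mb)",
              x$method, format(round(x$genome_size), big.mark = ","),
              x$genome_size / 1e6))
  if (!is.null(x$coverage) && is.finite(x$coverage))
    cat(sprintf(", C = %.2fx", x$coverage))
  cat("\n")
  invisible(x)
}

#' Alignment-free mitochondrial read screen
#'
#' Flags a read as mitochondrial iff it shares at least `min_shared` canonical
#' k-mer windows with the mitochondrial reference. The default threshold is
#' 35% of the read's k-mer windows, chosen to approximate the behaviour of a
#' 70%-identity mapping contract without shipping an aligner; it is a
#' documented approximation, not a reproduction of any specific mapper.
#'
#' @param reads FASTQ path(s), a `DNAStringSet`, or a character vector of
#'   read sequences.
#' @param mito_ref Mitochondrial reference: FASTA path, `DNAStringSet`, or
#'   character vector.
#' @param k Odd k-mer length (default 21).
#' @param min_shared_frac Fraction of a read's k-mer windows that must match
#'   (default 0.35); ignored when `min_shared` is given.
#' @param min_shared Absolute window-count threshold (optional override).
#' @return List with `kept` (non-mito read sequences), `flagged` (logical per
#'   read), and `stats` (a [library_stats()] with mito fields set).
#' @export
mito_screen <- function(reads, mito_ref, k = 21, min_shared_frac = 0.35,
                        min_shared = NULL) {
  if (k %% 2 == 0) stop("k must be odd")
  reads <- as_sequences(reads, format = "fastq")
  ref <- as_sequences(mito_ref, format = "fasta")
  if (length(ref) == 0 || sum(nchar(ref)) == 0)
    stop("mito_ref must be non-empty")
  w <- pmax(0L, nchar(reads) - k + 1L)
  shared <- shared_kmer_counts_cpp(reads, ref, as.integer(k))
  thr <- if (is.null(min_shared)) ceiling(min_shared_frac * w) else min_shared
  flagged <- w > 0 & shared >= pmax(1, thr)
  stats <- library_stats(n_reads = length(reads),
                         total_bases = sum(as.numeric(nchar(reads))),
                         n_mito_reads = sum(flagged),
                         mito_bases = sum(as.numeric(nchar(reads)[flagged])))
  list(kept = reads[!flagged], flagged = flagged, stats = stats)
}

# Normalize read/reference inputs to a plain character vector of sequences.
as_sequences <- function(x, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (is.character(x) && length(x) > 0 && all(file.exists(x))) {
    seqs <- unlist(lapply(x, function(p) {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", p)) "fastq"
             else if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", p)) "fasta"
             else format
      as.character(Biostrings::readDNAStringSet(p, format = fmt))
    }))
    return(unname(seqs))
  }
  if (is.character(x)) return(unname(x))
  stop("cannot interpret input as sequences")
}
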