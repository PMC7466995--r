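# Readers/writers for the plain-text formats the toolkit touches, and the
# domain containers they normalize into. Internal coordinates are 0-based,
# half-open everywhere; 1-based dialects are converted on ingestion.

#' Per-locus coverage container
#'
#' A `coverage_set` is an ordered, named list of non-negative integer vectors,
#' one per locus, holding read depth at each base (0-based internally).
#'
#' @param loci Named list of non-negative integer vectors, one per locus.
#' @return An object of class `coverage_set`.
#' @examples
#' cov <- coverage_set(list(locA = c(5L, 5L, 5L), locB = c(2L, 3L)))
#' lengths(cov)
#' @export
coverage_set <- function(loci) {
  if (!is.list(loci) || length(loci) == 0)
    stop("'loci' must be a non-empty named list of depth vectors")
  nm <- names(loci)
  if (is.null(nm) || any(!nzchar(nm))) stop("every locus must be named")
  if (anyDuplicated(nm)) stop("locus ids must be unique")
  loci <- lapply(loci, function(x) {
    x <- as.integer(x)
    if (length(x) == 0) stop("depth arrays must be non-empty")
    if (anyNA(x) || any(x < 0)) stop("depth values must be non-negative")
    x
  })
  structure(loci, class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat(sprintf("<coverage_set> %d loci, %d bases total\n",
              length(x), sum(lengths(x))))
  invisible(x)
}

#' Library-level read statistics
#'
#' Holds the read count N, total sequenced bases B and mean read length
#' L = B/N that enter the Lander-Waterman equation, with optional
#' mitochondrial-read accounting for "no mito" estimates.
#'
#' @param n_reads Number of reads N.
#' @param total_bases Total sequenced bases B.
#' @param n_mito_reads,mito_bases Reads/bases attributed to the
#'   mitochondrial genome (default 0).
#' @return An object of class `library_stats` with fields `n_reads`,
#'   `total_bases`, `mean_read_length`, `n_mito_reads`, `mito_bases`.
#' @examples
#' library_stats(4, 400)
#' @export
library_stats <- function(n_reads, total_bases, n_mito_reads = 0,
                          mito_bases = 0) {
  n_reads <- as.numeric(n_reads); total_bases <- as.numeric(total_bases)
  if (n_reads < 1) stop("n_reads must be >= 1")
  if (total_bases < n_reads)
    stop("total_bases must be >= n_reads (reads have length >= 1)")
  if (n_mito_reads > n_reads) stop("n_mito_reads must be <= n_reads")
  if (mito_bases > total_bases) stop("mito_bases must be <= total_bases")
  structure(list(n_reads = n_reads, total_bases = total_bases,
                 mean_read_length = total_bases / n_reads,
                 n_mito_reads = as.numeric(n_mito_reads),
                 mito_bases = as.numeric(mito_bases)),
            class = "library_stats")
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("<library_stats> N = %s reads, B = %s bases, L = %.2f",
              format(x$n_reads, big.mark = ",", scientific = FALSE),
              format(x$total_bases, big.mark = ",", scientific = FALSE),
              x$mean_read_length))
  if (x$n_mito_reads > 0)
    cat(sprintf(" (mito: %s reads, %s bases)",
                format(x$n_mito_reads, big.mark = ",", scientific = FALSE),
                format(x$mito_bases, big.mark = ",", scientific = FALSE)))
  cat("\n")
  invisible(x)
}

#' k-mer multiplicity histogram
#'
#' Counts `count[j]` of distinct canonical k-mers occurring exactly
#' `multiplicity[j]` times in a read set (Jellyfish "histo" semantics).
#'
#' @param k Odd k-mer length, >= 3.
#' @param multiplicity Strictly positive integer multiplicities (unique).
#' @param count Number of distinct k-mers at each multiplicity (>= 0).
#' @return An object of class `kmer_histogram`.
#' @examples
#' h <- kmer_histogram(21, c(1, 2, 20), c(100, 10, 500))
#' kmer_mass(h)
#' @export
kmer_histogram <- function(k, multiplicity, count) {
  k <- as.integer(k)
  if (is.na(k) || k < 3 || k %% 2 == 0) stop("k must be an odd integer >= 3")
  multiplicity <- as.integer(multiplicity)
  count <- as.numeric(count)
  if (length(multiplicity) != length(count))
    stop("multiplicity and count must have equal length")
  if (anyNA(multiplicity) || any(multiplicity < 1))
    stop("multiplicities must be strictly positive integers")
  if (anyDuplicated(multiplicity)) stop("duplicate multiplicity rows")
  if (anyNA(count) || any(count < 0)) stop("counts must be non-negative")
  o <- order(multiplicity)
  structure(list(k = k, multiplicity = multiplicity[o], count = count[o]),
            class = "kmer_histogram")
}

#' @rdname kmer_histogram
#' @param h A `kmer_histogram`.
#' @return `kmer_mass()`: the total k-mer mass T = sum(i * h_i), i.e. the
#'   number of k-mer tokens ingested.
#' @export
kmer_mass <- function(h) {
  stopifnot(inherits(h, "kmer_histogram"))
  sum(as.numeric(h$multiplicity) * h$count)
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("<kmer_histogram> k = %d, %d multiplicity bins, mass = %s\n",
              x$k, length(x$multiplicity),
              format(kmer_mass(x), big.mark = ",")))
  invisible(x)
}

# ---- per-base coverage dialects ---------------------------------------------

#' Read a per-base coverage file into a coverage set
#'
#' Supports the BBMap `basecov` dialect (tab-separated ref / 0-based position
#' / depth, optional leading `#` header) and the `samtools depth` dialect
#' (ref / 1-based position / depth; rows with zero depth may be omitted).
#' Positions absent from the file within a locus are filled with depth 0;
#' loci are ordered by first appearance.
#'
#' @param path Path to the coverage file.
#' @param dialect `"bbmap"` or `"samtools"`.
#' @param loci Optional reference locus lengths: a named numeric vector or a
#'   BED-style data frame (columns `name`, `start`, `end`). When supplied the
#'   declared length wins and trailing zero-depth positions are padded.
#' @return A [coverage_set()].
#' @examples
#' p <- tempfile()
#' writeLines(c("locA\t0\t5", "locA\t1\t5", "locA\t2\t5"), p)
#' read_basecov(p, "bbmap")
#' @export
read_basecov <- function(path, dialect = c("bbmap", "samtools"), loci = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0) stop("no coverage records in ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0)
    stop(sprintf("malformed line %d in %s: expected 3 fields",
                 lineno[bad[1]], path))
  flat <- unlist(parts, use.names = FALSE)
  ref <- flat[c(TRUE, FALSE, FALSE)]
  pos <- suppressWarnings(as.integer(flat[c(FALSE, TRUE, FALSE)]))
  dep <- suppressWarnings(as.integer(flat[c(FALSE, FALSE, TRUE)]))
  bad <- which(is.na(pos) | is.na(dep))
  if (length(bad) > 0)
    stop(sprintf("malformed line %d in %s: non-numeric position or depth",
                 lineno[bad[1]], path))
  if (dialect == "samtools") pos <- pos - 1L
  if (any(pos < 0))
    stop(sprintf("malformed line %d in %s: position out of range",
                 lineno[which(pos < 0)[1]], path))
  if (any(dep < 0))
    stop(sprintf("malformed line %d in %s: negative depth",
                 lineno[which(dep < 0)[1]], path))

  declared <- locus_lengths(loci)
  ids <- unique(ref)
  out <- vector("list", length(ids)); names(out) <- ids
  idx <- split(seq_along(ref), factor(ref, levels = ids))
  for (id in ids) {
    i <- idx[[id]]
    p <- pos[i]; d <- dep[i]
    if (any(diff(p) <= 0))
      stop(sprintf("non-monotone positions within locus '%s' (line %d)",
                   id, lineno[i[which(diff(p) <= 0)[1] + 1L]]))
    len <- max(p) + 1L
    if (!is.null(declared) && id %in% names(declared)) {
      dl <- declared[[id]]
      if (dl < len)
        stop(sprintf("locus '%s': declared length %d < observed %d",
                     id, dl, len))
      len <- as.integer(dl)
    }
    v <- integer(len)
    v[p + 1L] <- d
    out[[id]] <- v
  }
  coverage_set(out)
}

locus_lengths <- function(loci) {
  if (is.null(loci)) return(NULL)
  if (is.data.frame(loci)) {
    stopifnot(all(c("name", "start", "end") %in% names(loci)))
    setNames(as.numeric(loci$end - loci$start), loci$name)
  } else {
    stopifnot(is.numeric(loci), !is.null(names(loci)))
    loci
  }
}

#' Write a coverage set as a per-base coverage file
#'
#' The BBMap dialect writes 0-based positions with a `#RefName Pos Coverage`
#' header; the samtools dialect writes 1-based positions. Both write every
#' position (including zero-depth rows, as `samtools depth -a` does) so that
#' write-then-read round-trips are lossless.
#'
#' @param cov A [coverage_set()].
#' @inheritParams read_basecov
#' @return `path`, invisibly.
#' @export
write_basecov <- function(cov, path, dialect = c("bbmap", "samtools")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(cov, "coverage_set"))
  off <- if (dialect == "samtools") 1L else 0L
  ref <- rep(names(cov), lengths(cov))
  pos <- unlist(lapply(cov, function(v) seq_along(v) - 1L + off),
                use.names = FALSE)
  dep <- unlist(cov, use.names = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  if (dialect == "bbmap") writeLines("#RefName\tPos\tCoverage", con)
  writeLines(paste(ref, pos, dep, sep = "\t"), con)
  invisible(path)
}

# ---- FASTQ scanning ---------------------------------------------------------

#' Scan FASTQ files for library statistics
#'
#' Counts reads and sequenced bases across one or more FASTQ files (plain or
#' gzip), yielding the N, B and L = B/N of the Lander-Waterman equation.
#' Records must be in the standard 4-line form (no line wrapping); structural
#' problems are reported with the file and record index. Invariant under
#' file and read order.
#'
#' @param paths Character vector of FASTQ file paths.
#' @return A [library_stats()].
#' @export
scan_reads <- function(paths) {
  stopifnot(length(paths) >= 1)
  n <- 0; b <- 0
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p)
    con <- if (grepl("\\.gz$", p)) gzfile(p, "rt") else file(p, "rt")
    lines <- tryCatch(readLines(con),
                      finally = try(close(con), silent = TRUE))
    if (length(lines) == 0) stop("empty FASTQ file: ", p)
    if (length(lines) %% 4 != 0)
      stop(sprintf("truncated FASTQ record %d in %s",
                   length(lines) %/% 4 + 1, p))
    hdr <- lines[seq(1, length(lines), by = 4)]
    bad <- which(!startsWith(hdr, "@"))
    if (length(bad) > 0)
      stop(sprintf("malformed FASTQ record %d in %s: header does not start ",
                   bad[1], p), "with '@'")
    plus <- lines[seq(3, length(lines), by = 4)]
    bad <- which(!startsWith(plus, "+"))
    if (length(bad) > 0)
      stop(sprintf("malformed FASTQ record %d in %s: missing '+' separator",
                   bad[1], p))
    seqs <- lines[seq(2, length(lines), by = 4)]
    n <- n + length(seqs)
    b <- b + sum(as.numeric(nchar(seqs)))
  }
  library_stats(n_reads = n, total_bases = b)
}

# ---- k-mer histogram files --------------------------------------------------

#' Read / write Jellyfish-compatible k-mer histograms
#'
#' The on-disk format is two whitespace-separated numeric columns per line
#' (multiplicity, count). `write_histogram()` stores k in a `# k=<k>` comment
#' header; `read_histogram()` recovers it from such a header, or requires it
#' from the caller if absent.
#'
#' @param path File path.
#' @param k k-mer length; required when the file carries no `# k=` header.
#' @return `read_histogram()`: a [kmer_histogram()].
#' @examples
#' h <- kmer_histogram(21, c(1, 2, 20), c(100, 10, 500))
#' p <- tempfile()
#' write_histogram(h, p)
#' identical(read_histogram(p), h)
#' @export
read_histogram <- function(path, k = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  comments <- lines[startsWith(lines, "#")]
  m <- regmatches(comments, regexpr("k\\s*=\\s*[0-9]+", comments))
  if (length(m) > 0 && is.null(k))
    k <- as.integer(sub("k\\s*=\\s*", "", m[1]))
  if (is.null(k))
    stop("k not recorded in the file header; supply it via the 'k' argument")
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no histogram rows in ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(parts) != 2L))
    stop("malformed histogram line ", which(lengths(parts) != 2L)[1],
         ": expected 2 columns")
  flat <- unlist(parts, use.names = FALSE)
  mult <- as.numeric(flat[c(TRUE, FALSE)])
  cnt <- as.numeric(flat[c(FALSE, TRUE)])
  if (anyNA(mult) || anyNA(cnt)) stop("non-numeric histogram entry in ", path)
  if (anyDuplicated(mult)) stop("duplicate multiplicity rows in ", path)
  kmer_histogram(k, mult, cnt)
}

#' @rdname read_histogram
#' @param h A [kmer_histogram()].
#' @export
write_histogram <- function(h, path) {
  stopifnot(inherits(h, "kmer_histogram"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# k=%d", h$k), con)
  writeLines(paste(h$multiplicity, format(h$count, scientific = FALSE,
                                          trim = TRUE)), con)
  invisible(path)
}

# ---- BED --------------------------------------------------------------------

#' Read / write locus definitions in BED3(+name) format
#'
#' @param path File path.
#' @return `read_bed()`: a data frame with columns `chrom`, `start`, `end`,
#'   `name` (0-based, half-open coordinates).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name")[1:4],
                   fill = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file must have at least 3 columns")
  if (!"name" %in% names(df) || all(is.na(df$name)) || all(df$name == ""))
    df$name <- sprintf("locus_%04d", seq_len(nrow(df)))
  if (any(df$end <= df$start)) stop("BED intervals must satisfy end > start")
  df[, c("chrom", "start", "end", "name")]
}

#' @rdname read_bed
#' @param bed Data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
write_bed <- function(bed, path) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(bed)))
  write.table(bed[, c("chrom", "start", "end", "name")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
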