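# Independent brute-force reference implementations used as oracles.
# Deliberately naive (loops, string manipulation) and written without
# reference to the package internals they check.

ref_trim <- function(profile, t) {
  n <- length(profile)
  if (n <= 2 * t) return(NULL)
  out <- profile[0]
  for (i in seq_len(n)) if (i > t && i <= n - t) out <- c(out, profile[i])
  out
}

# Linear-interpolation quantile written from the textbook definition
# (h = (n-1)p + 1 between order statistics).
ref_quantile_lin <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

ref_iqr_keep <- function(v, m) {
  if (length(v) < 4 || !is.finite(m)) return(seq_along(v))
  med <- ref_quantile_lin(v, 0.5)
  iqr <- ref_quantile_lin(v, 0.75) - ref_quantile_lin(v, 0.25)
  keep <- integer(0)
  for (i in seq_along(v))
    if (abs(v[i] - med) <= m * iqr) keep <- c(keep, i)
  keep
}

ref_estimate_coverage <- function(cov, t, m, averaging = "locus_mean") {
  trimmed <- lapply(cov, ref_trim, t = t)
  cand <- which(!vapply(trimmed, is.null, logical(1)))
  means <- vapply(trimmed[cand], function(v) sum(v) / length(v), numeric(1))
  lens <- vapply(trimmed[cand], length, numeric(1))
  keep <- intersect(cand[suppressWarnings(ref_iqr_keep(means, m))],
                    cand[suppressWarnings(ref_iqr_keep(lens, m))])
  kept_trim <- trimmed[keep]
  if (averaging == "locus_mean") {
    mean(vapply(kept_trim, function(v) sum(v) / length(v), numeric(1)))
  } else {
    sum(unlist(kept_trim)) / sum(lengths(kept_trim))
  }
}

ref_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

# Canonical k-mer histogram by plain enumeration (tiny inputs only).
ref_count_kmers <- function(seqs, k) {
  counts <- new.env(hash = TRUE)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in 1:(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGTacgt]", w)) next
      w <- toupper(w)
      rc <- ref_revcomp(w)
      key <- if (w <= rc) w else rc
      counts[[key]] <- get0(key, envir = counts, ifnotfound = 0) + 1
    }
  }
  mult <- unlist(as.list(counts), use.names = FALSE)
  if (length(mult) == 0) return(list(multiplicity = integer(0),
                                     count = numeric(0)))
  tab <- table(mult)
  list(multiplicity = as.integer(names(tab)), count = as.numeric(tab))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- random-instance generators --------------------------------------------

random_coverage_set <- function(n_loci = NULL) {
  n <- n_loci %||% sample(4:12, 1)
  loci <- lapply(seq_len(n), function(i) {
    len <- sample(20:400, 1)
    as.integer(rpois(len, sample(2:60, 1)))
  })
  names(loci) <- sprintf("L%03d", seq_len(n))
  coverage_set(loci)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal FASTQ writer for fixtures.
write_tiny_fastq <- function(seqs, path, ids = NULL) {
  ids <- ids %||% sprintf("r%04d", seq_along(seqs))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), path)
  path
}

# Integer depth profile whose flank-trimmed mean is ~mu: zero flanks of
# width t, interior of floor(mu) with the fractional remainder spread as +1s.
profile_with_trimmed_mean <- function(mu, raw_len = 450, t = 75) {
  interior <- raw_len - 2 * t
  base <- floor(mu)
  extra <- round((mu - base) * interior)
  c(rep(0L, t), rep(base + 1L, extra), rep(base, interior - extra),
    rep(0L, t))
}
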