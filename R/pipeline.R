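# Run orchestration: execute the requested estimators on simulated or
# on-disk inputs, produce a self-describing report, and juxtapose
# read-depth and k-mer estimates per library.

#' Run the requested genome size estimators
#'
#' `config` is a named list (or path to a JSON file of one) with:
#'
#' * `library_id` — label for the report (default `"library"`).
#' * `seed` — integer; flows into the simulator (default 1).
#' * either `simulate` — arguments for [sim_config()] — or `inputs` — a list
#'   with `basecov` (+ `dialect`), `reads` (FASTQ paths) and/or `histogram`
#'   (+ `k`).
#' * `estimators` — subset of `c("gsec", "kmer")` (default both).
#' * `gsec` — arguments for [estimate_coverage()] /
#'   [lander_waterman()] (`trim_bases`, `iqr_multiplier`, `averaging`,
#'   `exclude_mito`).
#' * `kmer` — arguments for the spectrum estimator (`k`, `cutoff`,
#'   `ploidy_peak`, `refine`).
#'
#' Estimator failures are caught and recorded per method; the report is
#' still produced. Every filter decision (locus rejections, cutoff, peak)
#' is reported via `message()`.
#'
#' @param config Named list or JSON file path.
#' @return An object of class `run_report`: list with `library_id`, `stats`,
#'   `gsec` (estimate + coverage summary), `kmer` (list of estimates, one
#'   per k), `truth` (simulation runs only), `errors`, `config`, `version`,
#'   `timestamp`. The `ok` field is `TRUE` iff all requested estimators
#'   succeeded.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  id <- config$library_id %||% "library"
  seed <- config$seed %||% 1L
  estimators <- config$estimators %||% c("gsec", "kmer")
  gsec_par <- utils::modifyList(
    list(trim_bases = 75, iqr_multiplier = 3, averaging = "locus_mean",
         exclude_mito = FALSE),
    as.list(config$gsec %||% list()))
  kmer_par <- utils::modifyList(
    list(k = 21, cutoff = NULL, ploidy_peak = "primary", refine = TRUE),
    as.list(config$kmer %||% list()))

  truth <- NULL
  if (!is.null(config$simulate)) {
    sc <- as.list(config$simulate)
    if (is.null(sc$seed)) sc$seed <- seed
    sim <- simulate_library(do.call(sim_config, sc))
    cov <- sim$coverage
    reads <- sim$reads$reads
    stats <- sim$stats
    truth <- sim$truth[c("genome_size", "depth", "read_length", "het_rate",
                         "error_rate", "mito_fraction", "n_mito_reads",
                         "seed")]
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    cov <- if (!is.null(inp$basecov))
      read_basecov(inp$basecov, dialect = inp$dialect %||% "bbmap") else NULL
    reads <- inp$reads
    stats <- if (!is.null(inp$reads)) scan_reads(inp$reads) else NULL
    if (!is.null(inp$histogram))
      kmer_par$histogram <- read_histogram(inp$histogram, k = inp$k)
  } else {
    stop("config must name either a 'simulate' block or an 'inputs' block")
  }

  errors <- list()
  gsec_out <- NULL
  if ("gsec" %in% estimators) {
    gsec_out <- tryCatch({
      if (is.null(cov)) stop("gsec requested but no coverage input")
      if (is.null(stats)) stop("gsec requested but no read statistics")
      summary <- estimate_coverage(cov, trim_bases = gsec_par$trim_bases,
                                   iqr_multiplier = gsec_par$iqr_multiplier,
                                   averaging = gsec_par$averaging)
      rej <- table(summary$loci$rejection_reason[!summary$loci$kept])
      message(sprintf("[gsec] %d/%d loci kept (%s); C = %.3f",
                      summary$n_kept, nrow(summary$loci),
                      if (length(rej)) paste(names(rej), as.integer(rej),
                                             sep = "=", collapse = ", ")
                      else "no rejections", summary$mean_coverage))
      est <- lander_waterman(stats, summary,
                             exclude_mito = isTRUE(gsec_par$exclude_mito))
      list(estimate = est, summary = summary)
    }, error = function(e) {
      errors$gsec <<- conditionMessage(e)
      NULL
    })
  }

  kmer_out <- NULL
  if ("kmer" %in% estimators) {
    kmer_out <- tryCatch({
      h <- if (!is.null(kmer_par$histogram)) kmer_par$histogram
           else {
             if (is.null(reads)) stop("kmer requested but no reads")
             count_kmers(reads, k = kmer_par$k)
           }
      c0 <- kmer_par$cutoff %||% error_cutoff(h)
      pk <- find_peak(h, cutoff = c0, ploidy_peak = kmer_par$ploidy_peak)
      message(sprintf(
        "[kmer] k = %d: cutoff = %d, peak = %d (refined %.2f)%s", h$k, c0,
        pk$lambda, pk$lambda_refined,
        if (!is.na(pk$secondary_peak))
          sprintf(", secondary peak = %d", pk$secondary_peak) else ""))
      L <- if (!is.null(stats)) stats$mean_read_length else NULL
      est <- kmer_genome_size(h, cutoff = c0, peak = pk, read_length = L,
                              refine = isTRUE(kmer_par$refine))
      stats::setNames(list(est), paste0("k", h$k))
    }, error = function(e) {
      errors$kmer <<- conditionMessage(e)
      NULL
    })
  }

  structure(list(library_id = id, stats = stats, gsec = gsec_out,
                 kmer = kmer_out, truth = truth, errors = errors,
                 config = config,
                 ok = length(errors) == 0,
                 version = as.character(packageVersion("covsize")),
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "run_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s (covsize %s)\n", x$library_id, x$version))
  if (!is.null(x$stats))
    cat(sprintf("  N = %s, B = %s, L = %.1f\n",
                format(x$stats$n_reads, big.mark = ",", scientific = FALSE),
                format(x$stats$total_bases, big.mark = ",",
                       scientific = FALSE),
                x$stats$mean_read_length))
  if (!is.null(x$gsec))
    cat(sprintf("  gsec: G = %.1f Mb (C = %.2fx, %d loci kept)\n",
                x$gsec$estimate$genome_size / 1e6,
                x$gsec$estimate$coverage, x$gsec$summary$n_kept))
  for (nm in names(x$kmer))
    cat(sprintf("  kmer %s: G = %.1f Mb (peak %.2f)\n", nm,
                x$kmer[[nm]]$genome_size / 1e6,
                x$kmer[[nm]]$params$peak_refined))
  for (nm in names(x$errors))
    cat(sprintf("  %s FAILED: %s\n", nm, x$errors[[nm]]))
  invisible(x)
}

#' Tabulate and compare genome size estimates
#'
#' One row per (library, method). With `truth` supplied the signed percent
#' deviation is taken from the true size; otherwise from the per-library
#' mean across methods.
#'
#' @param reports A `run_report` or list of them.
#' @param truth Optional true genome size in bases (single value or vector
#'   named by library id).
#' @return Data frame with `library_id`, `method`, `genome_size`,
#'   `deviation_pct`, `reference`.
#' @export
compare_estimates <- function(reports, truth = NULL) {
  if (inherits(reports, "run_report")) reports <- list(reports)
  rows <- do.call(rbind, lapply(reports, function(rep) {
    out <- data.frame(library_id = character(0), method = character(0),
                      genome_size = numeric(0))
    if (!is.null(rep$gsec))
      out <- rbind(out, data.frame(library_id = rep$library_id,
                                   method = "read_depth",
                                   genome_size = rep$gsec$estimate$genome_size))
    for (nm in names(rep$kmer))
      out <- rbind(out, data.frame(library_id = rep$library_id,
                                   method = paste0("kmer_", nm),
                                   genome_size = rep$kmer[[nm]]$genome_size))
    out
  }))
  if (is.null(rows) || nrow(rows) == 0) stop("no successful estimates")
  ref <- if (!is.null(truth)) {
    if (is.null(names(truth))) rep(truth[1], nrow(rows))
    else truth[rows$library_id]
  } else {
    stats::ave(rows$genome_size, rows$library_id)
  }
  rows$deviation_pct <- 100 * (rows$genome_size - ref) / ref
  rows$reference <- if (is.null(truth)) "method_mean" else "truth"
  rownames(rows) <- NULL
  rows
}

#' Write a run report as TSV and JSON
#'
#' The TSV carries one row per locus (read-depth runs) followed by a
#' key-value summary block; the JSON twin carries identical content
#' structurally.
#'
#' @param report A `run_report`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @param timestamp Include the timestamp? Set `FALSE` for byte-reproducible
#'   output.
#' @return Named vector of the two paths, invisibly.
#' @export
write_report <- function(report, prefix, timestamp = TRUE) {
  stopifnot(inherits(report, "run_report"))
  tsv <- paste0(prefix, ".tsv"); json <- paste0(prefix, ".json")

  con <- file(tsv, "w")
  if (!is.null(report$gsec)) {
    writeLines("## per-locus", con)
    suppressWarnings(write.table(report$gsec$summary$loci, con, sep = "\t",
                                 quote = FALSE, row.names = FALSE))
  }
  writeLines("## summary", con)
  kv <- c(library_id = report$library_id, version = report$version)
  if (timestamp) kv <- c(kv, timestamp = report$timestamp)
  if (!is.null(report$stats))
    kv <- c(kv, n_reads = report$stats$n_reads,
            total_bases = report$stats$total_bases,
            mean_read_length = report$stats$mean_read_length,
            n_mito_reads = report$stats$n_mito_reads,
            mito_bases = report$stats$mito_bases)
  if (!is.null(report$gsec))
    kv <- c(kv, gsec_coverage = report$gsec$estimate$coverage,
            gsec_genome_size = round(report$gsec$estimate$genome_size),
            gsec_genome_size_mb =
              sprintf("%.1f", report$gsec$estimate$genome_size / 1e6))
  for (nm in names(report$kmer)) {
    est <- report$kmer[[nm]]
    kv <- c(kv,
            setNames(c(est$params$cutoff, est$params$peak,
                       round(est$genome_size),
                       sprintf("%.1f", est$genome_size / 1e6)),
                     paste0("kmer_", nm, "_",
                            c("cutoff", "peak", "genome_size",
                              "genome_size_mb"))))
  }
  for (nm in names(report$errors))
    kv <- c(kv, setNames(report$errors[[nm]], paste0("error_", nm)))
  writeLines(paste(names(kv), kv, sep = "\t"), con)
  close(con)

  payload <- report_payload(report, timestamp = timestamp)
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(tsv = tsv, json = json))
}

# Plain-list rendering of a run_report for JSON serialization.
report_payload <- function(report, timestamp = TRUE) {
  out <- list(library_id = report$library_id, version = report$version)
  if (timestamp) out$timestamp <- report$timestamp
  if (!is.null(report$stats)) out$library <- unclass(report$stats)
  if (!is.null(report$gsec)) {
    out$gsec <- list(
      genome_size = report$gsec$estimate$genome_size,
      coverage = report$gsec$estimate$coverage,
      params = report$gsec$summary$params,
      n_kept = report$gsec$summary$n_kept,
      loci = report$gsec$summary$loci)
  }
  if (!is.null(report$kmer))
    out$kmer <- lapply(report$kmer, function(est)
      c(list(genome_size = est$genome_size, base_coverage = est$coverage),
        est$params[c("k", "cutoff", "peak", "peak_refined", "secondary_peak",
                     "retained_mass")]))
  if (!is.null(report$truth)) out$truth <- report$truth
  if (length(report$errors)) out$errors <- report$errors
  out$config <- report$config
  out
}
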