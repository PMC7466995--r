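Package: covsize
Title: Genome Size Estimation from Read Depth of Single-Copy Loci and
    k-mer Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates haploid genome size from shallow shotgun sequencing
    by two complementary routes: (i) a read-depth protocol that trims the
    low-coverage flanks of single-copy reference loci, removes outlier loci
    by a three-interquartile-range rule, and converts mean coverage to
    genome size with the Lander-Waterman equation G = LN/C; and (ii) the
    classic k-mer spectrum estimator (canonical k-mer counting with
    Jellyfish-compatible histograms, error-multiplicity cutoff, coverage
    peak detection, genome size as retained k-mer mass over peak depth).
    A seeded shotgun simulator (repeat families, diploid heterozygosity,
    sequencing error, mitochondrial contamination, and a minimum-overlap
    mapping contract that reproduces locus flank-coverage artifacts) makes
    both estimators verifiable by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
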