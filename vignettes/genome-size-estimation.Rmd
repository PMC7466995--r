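---
title: "Estimating genome size from read depth and k-mer spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genome size from read depth and k-mer spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covsize)
```

covsize estimates the haploid genome size (the 1C value, reported in Mb)
of an organism from shallow shotgun sequencing alone, by two independent
routes, and ships a seeded simulator that makes both routes verifiable by
parameter recovery. This vignette is the package's account of the science:
the two models, their assumptions, the tunable parameters and why their
defaults are what they are, what the simulator does and does not emulate,
and the numerical choices that matter.

## The read-depth estimator

If a set of reference loci is genuinely single-copy, the mean read depth
across those loci estimates the sequencing depth of the whole genome, and
the Lander–Waterman identity converts depth into size:

$$G = \frac{LN}{C} = \frac{B}{C},$$

where $L$ is the mean read length, $N$ the read count, $B = LN$ the total
sequenced bases and $C$ the mean coverage. We implement the identity on $B$
directly, so libraries with variable read lengths need no special case.

Two artifacts must be corrected before $C$ is trustworthy:

**Flank ramps.** Read mappers refuse to map a read when only a small part
of it overlaps the reference, so the first and last positions of every
locus show depressed coverage: under a full-overlap contract the ramp is
$L - 1$ bases wide, and empirically the visible drop-off concentrates in
the outermost ~75 bases for 100–150 b reads. `trim_flanks()` excludes a
fixed number of terminal positions (default `trim_bases = 75`) from each
end before any averaging. A locus shorter than `2 * trim_bases` cannot be
trimmed and is excluded from the mean (reported as `too_short`), not
treated as an error.

**Outlier loci.** A locus that is secretly multi-copy (or hit by reads
from a pseudogene or contaminant) carries coverage far above the genome-wide
depth and can substantially distort a mean taken over, say, 74 loci.
`iqr_filter()` keeps a locus when its trimmed mean coverage lies within
`iqr_multiplier` (default 3) interquartile ranges of the median, and
independently applies the same rule to trimmed locus lengths. The filter is
two-sided; quartiles use linear interpolation between order statistics
(`stats::quantile()` type 7 — no convention is canonical in the field, so
we fix one and state it). Degenerate inputs are handled explicitly: with
fewer than four loci quartiles are meaningless and everything is kept with
a warning; an all-equal vector has IQR 0 and zero deviations, so everything
is kept.

The pipeline order in `estimate_coverage()` is: trim every locus, compute
trimmed means and trimmed lengths, filter on both, then average. Filtering
uses *trimmed* quantities because those are what the estimator consumes;
since trimming removes the same `2 * trim_bases` from every trimmable
locus, filtering on raw lengths would select the identical set whenever all
loci are trimmable. "Average coverage across loci" is read as the
unweighted mean of per-locus means (`averaging = "locus_mean"`), treating
each locus as one draw from the coverage distribution; a pooled,
length-weighted alternative (`"pooled"`) is provided because the phrase
admits both readings. With `trim_bases = 0`, `iqr_multiplier = Inf` and
pooled averaging the estimator degenerates to total depth over total bases
— a useful regression baseline. When a locus fails both filters it is
reported once, as a coverage outlier (coverage is the scientifically
interesting failure; the choice affects reporting only).

**Mitochondrial reads.** Mitochondria contribute sequenced bases but not
nuclear genome, inflating $B$; libraries in this family of organisms carry
roughly 0.1–3% mitochondrial DNA. `library_stats()` carries optional mito
fields, and `lander_waterman(..., exclude_mito = TRUE)` subtracts them from
$B$. `mito_screen()` fills those fields without an aligner: a read is
flagged when at least 35% of its canonical k-mer windows occur in the
mitochondrial reference. The 35% default is chosen to approximate a
70%-identity mapping contract (a read at ~98% identity to the reference
shares far more than 35% of its 21-mers; a read below ~70% identity shares
far fewer); the equivalence is approximate by construction and the
threshold is exposed (`min_shared_frac`, `min_shared`).

## The k-mer spectrum estimator

For reads with negligible artifacts, the multiplicity distribution of
genomic k-mers approximates a Poisson with its peak at the k-mer-level
sequencing depth. The classic estimator divides the spectrum's mass by its
peak:

$$\hat G = \frac{\sum_{i \ge c_0} i \, h_i}{\lambda},$$

with $h_i$ the number of distinct canonical k-mers seen exactly $i$ times,
$c_0$ an error cutoff and $\lambda$ the coverage peak. Note $\lambda$ is
k-mer depth, not base depth: a read of length $L$ yields $L - k + 1$
windows, so base coverage is $C_b = \lambda L / (L - k + 1)$, about 25%
larger at $k = 21, L = 100$. The two scales are easy to conflate;
`kmer_genome_size()` reports both when $L$ is known.

**Counting** (`count_kmers()`) is exact: canonical k-mers (the
lexicographic minimum of a window and its reverse complement — shotgun
reads are unstranded, so both-strand counting is assumed), 2-bit rolling
encoding, odd $k$ between 3 and 31 (odd avoids self-reverse-complement
palindromes), windows containing non-ACGT characters skipped. Histograms
are Jellyfish-compatible on disk (`write_histogram()`), so external
spectrum tools can consume them. The counter is in-memory and intended for
desk scale (up to ~1e8 windows); streaming approximation is deliberately
out of scope. No maximum-multiplicity truncation is applied by default.

**Error cutoff** (`error_cutoff()`). Sequencing errors create mostly
unique k-mers, a spike at multiplicities 1–2 that would inflate the mass.
The cutoff is the smallest $i \ge 2$ with $h_i \le h_{i+1}$ — the first
valley — accepted only when some later bin rises above it (i.e. a genuine
coverage peak exists beyond the valley). On a spectrum with no valley
(e.g. very low coverage) the cutoff falls back to 1 with a warning, since
error and genomic k-mers are then not separable by multiplicity. The
cutoff is a pragmatic classical device, not a model fit; mixture-model
approaches are out of scope. A user override is accepted.

**Peak detection** (`find_peak()`). $\lambda$ is the modal multiplicity at
or above the cutoff, ties broken toward the smaller multiplicity. Two
refinements:

* *Sub-bin position.* The integer mode is too coarse for the estimator:
  a spectrum whose true k-mer depth is 24.0 has (to first order) tied
  modes at 23 and 24, and dividing by 23 instead of 24 moves $\hat G$ by
  over 4%. For a Poisson-shaped peak the identity
  $\lambda = (i+1)\,h_{i+1}/h_i$ holds at every $i$, so a count-weighted
  average of those ratios over bins within ±2 of the mode gives a
  continuous peak position; it is clamped to mode ± 1, where the true peak
  of a unimodal spectrum must lie. `kmer_genome_size()` divides by this
  refined position by default (`refine = FALSE` restores the integer-mode
  estimator). The ratio identity is exact only for Poisson peaks; for
  mixtures (diploid spectra) nearby secondary structure can pull the
  refined value by a fraction of a bin, which is why the clamp exists.
* *Secondary peaks.* In a heterozygous diploid, k-mers overlapping a
  heterozygous site occur on one haplotype only and peak near $\lambda/2$
  (or, seen from the other side, the homozygous peak sits near
  $2\lambda$). `find_peak()` searches ±20% of both $2\lambda$ and
  $\lambda/2$ for a second local maximum with at least 5% prominence over
  the valley between the peaks, and reports it as `secondary_peak`.
  Searching both sides matters: which peak is taller depends on the
  heterozygosity (at 1% heterozygosity with $k = 21$ about 19% of
  positions are within a window of a het site, and the homozygous peak
  still dominates; at higher heterozygosity the half-depth peak wins).
  With `ploidy_peak = "homozygous"` the larger-multiplicity peak of the
  pair is used as the working depth — the appropriate choice when the
  primary peak is suspected to be the heterozygous one, a situation that
  halves genome size estimates if unrecognized.

**The k sweep** (`k_sweep()`, default $k = 13$–$31$ in steps of 2) runs
the whole chain per $k$ so the stability of $\hat G$ across $k$ can be
inspected; $k = 21$ is the conventional default. Failures at one $k$ are
recorded without aborting the sweep. Significance testing across $k$ is
left to the user's statistical toolkit.

## The simulator

`simulate_library()` exists so that both estimators can be checked by
recovering known truth, without external data. It generates, from one seed
expanded into per-stage substreams (so enabling heterozygosity never
changes the genome draw, etc.):

* an i.i.d. background genome at a configurable GC (default 0.40, typical
  of insect nuclear genomes);
* optional repeat families — near-identical copies of a random unit with
  per-copy substitution divergence — emulating the high repeat content
  (tens of percent) that real estimates contend with;
* `n_loci` single-copy loci placed at least one read length away from
  every repeat copy and from the genome ends, so locus coverage is a clean
  read-out of genome-wide depth;
* an optional second haplotype at `het_rate`, and an optional 16 kb
  mitochondrial contaminant contributing `mito_fraction` of reads;
* uniform single-end reads (`N = round(depth * genome_size /
  read_length)`), uniform strand, substitution errors at `error_rate`;
* locus coverage under a minimum-overlap mapping contract: a read counts
  toward a locus iff its overlap is at least `min_overlap_frac * L`
  (ties kept). With `min_overlap_frac = 1` this reproduces the flank
  ramps that motivate trimming; with 0 it reproduces raw genome depth.

The defaults — 1 Mb genome, 40 loci of 1.5 kb, 30× depth, 100 b
error-free homozygous reads, full-overlap contract — are the package's
reference scenario: large enough that estimator noise is ~1% (each locus
collects ~420 fully contained reads, giving a ~5% per-locus and ~0.8%
40-locus standard error on $C$; the k-mer spectrum pools 24 M windows),
small enough that the whole recovery suite runs in about a minute. The
tests and the acceptance script state their scales explicitly.

What the simulator does **not** emulate — and therefore what passing
recovery tests do not demonstrate about real data: GC-dependent coverage
bias, paired-end structure and insert sizes, indel errors, PCR duplicates,
quality-score structure, contamination other than a single mitochondrial
sequence, and real mapper behaviour beyond the minimum-overlap contract
(no mismatch-dependent mapping, no mapping-quality filtering). The flank
ramp it produces is the idealized full-contract ramp of width $L - 1$;
real ramps are softer. Substitution-only errors are sufficient to create
the error spike in the spectrum, which is all the estimator consumes.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; the 1-based
  samtools-depth dialect is shifted on ingestion, and positions absent
  from a sparse depth file are depth 0. Declared locus lengths (BED) win
  over observed lengths and pad trailing zeros; a declared length shorter
  than an observed position is an error, not a truncation.
* The samtools-dialect writer emits zero-depth rows (the `samtools depth
  -a` form) so write→read round-trips are lossless.
* `trim_flanks()` returns `NULL` (not an error) for untrimmable loci;
  `estimate_coverage()` fails only when *no* locus survives, and then
  reports the rejection tally.
* Genome sizes are kept as doubles in bases; reports round to whole bases
  and print Mb with one decimal.
* `which.max` tie-breaking (toward the smaller multiplicity) is relied on
  for the spectrum mode and documented rather than accidental.
* All simulator randomness flows from one integer seed below $2^{31}$;
  stage substreams are drawn from it with R's default generator.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_library(sim_config(seed = 1))      # reference scenario
cs <- estimate_coverage(sim$coverage, trim_bases = 75)
lander_waterman(sim$stats, cs)
kmer_genome_size(count_kmers(sim$reads$reads, k = 21), read_length = 100)
```

Both estimates land within ~1–2% of the true 1 Mb. Raising `het_rate` to
0.01 produces the bimodal spectrum discussed above; setting `trim_bases =
0` exposes the flank bias (≈ +7% on $\hat G$ under the full-overlap
contract, of which trimming removes ≳ 90%).

## Known limitations

* Both estimators assume unbiased, uniform coverage; neither corrects for
  GC bias or low-complexity dropout.
* The read-depth route is only as good as the single-copy assumption of
  its reference loci; the IQR filter catches gross violations, not subtle
  paralogy.
* The spectrum estimator's error cutoff discards genuine low-coverage
  genomic k-mers along with errors, biasing $\hat G$ slightly downward at
  low depth; below ~10× the peak itself becomes unreliable.
* Highly repetitive or highly heterozygous genomes violate the
  single-Poisson picture; covsize reports bimodal structure but fits no
  mixture model, and its estimates on such genomes inherit the classic
  method's biases (typically underestimation).
* The mitochondrial screen is a k-mer approximation of an identity-based
  mapping contract, not a reproduction of any aligner.
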