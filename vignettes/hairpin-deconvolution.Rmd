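---
title: "Hairpin bisulfite deconvolution: model, assumptions and design notes"
author: "methylsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hairpin bisulfite deconvolution: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylsnp)
```

## The measurement principle

Hairpin-linked bisulfite sequencing covalently joins a genomic DNA fragment
to an unconverted copy of itself before bisulfite treatment. After
amplification, Read1 reports the converted original strand and Read2 the
four-base copy strand, cycle-aligned from the same fragment end. Comparing
the two mates at the same cycle recovers both the original sequence and the
methylation state of every covered cytosine:

| Read1 | Read2 | interpretation            | deconvolved base |
|-------|-------|---------------------------|------------------|
| C     | C     | methylated C (`METH_C`)   | C                |
| T     | C     | unmethylated C (`UNMETH_C`) | C              |
| x     | x (x ≠ C) | agreement (`AGREE`)   | x                |
| N on either | — | ambiguous (`AMBIGUOUS`) | N               |
| anything else | — | mismatch (`MISMATCH`) | Read1 base      |

These five classes partition all 25 base combinations; `classify_position()`
is that partition and `deconvolve_pair()` / `deconvolve_pairs()` apply it
per cycle. Methylation calls are encoded in the Bismark XM alphabet
(`Z/z` CpG, `X/x` CHG, `H/h` CHH, `U/u` unknown context, `.` non-cytosine),
with context read from the *deconvolved* sequence itself; cytosines within
2 nt of the read end, or with N inside their context window, are reported
as unknown. A mismatch position whose retained Read1 base is C is annotated
`u`: its methylation state is unknowable from the pair, and the lowercase
symbol guarantees it never counts as methylated downstream while keeping
the one-symbol-per-C invariant.

A pair whose mismatch fraction exceeds `reject_frac` (default 0.10) is
flagged undeconvolvable. Real libraries contain 10–15% of such molecules —
conventional bisulfite pairs that escaped hairpin ligation — and the
simulator emulates them explicitly. The criterion (fraction of mismatching
cycles) is this package's own operationalization; the threshold is
configurable.

## Quality assignment

* Agreement (and both cytosine classes): the minimum of the two mate
  qualities. The protocol gives two independent reads of the same base;
  the minimum is a conservative summary.
* Ambiguous: Phred 0.
* Mismatch, reference-free mode: the Read1 base is kept at Phred 0 —
  the pair itself cannot say which mate erred.
* Mismatch, calibrated mode: after a first reference-free pass is aligned,
  `build_calibration_table()` counts, for every stratum (reference base r,
  Read1 base a, Read2 base b, cycle bin), how often the Read1 base equalled
  the reference. The posterior that Read1 can be trusted is the Beta(1,1)
  posterior mean p = (x+1)/(N+2), emitted as Q = round(−10·log10(1−p)),
  capped at 41 (the printable Illumina scale). An unobserved stratum falls
  back to the prior p = 1/2 (Q = 3). Cycle bins default to 10 cycles — wide
  enough to keep strata populated at desk-scale simulation depth, narrow
  enough to track cycle-dependent error. When the reference base for a new
  pair is unknown (not yet aligned), a companion table marginalized over r
  is used.

The empirical-Bayes stratification is this package's design; published
pipelines describe the same inputs (reference base, substitution type,
cycle) without fixing a formula.

## The simulator: what it emulates, what it does not

`simulate_read_pairs()` reproduces the protocol generatively: fragments are
drawn uniformly from both strands of the genome (lengths normal, default
300 ± 50 bp, truncated below at the read length unless adapter read-through
is enabled); Read2 is the fragment prefix read verbatim; Read1 is the same
bases with each unmethylated C converted to T with probability
`conversion_rate` (default 0.975, the rate the protocol achieves) and each
methylated C surviving with probability `methylated_retention` (default 1);
sequencing substitution errors are injected independently per mate;
a configurable fraction of pairs (`undeconvolvable_fraction`) is emitted as
conventional bisulfite pairs whose second mate comes, converted, from the
opposite fragment end; qualities are a constant Q37 with Q11 at injected
errors. Ground truth is returned per site and per read, so every
downstream stage is testable without any external data.

Methylation models:

* **rate mode** emulates vertebrate CpG methylation; each CpG cytosine is
  methylated independently with `cpg_rate`. By default the two cytosines of
  a CpG dyad are drawn independently at the same rate (`symmetric = TRUE`).
  Symmetry is the biological norm (maintenance methylation copies marks
  across the palindrome), and it is required for a both-strand read
  simulation to reproduce a stated global CpG level: with top-strand-only
  methylation, reads from the minus strand would contribute only
  unmethylated CpG calls and any pipeline estimate would be half the
  nominal rate. `symmetric = FALSE` restricts truth to top-strand
  cytosines for experiments that need it.
* **motif mode** emulates prokaryotic methyltransferases: every IUPAC
  occurrence of each motif, on either strand, is methylated at the stated
  cytosine offset with the stated efficiency.

Deliberately not modelled: indel sequencing errors, PCR/GC bias,
quality-by-cycle decay, hemimethylation (the protocol destroys the
information needed to observe it: only the original strand's methylation is
read). Truth is binary per site — a site is methylated on a molecule if and
only if it is methylated in the truth table — so per-read variability at a
site comes only from conversion chemistry and sequencing error. Passing
round-trip tests therefore demonstrate correctness of the deconvolution
algebra, not robustness to every artifact of real libraries.

## Alignment filters

Filters operate on single-end alignments of deconvolved reads, in the fixed
order: (1) unique mapping — keep records carrying only an AS tag, or with
AS ≠ XS; (2) duplicate marking — records sharing strand-aware 5′ position
*and* sequence are duplicates; the highest mean-quality record is kept,
ties broken by read id (the representative choice is this package's,
commonly left unspecified); (3) XM tagging from the deconvolution report,
reversed for minus-strand records so XM position i annotates mapped base i;
(4) non-conversion filtering — a read with ≥ 3 methylated non-CpG calls
(X/H) is presumed unconverted and removed (3 is the wrapped tool's default;
the threshold is exposed).

## Quantification

`pileup_methylation()` turns XM symbols into per-site counts (uppercase →
X and N, lowercase → N only; U/u excluded); coordinates are 1-based,
strand-resolved, contexts kept separate. Minus-strand cytosines are
reported at their own coordinate rather than collapsed onto the plus-strand
CpG — the protocol reads only the original strand of each fragment, so the
two strands are genuinely separate observations.

The conversion rate is 100·Σ(N−X)/ΣN over either designated unmethylated
control contigs (spike-in mode) or all CHG+CHH calls (context mode).
Region methylation is Σ X / Σ N over the CpG calls inside each interval,
with regions below 50 CpG calls of coverage flagged out (`coverage ≥ 50`
passes). Note this weights sites by coverage, which equals the
coverage-weighted mean of per-site levels.

Allele-specific methylation: reads covering a heterozygous SNP are split by
the read base at the SNP (deconvolved reads are four-base, so REF/ALT
assignment is direct, with no bisulfite ambiguity); per-group CpG pileups
are exported in the four-column `chr pos N X` format that differential
methylation tools consume, with the conventional thresholds (delta = 0.1,
p.threshold = 0.05) passed through as configuration. The differential test
itself is out of scope.

## Motif discovery

From a Bernoulli subsample of deconvolved reads (default 2%), every
cytosine call becomes an 8-mer context: 3 bases upstream, the C, 4
downstream. Reads with more than one methylated call are excluded — they
cannot attribute methylation to a single context (the exclusion counts all
contexts, the conservative reading). Per distinct 8-mer, k methylated of n
total occurrences feed the upper-tail binomial test against the global
average level P0 = Σk/Σn:

> P = 1 − BinomCDF(k; n, P0)

i.e. the probability of *strictly more* than k successes. This matches the
published formula; the conventional P(X ≥ k) is available via
`tail = "geq"`. Only k-mers with n ≥ 5 are tested (singleton contexts
cannot support significance), and Bonferroni correction uses the number of
*tested* k-mers. The family-wise guarantee presumes independent
occurrence-level draws: it holds exactly for i.i.d. noise such as
conversion failure, but site-level binary methylation sampled repeatedly by
overlapping reads produces dependent calls, and a single methylated site
covered a few times can legitimately reach significance. The package's
null-control test therefore uses a fully unmethylated genome with 5%
conversion failure — the regime the binomial model actually describes.

Significant k-mers are clustered by average-linkage hierarchical clustering
and each cluster is summarized as a position frequency matrix (columns
weighted by each member's methylated count k) and an IUPAC consensus
(letters with column frequency ≥ 0.2; fully degenerate flanks trimmed from
the reported core). The pairwise distance is a mismatch count in which a
mismatch at column j costs 1 + IC_j, IC being the column's information
content (2 − entropy, in bits) over the clustered k-mers. Plain Hamming
distance is provably unable to resolve a single-position wobble such as the
W of CCWGG inside an otherwise balanced k-mer set: the three free flanking
columns and the wobble are exchangeable, and every linkage rule then cuts
on a flank (we verified purity 0.50 across linkages and seeds on the
complete 128 k-mer set). The IC bonus makes the two-letter wobble column
dominate the near-uniform flanks, while the constant base cost keeps
unrelated motif families (which differ at many columns) far apart; both the
Dcm wobble split and a three-family mixture separate cleanly under it.
`ic_weight = FALSE` restores plain Hamming. A recovered consensus is
typically a *refinement* of the true recognition motif (e.g. `GCDHGC` for
GCNNGC, since D, H ⊂ N); `motif_matches()` implements that IUPAC-subset
comparison.

Cluster count is a user choice (as in practice, where it is read off the
clustering heatmap); no automatic selection is implemented.

## Numerical and scale choices

Simulation sizes used by the test-suite and the acceptance script were
chosen as the smallest that leave the checked statistics comfortably inside
their binomial noise bands: round-trip exactness on 50,000 pairs from a
200-kb genome; conversion-rate recovery on a 48.5-kb unmethylated control
(the size of the lambda spike-in genome) at ~20,000 pairs; global CpG
recovery on a 500-kb genome at ~100,000 pairs; motif recovery on 100-kb
(single motif) and 3 × 80-kb (mixture) genomes. One caveat is recorded for
the CpG-level recovery: the estimator 100·ΣX/ΣN does not correct for
conversion failure, so at conversion rate 0.99 its exact expectation is
100·(p + (1−p)·0.01) ≈ 45.85 for p = 0.453; the acceptance test asserts
the estimator against this exact expectation (within three site-level
binomial SD) and against the nominal 45.3 within the non-conversion
inflation bound. All randomness flows from explicit integer seeds; results
are bit-reproducible for a given seed.

## Known limitations

* Alignment itself is out of scope; filters consume alignments produced
  elsewhere (tests use truth-derived perfect alignments of simulated
  reads).
* Calibration assumes ungapped (M-only) alignments when mapping mismatch
  cycles to reference coordinates.
* The trimmer is a 3′-anchored matcher with 10% mismatch tolerance and
  minimum overlap 3; it does not model indels within the adapter.
* Motif discovery assumes a fixed methylated-C offset registry per k-mer
  (index 3); enzymes methylating near read ends lose those occurrences.
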