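---
title: "Methods: consensus INDEL calling and slippage analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus INDEL calling and slippage analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`indelcons` implements an ensemble approach to short coding INDEL
discovery: several independent caller call sets are normalized to a
common allele representation, merged, filtered by a supervised consensus
model, and the resulting set is characterized for slippage mutagenesis,
allele-frequency structure and validation quality. This vignette records
the model, its assumptions, and the design decisions that a maintainer
would otherwise have to reverse-engineer from the code.

## Allele representation and normalization

An INDEL allele is stored VCF-style: a 1-based anchor base preceding the
inserted/deleted sequence, with the anchor included in both allele
strings. Only pure INDELs live at this layer; `split_complex()` reduces
arbitrary REF/ALT pairs by end-anchored trimming (trim equal bases from
both ends, align the remaining cores from their left edge, emit
mismatching aligned bases as SNPs and the length difference as one
INDEL). The SNP components are discarded downstream: the analysis is
INDEL-only, and we deliberately do not attempt to model SNP-disrupted
repeats as a third class. Alleles of 100 bp or more are out of scope
(structural variation), as are sex chromosomes: all merged output is
autosomal.

`left_align()` produces the canonical representation by shifting an
event left one base at a time while the anchor base equals the last base
of the allele sequence, rotating the sequence as it goes. This is
idempotent and preserves the alternate haplotype exactly (both properties
are fuzz-tested against a brute-force enumeration oracle that tries every
candidate anchor). Numerical/edge choices:

* the shift window is capped at 300 bp (`max_shift`) — three times the
  maximum allele length, so the cap is never binding in practice but
  bounds worst-case cost on pathological references;
* an `N` at the anchor stops shifting: ambiguous sequence is treated
  conservatively rather than guessed across;
* sequence comparison is case-insensitive (everything is upper-cased at
  construction).

Matching across callers is by exact normalized key
`chrom:pos:ref:alt`. Validation matching is deliberately looser
(`match_indel()`): same signed length and anchor within 30 bp (5 bp for
1 bp alleles), since amplicon re-sequencing localizes an event without
re-deriving its canonical anchor.

## Union merge and covariates

Caller quality scales are incomparable (and heavy-tailed), so the union
records each caller's quality as its within-call-set empirical CDF value
(`rank/n`, mean ranks on ties; missing qualities get 0.5 as a median
prior). Target-region filtering tests the anchor position as a point —
deterministic, and consistent with the position-based matching used for
in-silico comparison. When an allele is reported by several callers, its
genotypes come from the first supporting call set in the configured
caller order, so caller-private alleles keep their private genotypes.

The consensus classifier consumes exactly six covariates per union
allele: supporting-caller count, mean normalized quality, mean carrier
depth, pooled variant-read ratio over carriers, the longest homopolymer
run within ±10 bp of the anchor, and |length|. The first four summarize
call and read support; the last two capture the sequence context that
drives slippage artifacts. The set is fixed in `consensus_covariates()`
and intentionally small: each covariate is available from VCF-level
information without revisiting alignments.

## Consensus model

A random forest (500 trees, default split parameters, seed recorded in
the model object) is trained on union alleles labeled by overlap with a
truth call set; the consensus probability is the fraction of trees voting
"true". Hyperparameters are deliberately untuned — determinism and
robustness matter more here than squeezing out accuracy, and the
two-class signal (multi-caller support + read support) is strong.
Because the scored set and the training set are the same table in the
standard workflow, `consensus_probability()` returns **out-of-bag**
probabilities for alleles that were part of training and ordinary forest
predictions otherwise; resubstitution probabilities would be near 0/1 and
would make the cutoff meaningless.

The retention rule keeps alleles with probability **≥ 0.4**: the
boundary value itself is retained (the exclusion rule is "less than
0.4"). Retained sites are regenotyped per sample by maximum likelihood
under a binomial read model with error rate `e = 0.02`, success
probability 0.5 for heterozygotes and `1 − e` for homozygotes, flat
prior, ties broken toward the lower genotype; zero or missing depth
yields a missing genotype. Any calibrated read-based genotyper could be
substituted — the contract is only that genotypes follow the evidence and
that sites called in no individual are pruned.

## Slippage (CCC) classification

The smallest motif *m* of the allele sequence is the shortest prefix
that tiles it (sequences with no proper tiling use the whole sequence,
so a single adjacent copy still counts: copy count 1→2 or 2→1). The
event is CCC iff the |m| reference bases immediately left **or** right
of the event equal *m*. Both sides are inspected even though records are
left-aligned: the symmetric rule is robust to representation and matches
the intuitive definition of expanding/contracting an adjacent copy. Any
`N` in the inspected windows gives NCCC with an `ccc_ambiguous` flag
rather than a guess. Classification is defined on the canonical
left-aligned form — a right-shifted encoding of the same allele can
superficially fail the adjacency test, which is precisely why ingest
normalizes first.

The null model for "how much CCC arises by chance" is
`simulate_random_indels()`: lengths are drawn from the call set's
empirical histogram, positions uniformly within the targets, deletion
sequences from the reference, insertion sequences i.i.d. uniform over
the four bases. Uniform insertions give a clean closed-form check — a
1 bp insertion on an i.i.d. uniform reference is CCC with probability
1 − (3/4)² = 7/16 — which the test suite verifies at n = 50,000.

## Population statistics

Variant density is count/(region Mb), computed per individual and then
averaged; allele frequency is the alternate-allele count over called
chromosomes (missing genotypes excluded from the denominator). The seven
allele-frequency bins use edges 0.1%, 0.5%, 1%, 5%, 10%, 50% over
(0, 1], left-open right-closed; summing bins reproduces the standard
reporting thresholds (rare < 1%, intermediate 1–10%, common ≥ 10%). Bin
indices are 1-based, following R convention. MAF comparisons use the
two-sided Wilcoxon rank-sum test as implemented in `stats::wilcox.test`
(normal approximation with tie correction at large n, exact method at
small tie-free n).

## Validation engine

Status rules, with 1 bp thresholds in parentheses: failed if the design
failed or fewer than 20 reads cover the site; confirmed if the
variant-read ratio is ≥ 20% (40%) **and** mean base quality ≥ 10 (20);
false positive if the ratio is < 3% (5%); ambiguous otherwise. A site
meeting the ratio floor but failing the quality floor is ambiguous, not
a false positive — the false-positive rule is stated purely in terms of
the ratio, and low base quality discredits the assay rather than the
variant.

`estimate_fdr()` returns FP/(TP+FP), the false fraction of decided
sites. `detectable_indels()` implements
`TP_union + (AMBG_cons + FAIL_cons) × (1 − S_cons)` and exposes an
optional variant that additionally scales the uninformative term by
`1 − FDR_cons`; the default is the simple product, and the flag exists
because the estimator's verbal description and its formula admit both
readings. We report the formula as written and leave the choice to the
caller rather than canonizing one interpretation.

Validation site selection is stratified by AF bin with
largest-remainder rounding so the selected sites preserve the source
set's frequency distribution; up to five carrier individuals per site
are drawn uniformly.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
study conditions under which the pipeline is exercised:

* **Reference**: 1 Mb over two autosomes, i.i.d. uniform background with
  3 planted repeat tracts per kb (70% homopolymers of 6–14 bp, 30%
  short tandem repeats with primitive 2–4 bp motifs, 3–6 copies), tracts
  non-overlapping by construction; exome-like 200 bp target intervals
  covering 50% of each chromosome.
* **Truth set**: 2,000 INDELs across 50 diploid samples. Signed lengths
  follow a power law heavy at 1 bp with a 2× enrichment at multiples of
  three and a 1.5× excess of deletions. 60% of sites are planted as
  copy-count changes: insertions duplicate the adjacent reference bases
  (always CCC by construction), deletions contract a planted tract
  leaving at least one motif copy; the remaining 40% are
  rejection-sampled to be NCCC on their left-aligned form, so the
  planted fraction is recovered exactly by the classifier. Allele counts
  come from the neutral 1/i spectrum (most sites rare), genotypes from
  drawing that many chromosomes without replacement. Events keep a ≥5 bp
  guard band from one another.
* **Callers**: three profiles with sensitivities 0.85/0.80/0.75,
  lognormal quality scores (true calls stochastically above false
  calls), false positives biased 50% toward repeat tracts, and a total
  false-positive load derived so the union's planted false fraction is
  ≈ 0.35 — the low-precision regime that motivates consensus filtering
  in the first place. A quarter of records are emitted right-shifted and
  5% as complex events to exercise ingest normalization. False sites
  carry artifact read support (variant-read ratio ~ Beta(2, 8) in their
  claimed carriers), so neither regenotyping nor any single covariate
  can separate classes trivially.
* **Validation assay**: fixed depth 100, per-read error 0.5%, 5% design
  failure rate; mean base quality ~ N(30, 3) for real signal and
  N(12, 4) for noise.

What the generator does **not** emulate: read-level data (FASTQ/BAM),
mapping bias, batch effects between sequencing platforms, genotyping
error correlated across callers, linkage between sites, and population
structure. Passing tests therefore demonstrate the pipeline's logic and
calibration under a realistic error model, not performance on any
particular real cohort.

## Problem sizes and runtime envelope

The test suite runs the normalization fuzz at 10,000 records, the
classifier-versus-oracle comparison at 5,000 loci, the analytic CCC null
at 50,000 insertions, the consensus-recovery experiment at 400 true
sites × 5 seeds, and the validation-recovery experiment at 800 sites —
sizes chosen so the full suite completes in a few minutes on one core
while keeping binomial standard errors small enough for the stated
tolerances. The acceptance script runs the full default configuration
(2,000 true sites, 50 samples).

## Known limitations

* The CCC rule inspects only the immediately adjacent motif copy; it
  does not model interrupted or near-miss repeats, and `ccc_ambiguous`
  loci are counted as NCCC in profiles.
* The regenotyper's binomial model ignores mapping bias toward the
  reference allele; with real alignments the heterozygote mean would sit
  below 0.5.
* Caller-private genotype adoption (first supporting caller wins) is a
  convention; alternatives (e.g. majority voting per genotype) are not
  implemented.
* The consensus model is trained per run; no mechanism is provided for
  transferring a trained forest across cohorts with different covariate
  distributions.
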