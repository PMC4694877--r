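---
title: "Methods: matched FF/FFPE concordance, artifact spectra and low-pass copy number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched FF/FFPE concordance, artifact spectra and low-pass copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffpeconcord)
```

## Scope and model

`ffpeconcord` quantifies how faithfully formalin-fixed paraffin-embedded
(FFPE) sequencing reproduces results from matched fresh-frozen (FF)
tissue. Formalin fixation deaminates cytosines, which sequencing reads as
C>T (or G>A when the damaged strand is the complement); the artifact is
strongly enriched at CpG dinucleotides. The package works from
per-position pileup summaries rather than raw reads: alignment, duplicate
marking and base recalibration are treated as upstream and replaced, for
testing, by a generative model of the pileup itself.

Throughout, coordinates are 1-based inclusive; BED files on disk use the
standard 0-based half-open convention and are converted exactly once on
read and once on write.

## The synthetic matched-pair generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream claim is checked.

* **Reference.** Bases are drawn iid with the configured GC fraction;
  CG-dinucleotide frequency is then adjusted toward
  `cpg_enrichment × (gc/2)²` by planting (or destroying) CG
  dinucleotides, compensating with A/T flips elsewhere so expected GC is
  preserved. Human-like genomes are CpG-depleted (enrichment < 1), but
  artifact analyses need CpG-rich substrate, so tests typically use
  enrichment 3–5.
* **Truth.** Heterozygous germline SNVs at `germline_het_rate` per base;
  somatic SNVs (tumor kinds only) at `somatic_rate` with truth VAF drawn
  from a Beta distribution (concentration 20) centered on
  `tumor_vaf_mean` — tumor purity is absorbed into that mean, with no
  subclonal structure. INDELs occur at `indel_rate` with shifted-Poisson
  sizes whose default means (insertions 6 bp, deletions 9 bp) match the
  sizes reported for this assay class. Germline, somatic and INDEL
  position sets are disjoint by construction.
* **Pileups.** Depth is negative-binomial with mean `mean_coverage_*`
  (Poisson at dispersion 0); tumor kinds scale expected depth by
  `copy_state / 2` of the covering CNV segment. Read bases follow the
  truth allele, are miscalled uniformly at `seq_error_rate`, and — in
  FFPE kinds only — read C bases at reference-C positions flip to T with
  probability `deamination_rate_cpg` when the 3′ neighbor is G and
  `deamination_rate_noncpg` otherwise (reference-G positions are the
  complementary-strand case, G→A conditioned on a 5′ C). Deamination is
  modeled per read with strand collapsed, matching the collapsed
  C·G>T·A classes used in analysis. Mapping quality is a per-position
  truncated normal on [0, 60] — a per-position scalar, because the hard
  filters act on per-position aggregates. An INDEL is supported by each
  read with probability equal to its truth VAF, independent of
  deamination (formalin damage to INDEL detection is not separately
  modeled).
* **Low-pass counts.** Expected bin count is
  `lowpass_mean_coverage × width × (copy_state/2 for tumors) × g(gc)`
  with `g(gc) = max(1 + gc_bias_strength·(gc − 0.5), 0.1)`; counts are
  negative-binomial, and each counted read receives a uniform start
  position within its bin, so binning the emitted read starts reproduces
  the counts exactly (count conservation is a tested invariant).
* **Array genotypes** are emitted at a configurable subset of germline
  sites and corrupted to a uniform other class with probability
  `error_rate`, emulating an orthogonal genotyping platform.

All randomness flows from one master seed through named substreams
(`substream_seed`), so adding a stage never perturbs another stage's
draws and identical configurations are bit-reproducible.

What the generator does **not** emulate: mappability structure, library
fragment-size effects, strand-specific damage asymmetry, PCR duplicates,
subclonality, and multi-allelic sites. Passing tests therefore certify
the analysis logic under a clean observation model, not performance on
real alignments.

## Calling and filters

Consensus and variant calling follow the hard-filter design used for
this assay family: no call below 13× coverage (20× in targeted mode) or
below mapping quality 43; variant calls additionally require VAF
strictly greater than 0.2. The VAF boundary is exclusive (a site at
exactly 0.2 is not called); the heterozygous/homozygous boundary of 0.8
is a package default, configurable, as the upstream analyses do not
constrain it. One alternate allele is considered per site (the
highest-count non-reference base, ties broken by base order).

The consensus caller has two modes. The default is a strict majority
vote with exact ties yielding no call — maximally deterministic and the
mode used for the documented tie examples. The `het_aware` mode emits
two-base IUPAC codes (e.g. `Y` for C/T) when the second allele exceeds
the VAF threshold, the way samtools-era pileup consensus represented
heterozygotes. The distinction matters for a subtle reason: under a pure
majority vote the consensus at a heterozygous site is a coin flip
between the two alleles, independently in each sample, so even a
noise-free matched pair cannot reach base-level concordance of exactly 1
— het-aware consensus restores determinism at het sites and is the mode
used in the zero-artifact fidelity checks.

For INDELs the same filter and VAF logic applies to the
insertion/deletion-supporting counts; when both event types are
supported, the higher count wins and an exact tie is a no-call. Event
sequences travel in optional `ins_seq`/`del_seq` pileup columns so calls
can emit concrete anchored-base alleles.

## Concordance classification

Base level: the intersect is all positions callable in both samples
(optionally within target regions); concordant means equal base calls.
Variant level: positions called variant in both samples are concordant
iff the alternate alleles agree — genotype class is deliberately ignored
at this level, since call-level agreement is the quantity of interest;
genotype-class agreement is assessed separately in the array comparison.
FFPE-only calls are false positives, FF-only calls false negatives, FF
being the reference sample by convention. Swapping the sample labels
swaps FP with FN and preserves the rest (a tested symmetry). Both the
whole-intersect and the targeted-regions denominators are available via
the `regions` argument.

## Artifact spectra and statistics

Substitutions are collapsed onto the pyrimidine strand into six classes;
the C·G>T·A fraction is reported over all variant positions and over
disagreeing positions (for each side of the pair separately, with an
empty denominator reported as missing, never as zero). The global
mismatch rate excludes called-variant positions from its denominator so
true variants do not masquerade as mismatches; the exclusion set is an
explicit argument because upstream definitions vary. Context rates
classify every reference C (and complemented G) by 3′ neighbor
(CpA/CpC/CpG/CpT) and 5′ neighbor (ApC/CpC/GpC/TpC), in two modes:
call-level (fraction of eligible sites with a C>T call) and read-level
(fraction of read bases supporting T at eligible sites) — the read-level
CpG rate is a direct estimator of the deamination rate and recovers the
injected value within binomial error in the tests. Both modes are
provided because published per-sample rates are computed against
denominators that differ between studies.

Paired FF/FFPE group comparisons use the classical two-tailed paired t
test (all-zero differences give the degenerate p = 1 path; constant
non-zero differences are an error). Multi-group context comparisons use
one-way ANOVA followed by Dunnett contrasts against a control group; the
Dunnett adjustment is computed by seeded Monte-Carlo estimation of the
null maximum-|t| distribution (default 10⁵ draws) rather than
multivariate-t quadrature — deterministic given the seed, exact enough
at the precision these comparisons need, and cross-checked against the
`multcomp` single-step reference in the test suite. With a single
comparison it reduces to the unadjusted pooled t test.

## Filter sweeps

The sweep recomputes both samples' calls and the pair classification at
each grid value of one threshold, holding the others fixed; callable
intersects are exactly nested along the grid (tested). The
`vaf_relationship` table carries both samples' VAFs and depths at every
disagreeing position — recomputing the missing side's VAF from its
pileup — which exposes the dominant disagreement mechanism: calls that
exist in one sample and merely failed a coverage, mapping-quality or VAF
threshold in the other. For that reason, coverage-vs-discordance
analyses in this package pool the disagreement classes (discordant +
false positive + false negative) when comparing against concordant
positions; strictly both-called discordant sites are too rare under this
observation model to carry the low-coverage signal on their own.

Similarly, the artifact-localization experiment (FFPE-side C·G>T·A
excess at disagreeing positions) is run with the VAF filter disabled
(`min_vaf = 0`): under the standard >0.2 threshold a deamination rate of
a few percent produces allele fractions that can neither overtake a true
alternate allele nor pass the filter, so both-called discordance driven
by artifacts is essentially invisible post-filter. The unfiltered regime
corresponds to characterizing artifacts before hard filtering — which is
exactly where such filters are motivated.

## Somatic accounting

Germline subtraction is allele-aware: a tumor variant survives unless
the normal carries the same (position, alternate) pair; the same
position with a different allele is retained. Subtraction is idempotent.
Paired FF/FFPE somatic overlap counts shared positions and splits them
into concordant/discordant by allele equality. Recurrence filtering
takes annotation as an input table (functional annotation is out of
scope): synonymous variants are dropped, population frequency strictly
above 10% is dropped (exactly 10% is kept), variants present in the
supplied panel of normals are removed, and surviving variants carried by
at least `min_samples` samples are reported sorted by carrier count.

## Low-pass copy number

Counts are binned at a fixed width (default 15 kb, the terminal bin
truncated), GC-corrected by dividing each count by its GC-decile median
and rescaling to preserve the overall median (zero-median strata are
flagged and left uncorrected; simpler and fully deterministic compared
with loess), and converted to log2 ratios against the sample median
(zero-count bins masked by default). Segmentation is penalized binary
segmentation: greedy splits are accepted while the SSE reduction exceeds
`penalty × log(n)`, followed by backward pruning of breakpoints that no
longer pay their penalty. The penalty is an absolute scale in squared
log2 units — the default of 1 suits log2 noise SD around 0.2–0.5 (the
low-pass regime); cleaner data (e.g. deep bins with noise SD ~0.08)
warrants a proportionally smaller penalty. On short signals the
segmentation objective is verified against exhaustive search over all
segmentations. This is deliberately not circular binary segmentation:
boundary-exact parity with any particular production segmenter is a
non-goal, and agreement is asserted at the level of injected-truth
recovery. Gain/loss calls use inclusive thresholds of ±0.15 on segment
mean log2 — package defaults, as no canonical values exist for this
normalization. Region harmonization imposes the union of all samples'
breakpoints and recomputes region means per sample; clustering uses
Euclidean distance with average linkage, and sample similarity is
Pearson correlation over regions (choices made here, not dictated
upstream; zero-variance samples get missing correlations).

## Numerical and degenerate-input conventions

Empty denominators are reported missing (`NA`), never zero: concordance
with an empty intersect, C·G>T·A rate with no disagreeing positions,
Ts/Tv with no transversions, mismatch rate with no qualifying read
bases. Readers reject malformed input (negative counts, base counts not
summing to depth, unknown genotype classes, start ≥ end intervals) with
the offending line where applicable; an unknown key in a simulation
configuration file is a hard error so misspellings cannot silently fall
back to defaults. Exact ties are resolved deterministically everywhere
(documented per function).

## Problem sizes used in the tests

The shipped suite simulates genomes of 20 kb–1 Mb with per-position
coverage 20–200×, chosen so binomial/normal oracles have power at 3-SD
tolerances while the whole suite stays fast: the zero-artifact fidelity
check uses a 1 Mb pair at 80× (Poisson, so depth stays above 30
everywhere at this scale); deamination recovery uses ≥10⁶ CpG read
observations; the CNV pairing experiment runs 100 replicates of 7
matched pairs over 2,000 bins with log2 noise SD 0.2, with every truth
breakpoint changing copy state so each simulated tumor genuinely
carries aberrations. Statistical acceptance checks (two-proportion and t
tests at p < 0.01) are run at sample sizes where the simulated effect
is detectable by design.

## Known limitations

* Pileup-level modeling cannot express read-level error correlation,
  strand bias, or mapping artifacts; MAPQ is a per-position aggregate.
* The INDEL observation model is intentionally simple (support with
  probability = truth VAF) and carries truth sequences through the
  pileup; it validates classification logic, not INDEL caller accuracy.
* Somatic counts depend on the VAF threshold: truth variants with VAF
  near 0.2 drop out by binomial sampling even at high depth, so
  "exact" somatic recovery is only guaranteed for variants whose truth
  VAF clears the threshold with margin.
* Absolute copy number, ploidy and mappability tracks are out of scope;
  gain/loss calls are relative to the sample median.
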