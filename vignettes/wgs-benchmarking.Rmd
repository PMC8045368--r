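---
title: "Benchmarking clinical WGS: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking clinical WGS: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgsbench)
```

This vignette is the package's account of what it computes and why the
defaults are what they are. The package evaluates a clinical WGS pipeline on
five axes: small-variant concordance against a truth set, CNV detection
sensitivity across sequencing depths, breadth of coverage of disease-gene
panels, trio-derived truth sets, and compilation of the disease-gene panel
itself. Everything is exercised on synthetic data with recorded ground
truth; the final section is explicit about what that does and does not show
about real sequencing data.

## Coordinates and domain types

All internal coordinates are 0-based half-open (`[start, end)`), the BED
convention. VCF positions (1-based) are converted on ingest, so a call at
1-based position $p$ lies in `[start, end)` iff $start < p \le end$. A
single convention applied everywhere removes the classic off-by-one
ambiguity between VCF, BED and depth tables; the boundary behaviour is
pinned by regression tests (a call at position 100 is inside `[99,100)` and
outside `[100,200)`).

Chromosome names are compared as exact strings: the data decides whether it
says `chr1` or `1`, and aliasing is the caller's preprocessing, not
guesswork in the library.

Multiallelic VCF records are split into one normalized call per alternate
allele, with the genotype re-expressed relative to the focal allele (a `1/2`
genotype yields two heterozygous calls). Variant class is SNP iff both
alleles are single bases; multi-base same-length substitutions are folded
into the indel class rather than given a third category that every
downstream stratification would need to carry. No indel left-normalization
is performed: call representation is assumed consistent between truth and
query (true for a single-pipeline comparison, and controlled exactly in the
synthetic data).

## Small-variant concordance

Given truth and query call sets restricted to the same high-confidence
regions, calls match on the exact key (chrom, pos, ref, alt). Matching is
**genotype-aware by default**: a key match with differing zygosity counts as
a false negative *and* a false positive (and is tallied separately as a
genotype mismatch). Results are conventionally stratified by hom/het, and a
het call reported where the truth is hom-alt is a wrong clinical answer;
the permissive mode (`genotype_aware = FALSE`) is available and provably
never lowers any metric.

Per stratum (SNP/indel × hom/het) and overall:

- sensitivity $= tp/(tp+fn)$, PPV $= tp/(tp+fp)$;
- specificity $=$ (assessed reference positions called reference) /
  (assessed reference positions);
- accuracy $= (tp + \text{ref agree}) / (\text{truth variants} +
  \text{assessed ref positions})$.

Reference-site totals cannot be derived from variant records, so the caller
supplies them; the natural choice is (bases in confident regions) −
(truth variant sites). Sites removed by quality gating are excluded from
the accuracy denominator. Zero denominators yield `NA`, never errors.

Quality gates default to **GQ ≥ 20 and DP ≥ 10**, boundary-inclusive — the
standard clinical gates for germline short-variant calling; calls with
missing GQ/DP are dropped and counted. Matching is exact-key, not
haplotype-aware: complex regions where truth and query represent the same
haplotype with different record decompositions will be scored as
FN+FP. This is a known fidelity limit relative to hap.py-style comparison
engines and is the main caveat when interpreting absolute values on real
data.

## CNV benchmarking and the miss detection index

Truth CNVs match calls with **reciprocal overlap ≥ 0.5** of the same type
(DEL/DUP), the BEDTools `-f 0.5 -r` convention, boundary-inclusive because
the criterion is "at least 50%". Matching is many-to-one: sensitivity counts
truth recovery, not a bijection. Breakpoints are treated as exact; no slop
window is added.

Sensitivity is reported per size bin (`[lo, hi)`), since CNV callers behave
very differently below ~1 kb than above it. The default bin edges
(1 kb, 5 kb, 10 kb, 50 kb, 100 kb, 500 kb, 1 Mb, plus an open overflow bin)
are a reasonable general-purpose ladder, but they are a placeholder rather
than a canonical set — reproduction runs should state their own bins, and
the functions take them as an argument.

The **miss detection index** asks: across the (tool × call set × size bin)
grid, which mean depth is most often the *worst*? A cell group qualifies if
every depth has at least `min_truth = 10` truth events in the bin and the
sensitivity profile is not completely flat (a flat profile says nothing
about which depth is worst). For each qualified group, every depth attaining
the group minimum scores one minima event; MDI(depth) = M(depth)/N where N
is the total number of events. Ties therefore count every attaining depth
and each attaining depth increments N, which keeps $\sum_i \text{MDI}(i) = 1$
exactly — the tie rule is a deliberate choice where conventions could
differ, and it is what the brute-force re-count oracle implements
independently.

Consensus call-set compilation takes the union of several benchmark sets,
deduplicates within type at RO ≥ threshold (first-come along the sorted
genome), and annotates each retained CNV with the number of tools having a
detection at RO **strictly greater** than the threshold — the support rule
is deliberately strict where the matching rule is inclusive, mirroring how
the two rules are stated in their respective contexts; both are
parameters. Visual confirmation of copy-ratio plots cannot be automated
here, so every consensus record carries `needs_manual_review = TRUE`.

## Breadth of coverage

Breadth over a region set is the fraction of (merged) region bases with
depth ≥ t; bases absent from the depth table count as depth 0, which makes
the denominator the declared region, not the sequenced region. Depth
profiles carry their declared regions precisely so this convention is
unambiguous, and asking for breadth outside them is an error rather than a
silent 0.

The threshold comparison is `≥ t` (the ACMG-style "covered at ≥ 10X"
convention); a `strict_gt` flag switches to `> t` where a strictly-greater
reading is wanted. Per-gene coverage merges the union of all supplied
transcript exons per gene — transcript selection/priority is the input
file's responsibility, the denominators are whatever regions are supplied.
A gene is "fully covered" only at fraction exactly 1, so a single
uncovered exonic base disqualifies it.

DP/GQ distribution summaries use integer-binned histograms (bin width 1),
the **lower** of the two middle values as the median of an even-length
sample, and the **smallest** value on mode ties — fixed tie-break rules so
that summaries are reproducible across implementations.

## Trio-derived truth sets

At a locus where one parent is homozygous reference and the other
homozygous alternate, the offspring must inherit exactly one alternate
allele: heterozygous on autosomes. Such loci, gated at DP ≥ 10 and GQ ≥ 20
in **both** parents, form a family-derived truth set. Both gates are applied
because the analysis is only as good as the parental genotypes; each is
independently configurable.

Two interpretation decisions are worth surfacing:

- The hom-ref parent must carry an **explicit** reference call at the key.
  Single-sample VCFs usually omit reference sites, and treating absence as
  hom-ref would conflate no-calls with confident reference genotypes;
  `absent_as_hom_ref = TRUE` opts into that reading when the inputs warrant
  it. Keys with conflicting duplicate records are dropped.
- On chrX with a male offspring, only maternal-alt loci are informative
  (the X is maternal), and the expected state is hemizygous-alt;
  `autosomes_only = TRUE` drops X entirely.

Offspring sensitivity is (loci with a gate-passing expected-genotype call) /
(all loci); PPV conditions on loci with **any** gate-passing non-reference
offspring call, so a hom-alt miscall at an informative locus lowers both
metrics rather than silently leaving the PPV denominator.

## Disease-gene-list compilation

The rule engine consumes one normalized evidence row per gene (raw
Orphanet/OMIM/HGMD dumps are licensed and heterogeneous; adapters are out of
scope). A gene is retained iff any of criteria 1–5 fires and criterion 6
does not exclude it: (1) Orphanet status "assessed" with one of seven
accepted association types (exact, case-sensitive string match; the list is
extensible, unknown strings warn rather than error); (2) a GHR disease
gene; (3) OMIM with molecular basis known, unless the inheritance codes
(union across phenotype rows) are somatic-mutation-only ("SMu"); (4) an
HGMD probable/possible pathological variant; (5) a ClinVar
pathogenic/likely-pathogenic variant; (6) exclusion when the gene lacks
well-defined coordinates. An Orphanet "Candidate gene tested in" entry is
retained on its own, per the literal criterion list, without requiring
corroboration. Retention is monotone in evidence by construction, and the
32-case power set of criterion firings is pinned against a hand-written
truth table.

## Synthetic data: what it emulates and what it does not

Each generator takes a mandatory seed, uses one seeded RNG stream and no
other entropy (same seed ⇒ byte-identical outputs), and writes its ground
truth next to its data — both the *analytic* expectation and the *realized*
bookkeeping after its own coin flips, which the pipeline must reproduce
exactly.

- **Variants**: truth placed uniformly without collision on a featureless
  contig; query = truth − Bernoulli($p_{fn}$) misses + Poisson false
  positives at novel positions, with Bernoulli genotype flips and a
  configurable fraction of gate-failing GQ/DP draws. Expected sensitivity
  per stratum is $(1-p_{fn})(1-e_{gt})(1-f_{gate})$.
- **Depth**: i.i.d. negative-binomial depths (defaults mean 40, dispersion
  10 — overdispersed, as real WGS is) with a dropout fraction forced to
  zero, so expected breadth is analytic:
  $(1-d)\,P(\mathrm{NB} \ge t)$.
- **CNVs**: log-uniform sizes within bins, mostly deletions, generous
  spacing so a jittered call can only match its own event; detection is
  Bernoulli with probability increasing in depth, and jitter is validated
  against the RO threshold up front ($\mathrm{RO} \ge (1-2j)/(1+2j)$).
- **Trio**: informative loci with explicit parental hom-ref records plus
  het-het decoys; the offspring is called with rate $r$ and, when called,
  errs to hom-alt with rate $e$, so sensitivity $\to r(1-e)$ and PPV
  $\to 1-e$.

What passing these tests shows: the metric definitions, coordinate
handling, matching rules, gating and accounting are correct, and parameters
injected into data with known structure are recovered at binomial
precision. What it does not show: performance on real reads — alignment
artefacts, representation differences between callers, systematic
(GC-driven, mappability-driven) coverage bias, clustered rather than
uniform variant placement, and CNV breakpoint uncertainty are all absent
from the generators. Absolute sensitivities on real data are a property of
the pipeline under test, not of this framework.

## Problem sizes and numerical conventions

The test suite runs at deliberately modest scale — 50–60 randomized
concordance fixtures of ≤ 200 calls against exhaustive oracles, 10,000
truth variants per stratum for parameter recovery, 1,000 random interval
pairs for the reciprocal-overlap oracle, 20 seeded CNV grids of 200 events
per bin, a 1 Mb depth profile, and trios of 5,000 informative loci —
sizes at which binomial standard errors are small enough for 3-SE
assertions to be sharp, while the whole suite stays fast enough to run on
every change. Statistical recovery tests use 3-standard-error bands
(99.7% coverage per comparison). Determinism is asserted byte-for-byte on
data files and modulo the manifest timestamp on JSON reports.

Floating-point conventions: reciprocal overlap and MDI are exact rational
arithmetic on integer counts, so oracle comparisons use exact equality;
$\sum_i \text{MDI}(i) = 1$ is asserted to $10^{-12}$. Metrics with zero
denominators are `NA` throughout, never exceptions, so depth-titration
tables keep their shape even when a stratum is empty.

## Command-line use

The exported dispatcher `wgs_cli()` (wrapped by the `inst/cli/wgsbench`
script) exposes the stages as subcommands (`bench-small`, `bench-cnv`,
`mdi`, `coverage`, `dist`, `trio`, `compile-geneset`, `demo`) with
flag > config > default precedence, defaults mirroring the clinical gates
(GQ 20, DP 10, RO 0.5, coverage threshold 10), exit status 0/2 semantics
and JSON reports that embed a run manifest (version, parameters, input
digests, seed, timestamp). The `demo` subcommand simulates every input
format, re-reads it and runs all stages, which doubles as the end-to-end
determinism check.
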