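---
title: "Simulating and benchmarking somatic copy-number calling on targeted-capture data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and benchmarking somatic copy-number calling on targeted-capture data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Somatic copy-number alterations (SCNAs) — tumor-acquired amplifications and
deletions — are routinely called from whole-exome or gene-panel capture
sequencing, where coverage is sparse, unevenly distributed, GC-biased, and
where the signal of an event is diluted both by admixture with normal cells
and by subclonal structure within the tumor. Assessing how well a caller
copes with these effects requires data in which the complete set of true
events is known. `scnabench` provides that: a generative model of an
admixed, heterogeneous tumor–control pair with an exported gold standard,
plus an evaluation harness that scores any caller's segment output under
three complementary metric families.

## The generative model

**Genomes.** A toy reference (default: fourteen 1 Mb chromosomes with a
centromere at the midpoint, GC 0.45 controlled per 1 kb window) receives a
germline background — SNPs, indels, and copy-number variants at 90%
heterozygosity — to form the diploid control genome. Five "pure" tumor
genomes are derived by additionally implanting somatic events: per
replicate, 16 arm-length SCNAs (spanning ≥ 90% of a p or q arm; typed
amp/del with equal probability, since the design leaves arm-event type
unstated), 50 focal deletions and 50 focal amplifications. Amplifications
are tandem duplications: the extra copy (default exactly one, i.e. 2 → 3
copies on one haplotype — the most conservative reading of "tandem
duplication") is inserted immediately after its source interval, and a
liftover block map records that both copies project onto the source
reference interval. No two variants of any category touch the same bases on
the same haplotype, and copy-number events additionally never share
reference space even on opposite haplotypes: a het amplification over a
het deletion on the other haplotype nets out to normal copy number, which
would leave two typed gold events with no depth signal at all. Placement is
rejection sampling with an explicit error (never a silent under-count) when
the genome cannot host the request. Enforcing disjointness across *all*
categories lets each genome be built in one left-to-right pass and makes
"reference + germline + clone somatic" exactly equal to "control + clone
somatic".

Somatic events are assigned to clones privately (one uniform clone each) by
default; a `truncal_fraction` parameter shares events across all clones.
The design source does not say whether its events were truncal or private —
we default to private, the harder and more conservative setting.

**Reads.** Shearing draws fragment start points uniformly over the two
haplotypes (weighted by haplotype length, so duplicated material yields
proportionally more fragments — this is precisely how a tandem duplication
becomes extra depth) and insert sizes from a truncated normal (101 bp
reads; insert 300 ± 50 bp, exome-like; 200 bp for panel-like runs).
In-silico capture keeps a fragment if its reference projection overlaps a
padded target (±100 bp) by ≥ 1 bp, then retains it with probability
`max(0.1, exp(-((gc-0.45)/0.15)^2/2))` — a transparent parametric stand-in
for hybridization GC bias. Errors are uniform substitutions (0.1%/base)
with flat qualities: downstream SCNA evaluation consumes coordinates and
depth, not base qualities. Read names carry truth tags (source pool,
haplotype coordinates, reference projection), which makes the harness
alignment-free by construction; alignment was deliberately left out of
scope.

**Mixing.** A heterogeneous tumor is a multinomial draw over the five clone
pools at proportions (0.27, 0.29, 0.36, 0.06, 0.02). Admixture level `a`
replaces `round(a·n)` of the `n` tumor read pairs with control reads —
constant total depth, matching the interpretation of "adding X% control
reads" as contamination of a fixed-size library; the additive alternative
is not modelled. Each admixed tumor is paired with an independent control
sample of equal depth. The full design is 5 replicates × 10 levels
(0.0–0.9) = 50 pairs carrying 5800 somatic gold records.

**Allele fractions.** The expected allele fraction of a somatic variant is
`AF = (1−a) · Σ_{c ∈ clones(v)} p_c · z`, `z = 0.5` (het) or `1` (hom).
This linear purity–clonality–zygosity model is not printed in the source
design; it is the minimal model consistent with the heterozygous 0.5
ceiling (a fully clonal heterozygous variant in a pure tumor reads out at
AF 0.5). Germline records are returned undiluted (`z`), since control reads
carry them too.

## Evaluation

All comparisons restrict both sides to target space first — only events
touching capture targets are observable. Nucleotide metrics clip segments
to the targets; interval and gene metrics keep any segment overlapping a
target by ≥ 1 bp whole. Typing is two-class (amp/del); magnitude and
zygosity are ignored in matching.

| approach  | TP | precision | sensitivity |
|-----------|----|-----------|-------------|
| nucleotide | bases in same-type intersection | TP/PP | TP/GP |
| interval   | predictions covered ≥ 80% of their length by same-type gold union | TP/PP | TD/GP, TD = gold covered ≥ 80% by prediction union |
| gene       | genes covered ≥ 80% by both sides, same type | TP/PP | TP/GP |

Thresholds are inclusive (≥ 0.8). Denominators use unions of the same-type
counterpart set, not best single matches, so several small predictions
inside one large gold event receive full credit — the motivating
oversegmentation case. A zero denominator yields `NA`, which cohort
averages exclude (with the contributing `n` reported) to keep "no calls"
distinct from "all calls wrong". Stratified views: sensitivity by expected
allele fraction (bins 0–0.1–0.2–0.3–0.4 with everything above 0.4 pooled,
because heterozygous designs rarely exceed 0.5), counts by event size
(log-decade classes, each segment binned by its own length, TP status
independent of the matching event's class), and the log2 ratio of
predicted vs gold copy-number-altered gene counts with a low-burden flag at
≤ 10 gold events.

## The naive depth-ratio caller

`naive_depth_caller()` exists so the simulate → call → evaluate loop closes
without any external tool: per-target depth from truth tags, library-size
normalization by total on-target mass, `log2(tumor/control)` thresholded at
±0.3, runs of ≥ 2 consecutive out-of-threshold targets merged into
segments, targets with zero control depth masked. Two knowing limitations:
total-mass normalization shifts the background when a large genome fraction
is deleted (a unit test documents the artifact), and single-target events
are invisible by construction. A truncal heterozygous +1-copy amplification
yields ratio 1.5 (log2 ≈ 0.585): one extra haplotype copy against a diploid
background — this is the copy-count arithmetic the tests assert.

## What the synthetic world does and does not establish

The toy genome reproduces the *structure* of the benchmark — capture
sparsity, GC bias, purity dilution, clonal structure, tandem-duplication
depth signal — at megabase scale. It does not reproduce mappability
artifacts, alignment errors, real probe efficiency profiles, replication
timing or other wave biases, duplicate reads, or the true human size
spectrum of events up to 100 Mb. A green acceptance suite therefore
establishes internal correctness (count bookkeeping, metric definitions,
monotone degradation with admixture, deletions-easier-than-+1-amplification
ordering), not caller performance on real tumors.

The test fixture cohort makes its events truncal and its deletions
homozygous-biased; with the default private assignment and the design
proportions, a private event changes depth by at most ~9% — below any sane
threshold — and every directional statement about the naive caller would be
vacuously `0 ≤ 0`. The package default remains private.

## Numerical choices

* Coordinates are 0-based half-open everywhere, including all emitted BED
  files; the SEG adapter converts from 1-based closed on input only.
* Rejection sampling retries default to 1000 per requested variant;
  failure names the category.
* Per-source read counts round as `round(a·n)` with the complement taken on
  the other side, so totals are exact.
* Every stochastic stage takes an explicit seed; child seeds are derived
  arithmetically, so a cohort is byte-reproducible (truth files and FASTQ)
  from one master seed.
* Requested depth is converted to read pairs as `D·T/(2·read_length)`, with
  a pilot draw estimating capture retention for the pre-capture fragment
  budget.
* Fig-style summaries use log base 2 (configurable) for gene-count ratios;
  pseudocounts are off by default, so an empty side yields `NA` rather than
  an arbitrary value.

## Known limitations

No inversions, translocations or dispersed duplications; no indel
sequencing errors or duplicate reads; no amplicon library model; no BAM
ingestion (the harness is alignment-free by design, though callers that
emit SEG or BED-like segments can be scored regardless of how they were
run); no tumor-in-normal contamination of the control.
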