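---
title: "Modeling paralog-mediated rearrangement risk from DNA end resection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling paralog-mediated rearrangement risk from DNA end resection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogrisk)
```

## The problem

Budding yeast carries hundreds of paralogous genes that retain high
sequence similarity. Each of them is a potential ectopic donor for
homologous recombination: a double-strand break (DSB) that engages the
wrong family member can be resolved as a translocation. This package asks
a purely geometric question: *from what fraction of the genome can a
randomly placed DSB reach a highly similar paralog?* The answer depends
strongly on the repair geometry assumed, and on how long resection has
been running.

## Pairwise paralog similarity

Family members are compared by match-count global alignment: score 1 per
identical aligned base, 0 for mismatches and gaps. The optimal score under
this scoring equals the longest-common-subsequence (LCS) length, and
`match_count_alignment()` computes it by the standard dynamic program in
$O(|a|\,|b|)$ time (full, unbanded — gene pairs are a few kb and the
analysis is one-shot). Comparison is case-insensitive and `N` matches
nothing, so ambiguity codes in curated sequences never inflate scores.

The raw count is normalized to $[0,1]$ before thresholding. Three
conventions are implemented (`normalizer` argument):

* `"max"` (default): score / $\max(|a|,|b|)$ — conservative, penalizes
  length mismatch, and equals 1 exactly when the sequences are identical;
* `"min"`: score / $\min(|a|,|b|)$ — insensitive to truncation;
* `"alignment"`: score / alignment length ($|a|+|b|-\mathrm{score}$ under
  this scoring).

The retention threshold $\theta$ defaults to 0.7: pairs scoring below it
are dropped, and a gene is "highly similar" if it belongs to at least one
retained pair. Because the normalization convention behind a bare
threshold is genuinely ambiguous in the literature, the choice is exposed
rather than hard-coded; the default is the max-length convention since it
is the only one for which 1.0 certifies identity. Cross-family pairs are
not scored by default (the curated family structure defines the
comparisons of interest); `all_pairs = TRUE` enables the exhaustive mode.

## The two risk geometries

Both geometries work on half-open, 0-based intervals and report merged
base-pair totals over the genome length (the sum of the supplied
chromosome sizes; circular chromosomes are out of scope).

**Crossover (CO).** A crossover between paralogs needs the break strictly
inside the repeat, more than `margin` bp (default 300) from both edges.
A repeat $[s,e)$ contributes the eligible zone $[s+m, e-m)$, empty
whenever $e-s \le 2m$. Eligible zones of overlapping repeats are merged
before summing, so nested annotations are never double-counted.

**Resection exposure.** One-ended repair pathways only require the repeat
to be exposed as single-stranded DNA. Resection proceeds from the break
in both directions at speed $v$ (default 4000 bp/h), so at time $t$ each
side of the break has a tract of $L = vt$ bp. A position $x$ is at risk
if one of its tracts contiguously covers at least $E_{\min}$ bp (default
300) of a single repeat — exposure never sums across different repeats.
The closed-form at-risk set per repeat is

$$[s-(L-E_{\min}),\; e-E_{\min}) \;\cup\; [s+E_{\min},\; e+(L-E_{\min})),$$

clipped to the chromosome. It is empty when $L < E_{\min}$ or the repeat
is shorter than $E_{\min}$; the two arms coalesce once the repeat is at
least $2E_{\min}$ long, while shorter repeats keep an excluded central
band from which neither side can expose enough contiguous homology.
`risk_profile()` evaluates the merged union over a time grid (default
0–4 h in 0.1-h steps, bracketing the 1-h and 4-h anchor points commonly
discussed for resection kinetics) and also reports static repeat
coverage, the $t \to \infty$ floor of the repeats themselves.

Two switches change the rule deliberately:

* `mode = "naive"` extends every repeat by $L$ on both sides with no
  exposure requirement — a compatibility mode for comparison with
  simpler extend-and-merge analyses. It over-counts by $2E_{\min}$ per
  repeat flank and counts repeats shorter than $E_{\min}$.
* `both_ends = TRUE` requires both sides of the break to expose a repeat,
  the strict two-ended analogue. It is off by default because the
  one-ended pathways need a single usable end.

## Exact verification: the per-base oracle

The discretization that makes the closed form exact is the one genuinely
open numerical choice. `per_base_oracle()` simulates the break *in the
middle of base $i$* (continuous position $x = i + 0.5$) and measures the
continuous overlap of the tracts $(x-L, x)$ and $(x, x+L)$ with every
repeat. With integer interval bounds this convention makes the set of
marked bases exactly the half-open closed form above — no $\pm 1$
boundary slack — so the test suite can assert *exact* equality between
`resection_risk_fraction()` and the oracle on hundreds of randomized
genomes (tandem, overlapping and chromosome-edge-clipped repeats
included), and likewise between `co_risk_fraction()` and the margin
oracle, where "strictly more than $m$ bp from each edge" at $x = i+0.5$
yields exactly $[s+m, e-m)$. Placing the break at integer junctions
instead would add one base per arm end; at the scale of the reported
fractions the difference is immaterial, but exactness makes the oracle a
meaningful invariant rather than a tolerance test.

Merging everywhere is position-set union: adjacent half-open intervals
([0,10) + [10,20)) merge. `merge_intervals()` delegates to
`GenomicRanges::reduce()`, and the suite checks its totals against an
explicit position-set enumeration.

## What the synthetic generator emulates

`generate_genome()` stands in for a curated paralog annotation. Each
family derives its copies from one random ancestral sequence by
independent per-base substitution (uniform over the three alternative
bases) and single-base indels (half insertions, half deletions); under
the substitution process alone the expected per-site identity between two
copies is $(1-p)^2 + p^2/3$, which the generator records in its truth
table and the tests verify against an independent Monte-Carlo
simulation. Placement rejects overlaps; `tandem` mode plants a family as
one cluster with a fixed spacer, which is what exercises interval
merging. Intergenic sequence composition is irrelevant to the interval
math and is not modeled, and no codon- or chromatin-aware evolution is
attempted — so passing tests certify the interval arithmetic, the
alignment scoring and the estimator algebra, not biological realism of
the sequences themselves. One integer seed drives a single generator
stream; identical spec + seed reproduces outputs byte-for-byte.

`generate_assay_replicates()` emulates replicate assay measurements with
multiplicative lognormal noise of a stated coefficient of variation. The
noise multipliers have expectation 1 ($\mu = -\sigma^2/2$,
$\sigma^2 = \log(1+cv^2)$), so the *ratio of group means* is unbiased for
the planted ratio; the *mean of per-replicate ratios* carries the
classical lognormal ratio bias $e^{\sigma^2} \approx 1 + cv^2$ (+9% at
cv = 0.3). Both estimators are reported by `relative_level()`; the
fold-recovery tests therefore check the ratio-of-means form.

## Assay ratio statistics

All quantification contracts start at per-replicate signal quantities
(raw qPCR-to-signal conversion is upstream of this package). Group
summaries are arithmetic means with SEM; ratios are computed
per-replicate whenever a pairing is given, with ratio-of-means as the
unpaired fallback. The circularization-normalized recombinant frequency
keeps the loading control in its signature even though it cancels
algebraically, so inputs mirror what is actually measured. The
DSB-dependent translocation frequency subtracts the no-induction
background and floors at zero — the combination rule is a package
decision, which is why both raw frequencies are always reported
alongside. `rank_sum_compare()` mirrors common practice in this assay
literature: an exact two-tailed Mann–Whitney–Wilcoxon test, switching to
a two-tailed Student t-test when either group has fewer than 4
replicates, and returning p = 1 for identical constant groups. The exact
small-sample null is fully enumerated in the tests, which check that the
realized type-I error never exceeds the nominal 0.05.

## Problem sizes and defaults used in validation

The oracle-equivalence suite uses 200 randomized genomes of 1–3
chromosomes, 3–30 kb each, with up to 6 repeats per chromosome (50 bp to
2.5 kb, including edge-hugging and tandem placements) — small enough for
exhaustive per-base enumeration to stay an independent, fast oracle while
covering every clipping and coalescence branch of the closed form. The
acceptance script scales up to a yeast-scale stand-in: the 16
*S. cerevisiae* nuclear chromosome lengths carrying 90 three-copy
families of 1.35-kb genes (270 genes, ~3% of the genome, one third
tandem, substitution rate 0.03), which reproduces the qualitative
behaviour of a real curated paralog set: a CO-eligible fraction of
~1.7%, and an at-risk fraction expanding roughly ten-fold between the
static coverage and the 4-h resection horizon. Parameter-recovery checks
use a planted 7-fold ratio at cv = 0.3 with n = 8 over 200 seeds.

## Known limitations

* The DSB distribution is uniform — the most conservative assumption;
  breaks in real genomes cluster at transcribed and fragile loci, which
  would raise, not lower, the at-risk fraction near highly transcribed
  paralogs.
* Resection speed is a single constant; no per-locus kinetics, no
  slow-down at chromatin barriers.
* Homology-search efficiency, donor choice and repair outcome are not
  modeled: "at risk" means the geometry permits an ectopic engagement,
  not that one occurs.
* Circular chromosomes (e.g. mitochondrial) are rejected rather than
  modeled.
* The similarity stage scores nucleotide identity only; protein-level or
  affine-gap alignment is out of scope.
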