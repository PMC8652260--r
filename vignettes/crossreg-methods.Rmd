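---
title: "crossreg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crossreg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossreg)
library(data.table)
```

`crossreg` implements a comparative regulatory-element analysis for
ChIP-seq data: super-enhancer (SE) and broad-H3K4me3-domain (BD) calling,
cross-tissue specificity classification, and three-species
functional-conservation analysis with per-base conservation scoring. This
vignette documents the models, the tunable parameters, the numerical
conventions, and the design decisions that were genuinely open — in
enough detail that every output is reproducible from first principles.

## Coordinate and counting conventions

All intervals are 0-based half-open (`[start, end)`), the BED convention;
1-based formats (GTF, fixedStep WIG) are converted at the reader
boundary. Fragment counting uses feature-count semantics: a fragment
supports a region if it overlaps it by at least 1 bp; per-base pileup is
never used for rpm. rpm is `count * 1e6 / library_size`, with library
size supplied in a manifest (fragments may be a subsample of the
library). All outputs are made deterministic by a global tie-break of
(chromosome lexicographic, start, end) ascending.

## Peak-level filters

Two filters precede element calling. For tissues with two replicates,
`reciprocal_overlap_filter()` keeps a first-replicate peak when a single
second-replicate peak shares an intersection covering at least 50%
(`min_fraction`, inclusive) of *both* peaks; overlaps are never summed
across partners, and the output keeps the first replicate's coordinates
(the merged-vs-intersected question is left open by the usual protocol;
keeping one replicate's frame is the simplest deterministic answer). For
tissues without replicates, `top_n_by_signal()` keeps the 20,000
highest-signal peaks (`n`), breaking ties at the boundary rank by
coordinate so the count is exact.

## Super-enhancer calling

`call_superenhancers()` composes four steps:

1. **Stitching.** Enhancer peaks whose end-to-start gap is at most
   `max_gap = 12500` bp (inclusive — the plain reading of "within
   12.5 kb") merge transitively into stitched regions
   (`stitch_enhancers()`). No TSS-proximal exclusion is applied: the
   default-parameter workflow this reproduces does not use one.
2. **Scoring.** Each region gets `chip_rpm` and `input_rpm` by fragment
   counting; the control is subtracted directly on the rpm scale and the
   result floored at zero: `net = max(chip_rpm - input_rpm, 0)`. No
   additional scaling of the control beyond library-size normalization is
   applied.
3. **Ranking.** Regions are sorted ascending by net signal.
4. **Cutoff.** `hockey_stick_cutoff()` finds the point where the ranked
   curve has slope 1 after both axes are rescaled to a common span:
   with signals `s_1 <= ... <= s_N` the reference slope is
   `m = (s_N - s_1)/N`, and the tangent rank `x*` minimizes the number of
   points lying on or below the line of slope `m` through `(x, s_x)` —
   the line that touches the convex elbow of the hockey stick from
   below. Ties go to the largest rank. Regions with net signal strictly
   greater than `s_{x*}` are SEs; a region exactly at the cutoff is a
   typical enhancer (TE).

Two operational readings of the slope-1 tangent exist: minimizing the
points *above* the line (tangent from above) or minimizing the points *on
or below* it (tangent from below). The first is degenerate — the
maximum of the residual `s_j - m*j` always sits at or near the top rank,
so nearly every input would yield zero SEs. The second is the
field-standard realization (it is what the widely used ranking
implementation computes via `optimize()`), and it is what `crossreg`
implements, by exhaustive evaluation over all `N` candidates rather than
a local optimizer. Consequences worth knowing: a perfectly flat curve
returns the common value with zero SEs; a perfectly *linear* curve has
its minimal residual at rank 1 and returns `N - 1` SEs — linear inputs
have no elbow, and no tangent rule gives a meaningful answer there.
Negative net signals are clamped to zero before ranking.

## Broad-domain calling

`call_broad_domains()` ranks H3K4me3 peaks by width and takes the top
`fraction = 0.05` as BDs with `k = ceiling(fraction * N)`, so any
non-empty sample yields at least one BD and the count is exact under
boundary-width ties (resolved by coordinate). Note that `k` is a
property of the sample size: with 105 peaks, `k = 6`, so a panel with 5
planted broad domains always carries one genuinely-widest background
peak in its BD set. Peak intensity (`peak_intensity()`) is
input-subtracted rpm per base pair, `max(chip - input, 0)/width`. The
alternative reading of "normalized to the input" as a ratio was
considered and rejected to keep a single background-normalization
convention (subtraction) across both element types; a ratio switch can
be added without changing any interface.

## Gene association and expression

`assign_nearest_tss()` anchors each element at its coordinate midpoint
(`floor((start+end)/2)`) and assigns the gene with the closest TSS on
the same chromosome, any strand; strand only places the TSS (`start` for
`+`, `end - 1` for `-`). Midpoint was chosen over summit (no signal
available post-calling) or boundary (asymmetric); ties go to the
lexicographically smallest gene id. Elements on chromosomes without
genes stay unassigned and are excluded from expression comparisons, with
counts logged. RPKM uses the annotated gene-span length
(`count * 1e9 / (library_size * length)`), not union-exon length: the
supported annotation is a tabular gene model with an explicit length
column (or GTF gene records), which sidesteps exon arithmetic.

## Tissue specificity

Elements are first unified to a common width (`unify_width()`, default
2000 bp) centred on the midpoint, truncating at chromosome edges rather
than shifting — shifting would silently move midpoints and bias the
linkage step. `classify_specific()` then pools all tissues' elements of
one class and groups them by single linkage: two elements link when
their midpoints lie within `merge_distance` on the same chromosome. An
element is tissue-specific iff its group contains one tissue. The merge
criterion is centre distance, not overlap, mirroring the distance mode
of the standard peak-merging tool; the unified width and the distance
are deliberately independent knobs even though at the defaults (2 kb
width, `-d 2000`) linked elements necessarily overlap. The paired
SE-vs-TE (BD-vs-ND) comparison uses an exact two-sided Wilcoxon
signed-rank test on per-tissue fractions.

## Liftover and functional conservation

`parse_chain()` reads UCSC chain files and verifies both block-arithmetic
invariants per chain (sizes plus gaps must span the stated target and
query ranges). `liftover()` maps an interval through the
highest-scoring chain whose target span overlaps it: the match fraction
is the share of the interval's bases inside aligned blocks
(`min_match = 0.2` default, inclusive), and the mapped interval is the
span from the first to the last block-mapped query base — standard
span semantics, not fragmented output. Minus-strand chains reflect
alignment coordinates as `pos' = q_size - pos`. An interval passing
`min_match` on two chains with disjoint query spans is rejected as
`ambiguous_multiple_chains` rather than duplicated, mimicking default
liftover behaviour.

A focal-species element is *functionally conserved* when, after lifting
into the reference frame, it links (interval overlap of at least 1 bp by
default; a midpoint distance is available) to at least one
reference-species element *and* at least one third-species element of
the same class. Elements that fail liftover cannot be conserved but are
kept in the denominator, so conserved fractions are fractions of all
focal elements. Conservation scores (`mean_conservation_score()`) are
averaged over bases *with* data only, with the covered fraction reported
separately; an unscored element is `NA`, never 0. Scores are read from
fixedStep WIG or bedGraph (bigWig is out of scope as a binary format).
Elements are scored in the coordinate frame the track is supplied for —
the pipeline scores focal elements on the focal genome.

## Statistical components

`rank_sum_compare()` is a two-sided Wilcoxon rank-sum test. When both
groups have at most 8 observations the p-value is an exact enumeration
over all `choose(n+m, n)` rank splits using midranks, so tied data are
handled exactly (identical groups give exactly p = 1); beyond that, the
normal approximation with tie correction and no continuity correction is
used. `paired_fraction_test()` is the two-sided signed-rank analogue:
zero differences are dropped, an all-zero vector returns p = 1, the null
is enumerated exactly over all `2^n` sign vectors for up to 15 non-zero
pairs, and the normal approximation with tie correction is used beyond.
With only 2 pairs the smallest attainable exact p is 0.5, and with 6
uniformly-signed pairs it is `2/2^6 = 0.03125` — panel size bounds the
attainable significance.

## The synthetic-data generator

`generate_panel()` emits every input the pipeline consumes, with planted
truth, on three toy genomes (focal, reference, third; two ~5 Mb
chromosomes each) connected by constructed alignment chains (one of the
focal chains is minus-strand to exercise reflection). All elements sit
on a site grid inside aligned chain blocks with 25 kb pitch, so distinct
sites never stitch together (gap > 12.5 kb) and never merge at the
widest specificity distance (8 kb); shared sites recur at identical
coordinates in every tissue, private sites in exactly one. Fragments are
emitted as exact counts placed inside their peaks (a Poisson switch
exists but is off by default), and manifest library sizes are 1e6, so
rpm equals the fragment count and planted net signals are exact.

Defaults were chosen once as a desk-scale caricature of a real panel:
6 tissues; 100 background enhancer peaks plus 5 SE clusters (4 peaks of
1 kb, 2 kb gaps) per tissue, cluster net signal 10 times the strongest
background peak; 100 background H3K4me3 peaks (300-1000 bp) plus 5 BDs
at 3 times the maximum background width; privacy fractions SE 0.6 /
TE 0.4 / BD 0.2 / ND 0.1, preserving the SE > TE and BD > ND specificity
ordering seen in real tissue panels; conserved fractions SE 0.4 / BD 0.4
drawn from the shared-site pool so the flag is tissue-consistent;
baseline expression log-normal (meanlog `log 200`, sdlog 0.5) with an
8-fold boost for genes nearest planted SEs/BDs; conservation scores
~N(0.8, 0.05) for conserved and ~N(0.3, 0.05) for unconserved elements,
with a direction switch to plant the reversed pattern.

What the generator does *not* emulate: read-level noise and mappability
artifacts, overlapping or nested elements, signal gradients within
peaks, chromosome-scale covariates, or sequence content. A green
recovery test therefore establishes that the algorithms implement their
definitions exactly on cleanly separated inputs — not that the callers
are robust to the noise structure of real ChIP-seq, which is a property
of the upstream peak caller as much as of these rules.

## Known limitations

* The hockey-stick cutoff is meaningful only for elbow-shaped curves; on
  near-linear rankings the SE/TE split is arbitrary (as with any
  slope-based rule).
* Liftover returns spans, not fragment sets; an element spanning a large
  query-side insertion maps to a correspondingly large span.
* BD intensity normalization is subtraction, not ratio; samples with
  very deep input libraries may floor at zero.
* Desk-scale panels bound attainable p-values (see above); significance
  assertions in the tests are calibrated to the panel sizes actually
  generated, with directions asserted always.
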