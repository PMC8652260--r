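# crossreg

Comparative analysis of **super-enhancers (SEs)** and **broad H3K4me3
domains (BDs)** across tissues and species, as a tested, reusable R
pipeline.

Large clusters of enhancers with exceptionally high H3K27ac signal
(super-enhancers) and unusually broad H3K4me3 peaks (broad domains) mark
the genes that define tissue identity. Comparative studies ask, for a
focal species with a handful of assayed tissues: how many SEs/BDs does
each tissue have, how tissue-specific are they relative to their typical
counterparts (typical enhancers, TEs; narrow domains, NDs), and which of
them are *functionally conserved* — present as orthologous elements in
two other species — with or without underlying sequence conservation?
`crossreg` implements that full analysis from BED-level inputs, plus a
seeded synthetic-data generator with planted ground truth so every stage
is testable without any external download.

## The core rules

* **SE calling** (ROSE-style, from H3K27ac peaks and ChIP/input
  fragments): peaks within **12.5 kb** are stitched; stitched regions are
  scored by background-normalized signal, `net = max(rpm_ChIP -
  rpm_input, 0)` with rpm = fragments overlapping the region × 10⁶ /
  library size; regions are ranked ascending and cut at the point where
  the curve's slope is 1 after rescaling both axes — operationally, the
  rank `x*` minimizing the number of points on or below the line of
  slope `m = (s_N - s_1)/N` through `(x, s_x)`. Regions strictly above
  the cutoff are SEs; the rest are TEs.
* **BD calling**: the top **5%** broadest H3K4me3 peaks
  (`k = ceil(0.05 N)`, coordinate tie-break), with per-bp intensity
  `max(rpm_ChIP - rpm_input, 0) / width`.
* **Replicate handling**: peaks kept when replicates overlap **≥ 50%
  reciprocally**; without replicates, the top **20,000** peaks by signal.
* **Specificity**: elements unified to **2 kb** (also 4/8 kb) about their
  midpoints, pooled across tissues, single-linkage grouped at midpoint
  distance ≤ *d* (2000/4000/8000 bp); an element is tissue-specific iff
  its group holds one tissue. Paired Wilcoxon signed-rank across tissues
  compares SE vs TE (BD vs ND) fractions.
* **Conservation**: elements lifted between genomes through UCSC chain
  files with minimum match **0.2**; a focal element is functionally
  conserved iff its lifted coordinates overlap an element of the same
  class in *both* other species; per-element mean conservation scores
  (phastCons-style, in [0,1]) are compared between conserved and
  unconserved elements with a Wilcoxon rank-sum test.

## Worked example

Generate a synthetic six-tissue panel with planted truth, call SEs in one
tissue, then run the whole pipeline:

```r
library(crossreg)
library(data.table)

cfg   <- sim_config(seed = 42)
dir   <- file.path(tempdir(), "panel")
panel <- generate_panel(cfg, dir)

manifest <- read_manifest(file.path(dir, "focal", "manifest.tsv"))
peaks    <- read_bed(file.path(dir, "focal", "brain.k27.peaks.bed"))
se <- call_superenhancers(peaks,
                          load_fragments(manifest, "brain_k27_chip"),
                          load_fragments(manifest, "brain_k27_control"))
se
#> <se_call> 105 stitched regions: 5 SE / 100 TE (cutoff 18 at rank 100)
```

The five called SEs are exactly the five planted clusters: the strongest
background region nets 18 rpm (the cutoff, itself a TE under the strict
inequality), while the planted clusters net 192–276 rpm:

```r
se$superenhancers[, .(chrom, start, end, net_signal)]
#>     chrom   start     end net_signal
#> 1:   chr1 1235000 1245000        192
#> 2:   chr2 3285000 3295000        204
#> 3:   chr1 3720000 3730000        252
#> 4:   chr1 3105000 3115000        264
#> 5:   chr2 4895000 4905000        276

res <- run_all(read_run_config(file.path(dir, "run.yaml")))
res$elements[tissue == "brain"]
#>    tissue class   n median_width median_value median_rpkm p_value_vs_typical
#> 1:  brain    se   5      10000.0 252.00000000      75.200       0.0001621652
#> 2:  brain    te 100        910.5  12.00000000       9.875                 NA
#> 3:  brain    bd   6       3000.0   0.01933333      76.600       0.1991470895
#> 4:  brain    nd  99        644.0   0.01242236       9.300                 NA
```

SEs are an order of magnitude longer and stronger than TEs and their
associated genes are expressed ~8-fold higher (rank-sum p < 0.001),
mirroring the structure planted by the generator. Conservation
classification recovers exactly the planted three-way orthologs:

```r
res$conservation[tissue == "brain",
                 .(class, n_conserved, n_total, fraction)]
#>    class n_conserved n_total  fraction
#> 1:    se           2       5 0.4000000
#> 2:    bd           2       6 0.3333333
```

(The sixth BD is the genuinely widest background peak — `ceil(0.05 N)`
at work, see the methods vignette.) `run_all()` also writes
`elements.tsv`, `specificity.tsv`, `specificity_tests.tsv`,
`conservation.tsv`, per-class element BEDs and a run log under the
configured output directory.

## Command line

A thin CLI wraps the same functions (`inst/cli/crossreg`; after
installation, `system.file("cli", "crossreg", package = "crossreg")`):

```sh
crossreg simulate --out-dir panel --seed 42
crossreg run --config panel/run.yaml
crossreg call-se --peaks X.bed --manifest mani.tsv --chip s1 --control s2 \
                 --max-gap 12500 --out-prefix X
crossreg call-bd ... ; crossreg specificity ... ; crossreg conserve ...
```

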