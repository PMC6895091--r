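---
title: "Methods: variant-centric nucleosome occupancy and chromatin-state annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant-centric nucleosome occupancy and chromatin-state annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucsnp)
```

# The analysis

`nucsnp` asks a simple question about each variant in a region of interest:
does it sit on a nucleosome, and in what chromatin state? The pipeline takes
aligned single-end MNase-seq reads (as BED6), anchor sites (SNPs, TSSs),
histone-mark peak sets, and position weight matrices, and produces occupancy
tracks, site-anchored metaprofiles, per-variant Poisson occupancy calls with
a cross-cell-type consensus, chromatin-state labels including bivalency, and
ref/alt motif delta scores.

## From reads to occupancy

MNase protects ~147 bp of nucleosomal DNA; a sequencing read marks one end
of that protected fragment. Each read is therefore replaced by a 73 bp
interval shifted 36 bp in the read's 3' direction:

* `+` strand read starting at $s$: fragment $[s+36,\; s+109)$
* `-` strand read ending at $e$: fragment $[e-109,\; e-36)$

For a read sequenced from the end of a 147 bp mononucleosomal fragment this
places the interval's centre at the nucleosome **dyad** (~72.5 bp from the
5' read end), so per-base coverage of the transformed fragments —
*nucleosome occupancy* — peaks over dyads. The original read length is
discarded; with zero positional noise the coverage maximum is an exactly
dyad-centred plateau, and total coverage mass equals 73 bp per read when no
fragment is clipped at a chromosome end. Fragments running past chromosome
ends are clipped rather than dropped, preserving counts near the boundaries
of small fixtures.

For display and cross-sample comparison a track is rescaled by its own
genome-wide maximum count times 100, so every non-empty normalized track has
maximum exactly 100. Each sample is normalized independently before any
comparison across cell types. Statistical testing always uses the raw
counts: the 0–100 scale is not a count and has no Poisson interpretation.

## Metaprofiles and periodicity

The profile around a site set is the per-offset mean of the track over all
sites, strand-aware (windows of `-` strand anchors are mirrored), with
offsets spanning `±flank` (default 1000 bp, enough to cover an NDR plus a
five-nucleosome array). Sites whose window leaves the chromosome are dropped
with a warning rather than zero-padded — padding would deflate the mean near
fixture edges.

`detect_periodicity()` estimates the nucleosome repeat length as the lag
maximising the autocorrelation of the mean-subtracted profile. The lag-$k$
statistic is the cosine similarity of the two overlapping profile segments,
which is bounded in $[-1, 1]$ and — unlike the conventional $1/n$-normalized
estimator, whose edge bias shifts the argmax off the true period for finite
windows — equals 1 exactly at the period of a periodic signal. A constant
profile returns score 0 and no period.

## The Poisson occupancy test

With $\lambda$ the genome-average per-base count and $k$ the count at the
SNP base, the point probability is
$P(k) = e^{-\lambda}\lambda^{k}/k!$. Two modes are exposed:

* **upper-tail** (default): $P(X \ge k)$, a proper p-value, non-increasing
  in $k$;
* **pmf**: the literal $P(k)$, retained for fidelity with analyses that
  threshold the point mass directly. It is not monotone in $k$ and is small
  for *every* $k$ once $\lambda$ is large, so it is flagged in output and
  not the default.

A site is called occupied when $p \le \alpha$ (default $\alpha = 0.05$, raw —
no multiple-testing correction by default, matching the classical single-site
cutoff; a Benjamini–Hochberg flag exists). $k$ is the count at the single
SNP base by default; a `window` option substitutes the local maximum within
`±window` bp. $\lambda$ is estimated genome-wide from the raw track
(per-chromosome estimation is available). Both choices matter for power: a
73 bp fragment covers only `±36` bp around its dyad, so with single-base
counts a SNP more than ~37 bp from the dyad receives no nucleosomal signal
at all. In the synthetic benchmark, where on-nucleosome SNPs are placed
uniformly within `±40` bp of dyads, roughly 7% of them are geometrically
undetectable; the measured sensitivity of ~0.9–0.95 reflects that geometry,
not miscalibration, and `window = 5` or more recovers those sites.

The **consensus** rule across cell types is the strict conjunction: a SNP is
consensus-occupied only if significant in every cell type.

## Chromatin-state annotation

Site-versus-peak overlap uses BEDTools-default semantics: at least 1 shared
bp between half-open intervals, strand-blind; a point site overlaps a peak
iff the peak contains its base (site at peak start: hit; at the half-open
end: miss). A `slop` parameter widens peaks for "near a peak" annotation
(default 0; proximity has no canonical distance). Open-chromatin and repeat
annotations are the same machinery applied to other peak sets.

States follow the mark partition — activating `{H3K27ac, H3K4me1, H3K4me3,
H3K36me3}`, repressive `{H3K27me3, H3K9me3}`:

| membership | state |
|---|---|
| ≥1 activating and ≥1 repressive | bivalent |
| activating only | active |
| repressive only | repressed |
| none | none |

Every membership vector maps to exactly one state. H3K36me3 is placed in the
activating set as a transcription-elongation mark; the partition is a plain
argument, so reclassifying it is a one-line change. A mark in neither set is
a configuration error rather than silently ignored.

## TF-motif delta scores

PWMs are pseudocount-regularised probability matrices over A/C/G/T (columns
sum to 1) scored as $\sum_j \log_2 (p_j(b_j) / 0.25)$ against a uniform
background — no background model is assumed beyond base equiprobability.
`score_variant_tf_effect()` scans both strands at every offset of the ref
and alt windows and reports the change in the best match score; scores are
reverse-complement invariant by construction. Windows must differ at exactly
one base.

# The synthetic-data generator

The generator emulates the canonical promoter architecture: a
nucleosome-depleted region (NDR) centred on each TSS, flanked by
well-positioned −1/+1 nucleosomes whose footprints abut the NDR edges, and
an equally spaced downstream array. Defaults, chosen once as typical of
vertebrate MNase-seq:

| parameter | default | meaning |
|---|---|---|
| `ndr_width` | 140 bp | nucleosome-free span centred on the TSS |
| `spacing` | 200 bp | centre-to-centre repeat length of the array |
| `n_array` | 5 | array nucleosomes beyond the +1 |
| `fuzziness_sd` | 10 bp | Gaussian jitter of each dyad |
| `occupancy_prob` | 0.9 | chance a template carries each nucleosome |
| `background_rate` | 0.01 /bp | uniform non-nucleosomal reads |
| `depth_per_nucleosome` | 50 | mean fragments per occupied nucleosome |
| `read_length` | 36 bp | emitted single-end read length |

Each nucleosome sheds `Poisson(depth × occupancy_prob)` fragments of 147 bp
centred on its (jittered) dyad, read from a uniformly chosen end with the
matching strand; the background is strand-balanced uniform, the simplest
null consistent with the homogeneity assumption of the Poisson test. SNPs
are planted either within ±40 bp of a dyad (`on_nucleosome`) or ≥100 bp from
every dyad (`in_linker`), and peak sets place one fixed-width peak on each
covered site so that bivalency arises exactly where two marks share a site.
All generators are pure functions of their inputs and a seed.

What the generator deliberately does **not** emulate: sequence-level output
(reads are emitted pre-aligned as BED; alignment is out of scope), MNase
digestion sequence bias, paired-end fragments, mappability gaps, copy-number
variation, diploid genotypes, and inter-nucleosome spacing irregularity
beyond independent Gaussian dyad jitter. Passing tests therefore demonstrate
the correctness of the transforms, statistics and logic — not robustness to
the full messiness of real MNase-seq libraries.

# Numerical and design choices

* **Coordinates** are 0-based half-open (BED) throughout; a BED SNP's anchor
  is its `start`. WIG output is 1-based as the format requires, fixed-step
  with `span = step = bin` (default 200 bp) and a trailing partial bin
  averaged over its actual width.
* **Degenerate inputs**: an all-zero track normalizes to all zeros without
  division errors but is rejected for λ estimation; a constant profile
  returns periodicity score 0; empty BED files parse to empty tables;
  `alpha = 1` marks every site occupied.
* **Ties**: the periodicity argmax takes the smallest best lag; occupancy
  plateaus are reported as-is (callers who need a point dyad estimate should
  use the plateau midpoint).
* **Reproducibility**: every stochastic stage takes an explicit seed; the
  pipeline derives per-stage streams from one master seed and logs them, so
  identical configs give byte-identical result tables.

Problem sizes used by the test-suite benchmarks (20 promoters on a 300 kb
chromosome, 40+40 SNPs, 3 cell types, 5 replicate seeds; 10,000 null sites
on 1 Mb for calibration) were chosen so the whole suite documents the
method at meaningful statistical resolution while remaining quick to run on
a laptop.

# Worked example

```{r example, eval = FALSE}
cfg <- run_config(out_dir = tempfile("nucsnp_run"), seed = 7)
res <- run_pipeline(cfg)

table(res$states$state)
head(res$consensus)
plot(res$profiles_tss[[1]])
detect_periodicity(res$profiles_tss[[1]], 150, 250)
```

# Limitations

The Poisson model assumes a homogeneous background; real genomes violate
this through mappability and copy-number structure, so on real data a local
or GC-stratified λ would be more defensible than the genome-wide mean. The
single-base count is faithful to the classical definition but, as noted,
blind to SNPs near fragment edges. Chromatin-state calls are binary
overlap logic over pre-called peaks — they inherit whatever threshold the
peak caller applied and make no use of signal strength. Motif delta scores
rank candidate TF-binding disruptions; they are not binding-affinity
measurements.
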