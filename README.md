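# nucsnp

Variant-centric nucleosome occupancy and chromatin-state annotation from
MNase-seq.

Regulatory interpretation of disease-associated SNPs often starts with two
questions: *is the variant packaged in a nucleosome*, and *what chromatin
state surrounds it*? `nucsnp` answers both from standard inputs — aligned
single-end MNase-seq reads (BED6), anchor sites (SNPs/TSSs as BED),
histone-mark peak sets (BED) and plain-text PWMs — and ships a synthetic-data
generator that emulates promoter nucleosome architecture, so the entire
pipeline is testable without downloading any sequencing data. It is aimed at
computational biologists who have peak calls and aligned MNase reads in hand
and want reproducible, scriptable variant annotation.

## Method

**Occupancy.** Each read is replaced by a 73 bp fragment shifted 36 bp
3'-ward (`+` read at *s* → [*s*+36, *s*+109); `-` read ending at *e* →
[*e*−109, *e*−36)), centring the fragment on the nucleosome dyad of the
147 bp footprint it came from. Occupancy at a base is the number of
fragments covering it; tracks are normalized to 0–100 by the genome-wide
maximum for display, never for testing.

**Poisson occupancy call.** With λ the genome-average per-base count and
*k* the count at the SNP base,

> P(k) = e^−λ λ^k / k!

the default test is the upper tail P(X ≥ k); a site is *occupied* when
p ≤ α (default 0.05). A SNP is **consensus**-occupied only if significant
in every cell type.

**Chromatin state.** Site/peak overlap follows BEDTools defaults (≥ 1
shared bp, half-open, strand-blind). Sites carrying both an activating mark
(H3K27ac, H3K4me1, H3K4me3, H3K36me3) and a repressive one (H3K27me3,
H3K9me3) are called **bivalent**; otherwise active, repressed or none.

**TF motifs.** Ref and alt windows around a variant are scanned on both
strands at all offsets with log2(p/0.25) PWM scores; the delta of the best
scores ranks candidate binding-site disruptions.

## Worked example

```r
library(nucsnp)
cfg <- run_config(out_dir = "nucsnp_run", seed = 7)   # 300 kb genome, 20 TSSs,
res <- run_pipeline(cfg)                              # 80 SNPs, 3 cell types

table(res$states$state)
#>    active  bivalent      none repressed
#>        22        28        16        14

detect_periodicity(res$profiles_tss$lymphoblastoid, 150, 250)
#> $period
#> [1] 203        # bp — the simulated array spacing is 200 bp
#> $score
#> [1] 0.563
```

The TSS profile shows the expected nucleosome-depleted region (mean
normalized occupancy 8.9 over ±50 bp of the TSS against a +1-nucleosome
peak of 66.2), and the repeat length estimate recovers the 200 bp array
phasing. Of the 40 SNPs planted on nucleosomes, 36 are consensus-occupied
across all three simulated cell types at α = 0.05; none of the 40 linker
SNPs are. Per-cell-type occupancy calls, the consensus table, chromatin
states, TF delta scores, WIG tracks and a parameter-complete run log are
written to `out_dir`.

A command-line driver with `simulate`, `track`, `profile`, `test`,
`annotate` and `run` subcommands is installed at
`system.file("scripts/nucsnp.R", package = "nucsnp")`.

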