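# fmphase

Tools for resolving the complex duplication–inversion rearrangement at the
chicken fibromelanosis (*Fm*) locus from long-read alignments, and for the
windowed population-genetic sweep scan used around it.

## The problem

Black-bone chicken carry a rearranged haplotype of a ~1.2 Mb region on
chromosome 20 in which two non-paralogous segments — Dup1 (~127 Kb,
containing *EDN3*) and Dup2 (~170 Kb) — are each duplicated around a
single-copy intermediate segment (Int, ~412 Kb). The rearrangement creates
two carrier-specific junctions, A: `Dup1.END–Dup2.END`
(Dup1 + inverted Dup2) and B: `Dup1.START–Dup2.START`
(inverted Dup1 + Dup2). Three arrangements are compatible with those
junctions and copy numbers; they differ only in which neighbourhood each
copy of a duplicated region occupies:

```
N    : Flank1 – Dup1 – Int – Dup2 – Flank2
Fm_1 : Flank1 – Dup1 – inv(Dup2) – inv(Int) – inv(Dup1) – Dup2 – Flank2
Fm_2 : Flank1 – Dup1 – inv(Dup2) – Dup1 – Int – Dup2 – Flank2
Fm_3 : Flank1 – Dup1 – Int – Dup2 – inv(Dup1) – Dup2 – Flank2
```

Because both copies of a duplicated region co-align to the same reference
interval, position cannot separate them — but allele linkage on long reads
can. The package implements that inference chain:

* **coverage breakpoints** — windowed depth contrast between carriers and
  non-carriers, refined to base pair by a one-step changepoint snapped to
  the clip-pile depth jump;
* **junction reads** — region labeling of split alignments and an
  orientation grammar classifying junction-spanning reads as A, B, native
  or unclassified;
* **read-backed phasing** — candidate het sites (≥10 reads per allele,
  tri-allelic sites excluded), per-pass allele labels, 4×4 site-pair
  linkage counts, and two-chain haplotype extension (≥5 supporting passes
  per step) from an automatically selected seed;
* **scenario inference** — phased haplotypes anchored to their neighbour
  contexts, tested against candidate arrangements (and diploid
  arrangement pairs) by canonical-context consistency;
* **popgen scan** — per-window π, Watterson's θ, Tajima's D, Fu & Li's
  D*, Hudson's F_ST (ratio of averages), D_xy, with 80%-callability and
  0.1-repeat-fraction window filters, top-1%/top-10% empirical outlier
  calling, per-site F_ST > 0.9 fixed sites, private-allele counts, and
  unpolarized iHS / XP-EHH from EHH integrals;
* **synthetic data** — a seeded generator for rearranged diploid genomes,
  planted copy-distinguishing het sites, junction-splitting long reads,
  breakpoint-stepping short-read depth, and multi-population phased
  panels (neutral SFS + Balding–Nichols drift + optional planted sweep),
  each with full truth tracking.

## Worked example

Simulate an `Fm_2/N` heterozygote at the default 1/10-scale locus and
resolve its genotype from the long reads alone:

```r
library(fmphase)

cfg <- sim_config(seed = 42, arrangements = c("Fm_2", "N"))
sim <- simulate_locus_sample(cfg)
aln <- assign_blocks(sim$long$alignments, cfg$map)
res <- resolve_locus(aln, cfg$map)

res$junctions
#>            A            B       native unclassified
#>           29           31            2            0
res$contexts
#>   region haplotype left_region left_orient right_region right_orient support
#> 1   Dup1         A      Flank1           +         Dup2            -      10
#> 2   Dup1         B        Dup2           -          Int            +      15
#> 3   Dup1         B      Flank1           +          Int            +      15
#> 4   Dup2         A        Dup1           -         Dup1            -       9
#> 5   Dup2         B         Int           +       Flank2            +      30
res$genotypes[res$genotypes$consistent, ]
#>   hap1 hap2 consistent
#> 4    N Fm_2       TRUE
```

Reading the output: 29 reads span junction A and 31 junction B, so the
sample carries the rearrangement. Phasing Dup1 yields one haplotype
anchored `Flank1 → inverted Dup2` and a second whose passes split between
`inverted Dup2 → Int` and the native `Flank1 → Int` — the signature of a
heterozygote, whose *N* chromosome shares the ancestral allele class with
one duplicated copy. Those contexts are jointly consistent with exactly
one diploid genotype, `Fm_2/N`; every other arrangement pair is rejected.
The short reads agree:

```r
prof <- window_coverage(sim$short$reads, map_span(cfg$map))
classify_carrier(prof, res$junctions, cfg$map)$evidence$dup1_ratio
#> [1] 1.509615   # ~1.5x relative depth: duplicated on one chromosome
```

The GRCg6a coordinates of the real locus ship as the default map:

```r
fm_region_map()
#> <region_map> 20: 10263555-11980000
#>   Flank1     10263555 -   10766771  (503,217 bp)
#>   Dup1       10766772 -   10894151  (127,380 bp)
#>   Int        10894152 -   11306685  (412,534 bp)
#>   Dup2       11306686 -   11477501  (170,816 bp)
#>   Flank2     11477502 -   11980000  (502,499 bp)
```

See `vignettes/fm-locus-methods.Rmd` for the models, parameter rationale
and limitations.

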