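---
title: "Resolving the fibromelanosis duplication–inversion locus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving the fibromelanosis duplication–inversion locus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmphase)
```

## The problem

The fibromelanosis (*Fm*) locus on chicken chromosome 20 is a complex
duplication–inversion rearrangement: two non-paralogous segments, Dup1
(~127 Kb, containing *EDN3*) and Dup2 (~170 Kb), are each present in two
copies in black-bone chicken (BBC), separated by a single-copy ~412 Kb
intermediate segment (Int) and bracketed by ~500 Kb flanks. Carriers show
two junctions absent from the un-rearranged (*N*) arrangement:

* **junction A** — Dup1's end joined to Dup2's end (Dup1 + inverted Dup2),
* **junction B** — Dup1's start joined to Dup2's start (inverted Dup1 + Dup2).

Three arrangements (`Fm_1`, `Fm_2`, `Fm_3`) are compatible with those two
junctions and the copy numbers (Dup1 = 2, Dup2 = 2, Int = 1). They differ
in *which neighbourhood* each copy of a duplicated region occupies, and
that is what the package infers: it reconstructs copy-specific haplotypes
of each duplicated region from long reads aligned to the un-rearranged
reference, anchors them to their neighbouring segments, and tests which
candidate arrangement(s) the anchored contexts permit. A windowed
population-genetic scan with the same filtering and outlier rules used in
BBC sweep analyses completes the toolkit.

## The arrangement model

An `arrangement()` is an ordered list of oriented segments; `Flank1` is
always first and `Flank2` last, both forward. The built-ins are:

```{r}
for (s in c("N", "Fm_1", "Fm_2", "Fm_3")) print(fm_arrangement(s))
```

`Fm_2` and `Fm_3` are fully determined by the haplotype anchors reported
for the locus: in `Fm_2` the distal half (Dup1, Int, Dup2, Flank2)
resembles *N*; in `Fm_3` the proximal half does. `Fm_1` is encoded as a
single duplication–inversion event placing an inverted (Dup2 + Int + Dup1)
block — ~709 Kb at full scale — between the two native-like outer copies;
this is the unique single-event layout with the required copy numbers and
junction set.

Two algebraic devices make inference orientation-proof:

* **Canonical adjacencies.** The junction between consecutive segments is
  the unordered pair of segment ends that meet; an adjacency equals its
  mirror image, so `enumerate_adjacencies()` is invariant under reading a
  haplotype from the other end. Novelty is defined against the *N*
  adjacency set.
* **Canonical copy contexts.** Each occurrence of a region is described by
  its left and right neighbours *in the copy-forward reading frame*
  (flipping an inverted copy swaps and re-orients its neighbours). A copy
  and its reverse-complement reading therefore yield the same context.

`scenario_consistency()` follows elimination logic: a candidate is
consistent iff every observed context equals one of its copy contexts.
Observing both Dup1 contexts of a carrier rules out `Fm_3`; adding the
Dup2 contexts leaves only `Fm_2`:

```{r}
cands <- lapply(c("N", "Fm_1", "Fm_2", "Fm_3"), fm_arrangement)
obs <- all_copy_contexts(fm_arrangement("Fm_2"), c("Dup1", "Dup2"))
scenario_consistency(obs, cands)[, 1:2]
```

A diploid exposes the union of two arrangements' contexts, so
`infer_genotype()` scores unordered arrangement pairs and requires set
equality (everything observed is explained *and* everything implied is
observed). The completeness half is what distinguishes an `Fm_2`
homozygote from an `Fm_2/N` heterozygote, whose *N* chromosome must also
show native contexts.

## The synthetic-data generator

`simulate_locus_sample()` builds, under one seed, a diploid sample at a
1/10-scale locus (Dup1 12,738 bp; Int 41,253 bp; Dup2 17,081 bp; flanks
50 Kb — full-scale coordinates work identically, scaled sizes keep a full
pipeline run in seconds):

* **Haplotypes.** Each chromosome's sequence is the concatenation of its
  arrangement's segments over a random reference, with a piecewise
  monotone projection map to signed reference intervals (the truth
  lift-over).
* **Heterozygous sites.** Inside each duplicated region, sites are planted
  at 1% density with two ancestral allele classes: copy 1 carries class 1
  and copy 2 class 2 on every carrier chromosome, and an *N* chromosome's
  single copy carries the ancestral-like class 2. The two copies of a
  region therefore differ at every planted site. This mirrors what the
  ~1% observed heterozygosity in a carrier *is* — divergence between the
  two duplicated copies — and is what makes copy-specific haplotypes
  phaseable at all; a fully independent per-copy draw would create more
  than two lineages per reference interval, which the two-chain extension
  procedure (and the underlying biology of a single duplication event)
  does not describe. Outside the duplications, ordinary chromosome-level
  het sites are planted at 0.2%.
* **Long reads.** Log-normal lengths (median 20 kb, so reads sometimes
  span a scaled duplicated region and sometimes do not — extension, not
  single-read spanning, is exercised; a `mega_reads` mode lifts the median
  above the region size), 5% i.i.d. substitution error, 60× diploid depth.
  Reads are placed on their chromosome and decomposed into
  reference-forward alignment blocks via the projection: colinear,
  reference-contiguous blocks are merged (a read crossing a native border
  aligns as one block, as a real aligner reports it), so only true
  rearrangement junctions split an alignment. SAM round-trip I/O keeps the
  block geometry exact.
* **Short reads.** 150 bp pairs at 30× diploid depth; junction-crossing
  reads keep every within-segment piece of at least 20 bp (clipped primary
  plus seedable supplementary), so relative depth steps exactly at the
  breakpoints (2× over duplications in a homozygote, 1.5× in a
  heterozygote).
* **Panels.** `simulate_panel()` draws neutral allele counts from the
  neutral site frequency spectrum (weight 1/i), induces differentiation
  Balding–Nichols style with an independent drift parameter per population
  (monomorphic redraws stay inside the drift model so the realized F is
  unbiased), and optionally plants a sweep by copying one donor haplotype
  into a configured fraction of a population across a window.

What the generator does **not** model: indel or homopolymer errors,
chimeric reads, alignment jitter at junctions, GC-coverage bias,
recombination/coalescent ancestry within populations, and gene conversion
between copies. Green tests therefore certify the algorithms under clean
alignment geometry and i.i.d. substitution noise, not performance on raw
field data.

## Coverage breakpoints

`window_coverage()` counts reads per 1 Kb tiled window (a read counts once
in every window it overlaps) and normalizes by the median window count —
the median rather than the mean so the duplicated windows themselves do
not distort the normalizer. `detect_boundaries()` calls a boundary where
the case's two-window side means differ by ≥ 1.5× while every control
stays quiet at the same position. Two deliberate choices:

* The 1.5 threshold sits halfway between single-copy (1×) and the
  heterozygote/homozygote duplicated levels (1.5×/2×); no published
  numeric criterion exists for "drastically different", so it is exposed
  as a parameter.
* The contrast is measured over two windows per side rather than the bare
  adjacent pair: paired-end reads double the window-count variance, so a
  single noisy pair can fake (or, at a window-edge breakpoint, dilute) the
  one-window ratio. Partial trailing windows are excluded; same-direction
  calls within two windows collapse to the strongest.

`refine_breakpoint()` then fits a one-step mean model to per-base depth in
a ±2 Kb window (least squares via cumulative sums) and snaps the
changepoint to the strongest direction-consistent single-base depth jump
when that jump carries at least half the fitted step. The snap matters:
coverage noise is correlated over a read length, which limits the plain
least-squares changepoint to roughly ±(read length) at 30×, whereas
junction-clipped read ends pile on the exact breakpoint base — with the
snap the simulated breakpoints are recovered exactly at 200× and within a
read length at 30×. The mean-shift/SD confidence score comes from the
least-squares fit; flat windows are left unrefined.

`classify_carrier()` combines both evidence types and treats junction
reads as primary: a heterozygote at ~1.5× relative depth fails the 1.6×
depth ratio but is carried by its junction-read support, while a
depth-only signal with zero junction reads (a shared or unrelated CNV) is
called non-carrier and flagged discordant.

## Junction reads

`assign_blocks()` labels each alignment block with its majority-overlap
region (blocks under 200 bp stay unlabeled; 80% inside a region makes the
label confident). `classify_junctions()` walks each Dup1–Dup2-spanning
read in read order and applies the orientation grammar: a forward Dup1
block exiting at Dup1.END joined to a reverse Dup2 block at Dup2.END
(signature `START-DUP1-END|END-DUP2-START`) is junction A; the mirrored
start-to-start pattern is junction B; a colinear same-strand traversal
through Int is native; junction-side endpoints further than 100 bp from a
region border leave the pair unclassified. Reads are canonicalized so a
read and its reverse-complement reading classify identically, and a long
read crossing both junctions (common at scaled size) contributes one call
per junction it spans.

## Read-backed phasing

The two copies of a duplicated region co-align to the same reference
interval, so position cannot separate them; allele linkage can. The chain
is the published procedure, made deterministic:

1. `pileup_counts()` — per-base A/C/G/T support from the alignment blocks.
2. `call_het_sites()` — a candidate site needs ≥ 10 reads per allele for
   exactly two bases; a third base at ≥ 10 reads marks the site
   tri-allelic and excludes it.
3. `label_reads()` — the labeling unit is an alignment *pass*, not a read:
   a read traversing the inverted Dup2 copy crosses Dup1's interval twice
   with different alleles on each pass, and collapsing those passes would
   poison the pair counts.
4. `pair_matrix()` — the 4×4 count of base combinations at a site pair.
5. `extend_haplotypes()` — from a seed outward in both directions, accept
   the nearest site whose pair matrix with the frontier has one cell per
   chain at ≥ 5 passes, distinct alleles between chains, and every other
   cell in those rows at most 20% of its row's accepted cell. The support
   floor is the published rule; the 20% noise ceiling is this package's
   formalization of the manual inspection of the 16-cell counts (accepted
   cells must dominate their rows). Rejected candidates are skipped, and a
   side with no acceptable next site ends as a flagged fragment.
6. `select_seed_site()` replaces visual inspection: the called site
   nearest a region border with ≥ 5 border-extending passes per allele
   and balanced allele support (minor/major ≥ 0.25 — a genuine het site at
   full depth is roughly balanced, while an error pile that reaches the
   10-read floor is strongly skewed). If a chain still stalls below half
   the candidate sites, `phase_region()` retries from up to three
   alternative seeds and keeps the longest chain. Ties in candidate order
   break toward higher support, then lower position, so phasing is
   invariant to read input order.

`anchor_haplotypes()` follows the passes that carry a haplotype's terminal
alleles across the region borders — native block crossings and junction
splits both yield a (neighbour, orientation) context in the canonical
region-forward frame. Passes reaching both borders give full
(left | right) contexts directly, and every full context with ≥ 5
supporting passes is emitted; this matters for heterozygotes, where the
shared-allele class genuinely mixes two physical lineages and must show
*both* of its contexts. The anchored contexts feed
`scenario_consistency()`/`infer_genotype()`, and `resolve_locus()` wires
the whole chain together.

## The population-genetic scan

Windows are tiled 50 Kb from position 1 (the last partial window is kept
but flagged). `window_filters()` excludes windows below 80% callable
fraction or above 0.1 repeat fraction — both masks are consumed as BED
inputs, never computed here. Per window and population,
`diversity_stats()` reports S, π (mean pairwise differences per effective
site), Watterson's θ (S / (a_n · effective sites)), Tajima's D (1989
constants), and Fu & Li's D* in its outgroup-free singleton form — the
starred variant is the only one computable from a folded spectrum, so it
is what a folded pipeline's "Fu and Li's D" can mean, and outputs label it
D*. `differentiation_stats()` uses Hudson's F_ST as a *ratio of averages*
per window over sites polymorphic in the pair (negative estimates are
preserved; a window of literally duplicated samples scores the analytic
−1/(n−1)) and D_xy over all sites per effective site. Outlier calling is
the empirical-quantile rule: top 1% of passing windows for F_ST, top 10%
for D_xy, bookended windows merged. `fixed_sites()` applies the per-site
F_ST > 0.9 rule, and `private_alleles()` counts alleles present in a
focal population and absent from all comparison populations, honouring an
exclusion list of known positions.

Haplotype statistics are computed unpolarized. EHH at distance d is the
probability two random carrier haplotypes are identical from the core out
to d; iHH is its trapezoid integral over physical distance, truncated
where EHH drops below 0.05 or an inter-site gap exceeds 200 Kb. iHS is
ln(iHH_majority / iHH_minority) — the majority allele plays the ancestral
role — standardized within 20 equal-frequency minority-allele bins;
XP-EHH is the log-ratio of pooled-core integrals (EHHS normalized to 1 at
the core) between two populations, standardized genome-wide. Cores whose
minor allele has fewer than two carriers are skipped. `sweep_report()`
assembles merged F_ST outliers annotated with the corroborating
statistics (π ratio, focal Tajima's D, |iHS|, XP-EHH, D_xy top-decile
membership, distance to Dup1) and ranks by F_ST.

## Numerical and design notes

* All coordinates are 1-based inclusive internally; BED I/O converts to
  0-based half-open at the boundary. Region length is end − start + 1,
  and quoted sizes use the floor-Kb convention (127,380 bp → "~127 Kb").
* Determinism: every simulation entry point takes a seed and reproduces
  byte-identical output; the inference path contains no randomness.
* Default parameters — 1 Kb coverage windows, ratio 1.5, depth-ratio 1.6,
  ≥ 3 junction reads, min 10 reads/allele, min 5 passes/step, 100 bp
  junction tolerance, 200 bp minimum block — are package choices where
  the published pipeline states none, each exposed as an argument.
* Validation problem sizes (chosen to keep the full suite comfortably
  under desk-scale runtimes): 20 seeded pipeline runs across the five
  genotype settings, 20-seed phasing and breakpoint checks at 30×/200×,
  100 random panels against brute-force estimator oracles, and
  10,000-site panels for drift recovery and neutral calibration.
* Known limitations: no indel realism or alignment jitter (junction
  tolerances are therefore generous rather than estimated), no
  genotype-likelihood estimation path (called, phased genotypes are the
  input), no polyploid support, and arrangement inference assumes the
  five-region locus decomposition is given.
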