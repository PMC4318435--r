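---
title: "Methods: nucleosome calling, remodeling detection, and motif statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome calling, remodeling detection, and motif statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucdyn)
```

# The model

`nucdyn` analyses MNase-digestion tiling-array data for *Arabidopsis
thaliana* under control and salicylic-acid (SA) treatment. The primary
observable is the per-probe *enrichment value*: the log2 signal of
mononucleosomal DNA over sheared genomic DNA, measured at ~35-bp probe
pitch in three biological replicates per condition. The pipeline makes four
kinds of inference, each with explicit, auditable rules rather than a
probabilistic model — the design goal is reproducibility of a rule-based
analysis, not optimal positioning.

## Nucleosome calling

A probe *qualifies* at stringency level $s$ when its enrichment value is
$\ge s$ in **every** replicate (implemented as the per-probe replicate
minimum $\ge s$; the comparison is inclusive). Seven levels are swept:
$s \in \{0.0, -0.01, -0.1, -0.5, -1.0, -1.5, -2.0\}$, and $-1.0$ is the
conventional working level. A maximal run of consecutive qualifying probes
(adjacent in track order, start-to-start gap $\le$ 50 bp) of length
$\ge 4$ becomes a region.

**Region extent.** Each qualifying probe claims a pitch-wide tile
$[p, p + 34]$, so the region runs from the first qualifying probe start to
the last start + 34. This is the only convention under which a 4-probe run
spans 140 bp and a 5-probe run 175 bp — consistent with the classification
bands: spans in $[131, 161)$ bp are **distinct** nucleosomes, spans
$\ge 161$ bp are **fuzzy**. The two bands meet at 161 bp; we resolve the
overlap half-open (161 bp is fuzzy). Spans below 131 bp, which can arise
with irregular pitch, have no defined category and are discarded but
counted (the `discarded` attribute).

**Gap rule.** The 50-bp `max_probe_gap` breaks runs across tiling holes
(repeats, centromeres) instead of bridging them. The source analysis is
silent here; bridging arbitrary holes would manufacture continuous
occupancy out of missing data, so breaking is the conservative choice.

**bp per nucleosome.** The summary statistic divides chromosome size by the
*count* of called regions. The defining text says "divided by the total
region covered", but the reported genome figure (~346 bp per nucleosome)
only follows from the count; we implement the count and keep the literal
per-base ratio behind `per_base = TRUE`.

## Remodeling

Control and treated region sets (distinct and fuzzy pooled — type is
irrelevant to base accounting) are merged per chromosome and compared at
base resolution: *depleted* = control-only bases, *enriched* =
treated-only, *common* = both. The accounting identity
$\text{remodeled} = \text{total} - \text{common}$ holds by construction,
and `genome_remodeling_summary()` expresses the three sets as genome
percentages ($\%\text{unique} = \%\text{NOR} - \%\text{common}$). Base
resolution means a shifted nucleosome contributes both depleted and
enriched bases — deliberately, since the downstream accounting is stated in
bases, not region identities.

## TSS-anchored profiles

Forty 50-bp windows tile $-1000..+1000$ bp around the TSS in TSS-relative
space: upstream window $k$ covers offsets $[-50k, -50k + 49]$ with label
$-(50k - 25)$ (so $-75$ means $-100..-51$), downstream window $k$ covers
$[50(k-1), 50k - 1]$ with label $50k - 25$; the TSS base (offset 0) sits in
window $+25$. A window scores 1 when a **single** region covers $\ge 25$
contiguous bp inside it; fragments summing past 25 bp do not count. Genes
whose $\pm 1000$ bp spans overlap another gene's span are removed — both
members of the pair, following the source's filtering — before group
averaging.

**Significance.** A 150-bp block (three windows, one nucleosome length)
slides across the profile; per block, each replicate contributes its mean
coverage, computed from regions called on that replicate *alone*, and a
two-sample Student's t (N = 3 per group) compares groups. The consensus
all-replicates call cannot supply three observations per window, so the
per-replicate calls are our reading of the stated N = 3 design — recorded
as an assumption. The slide step defaults to one window (50 bp); a
full-block step is available (`step = 3`) since the source does not say
which was used. Multiple testing uses Benjamini–Hochberg by default with a
Storey option at fixed $\lambda = 0.5$ ("Q-value package" is named without
parameters; BH is the conservative, parameter-free default). Zero-variance
blocks: equal means give $p = 1$ by convention; unequal means with zero
variance are flagged and given the smallest positive double, so perfectly
separated noise-free groups remain significant instead of crashing the t.

## Expression classes

From the 2×2 genotype (Col-0, npr1-1) × treatment design: SI requires
Col-0 log2 FC $\ge 2$ with $p \le 0.05$, SR $\le -2$ (we read "fold change
$\le -2$" as log2, by symmetry with the explicitly log2 up-regulation
rule); SIL/CON require *every* Col-0 replicate value of both treatments
$\le 0$ / $\ge 3$. The differential-expression p is a plain two-sample
Student's t between Col-0 control and SA replicates — the original's
moderated array statistics are out of scope and this substitution is
documented, not hidden.

The per-gene two-way ANOVA uses the classical fixed-effects decomposition
(df 1, 1, 1; error $4(r-1)$). *SA-regulated* means treatment-effect
q $\le 0.05$; *NPR1-dependence* p comes from the genotype×treatment
**interaction** (a genotype-main-effect alternative is exposed via
`dependence_term`), with ND at $p \le 10^{-4}$, NI at $p \ge 0.1$, and the
gap in between left `unclassified` — the source defines no category there.
With zero error variance (noise-free synthetic data) F is formally
undefined; we resolve $p = 0$ when the effect sum-of-squares is positive
and $p = 1$ when it is zero, flagged `degenerate`, which makes planted
noise-free classes recover exactly.

## Motif statistics

For a region class with base frequencies $F$ over $T$ counted bases
(N bases excluded) and a motif of length $N$:

$$E = \frac{\prod_{i=1}^{N} F(b_i)}{N} \cdot T$$

The division by $N$ is almost certainly a transcription artifact of the
source formula — the textbook sliding-window expectation has no such term —
but the source's observed/expected tables were produced with it, so we
implement it **as printed** and expose `standard_expectation = TRUE` to
drop it. The measurable consequence, asserted by a seeded Monte-Carlo test:
the corrected frequency (observed/E) of a motif over i.i.d.
composition-matched sequence converges to $N$, not 1. Ratios of corrected
frequencies between classes are unaffected by the constant.

Occurrences are counted overlapping (step 1) on the promoter strand only —
reverse-complement counting is not mentioned by the source. An occurrence
is assigned to the region class containing its 5′-most base, making
straddling occurrences uniquely classified. Promoter classes partition each
1000-bp promoter: NOR = occupied under both conditions, remodeled =
occupied under exactly one, NFR = occupied under neither ("free under
either condition" is ambiguous; only this reading partitions). The 95% CI
is a Wilson score interval on observed/$T$, rescaled by $T/E$ to the
corrected-frequency axis — the source names no interval method, and Wilson
behaves at zero counts. The hexamer screen covers all $4^6$ hexamers;
ratios add a pseudocount of 1 to every observed count so hexamers absent
from one set stay defined, and a hexamer "passes" when both the
observed/expected ratio and the lift (frequency relative to background)
ratio reach the fold cutoff of 2.

# The synthetic world

The generator states one fixed world; its defaults are not tuned to tests.

| parameter | default | why |
|---|---|---|
| `probe_pitch` | 35 bp | the array's stated resolution |
| `replicate_count` | 3 | the study design (also used for expression) |
| `noise_sd` | 0.3 log2 | realistic post-normalization replicate scatter |
| `nucleosome_signal_mean` | +0.5 log2 | with background −3.0, the seven thresholds (0.0..−2.0) span the separation |
| `background_mean` | −3.0 log2 | below the loosest threshold |
| `effect_size_log2fc` | 3 | comfortably past the ±2 classification cutoff |
| `group_fractions` | 0.25 each | balanced SI/SR/CON/SIL |
| `motif_plant_rate` | 2 per kb NFR | a few planted sites per promoter over background |

Planted structure: every gene gets a stable gene-body nucleosome
(fuzzy-scale, +300..+540 from TSS); SI genes carry a promoter nucleosome
(−215..0) in control only, SR genes in treated only, CON in both, SIL in
neither; intergenic 4-tile (distinct) and 6-tile (fuzzy) runs are planted
between gene slots, some condition-specific. Expression cell means follow
the class (ND genes lose the response in npr1-1; NI genes are exactly
additive, so their interaction is zero by construction). W-box/TGA motifs
are planted only inside truth-NFR promoter segments of SI/SR genes. All
draws come from one RNG stream keyed by the seed in a fixed order, so equal
seeds give checksum-identical files.

The note on expression replicates: the study profiled RNA in two biological
replicates; the simulator uses the track design's three, because a single
`replicate_count` governs both and N = 3 matches the stated t-tests. The
classifiers accept any $r \ge 2$.

What the generator does **not** emulate: probe-sequence cross-
hybridization, GC bias, MNase sequence preference, spatially correlated
noise, partial occupancy, and overlapping gene architecture. A green test
therefore establishes that the *rules* are implemented correctly and
recover planted truth under i.i.d. Gaussian noise — not that the rules are
optimal on real arrays.

# Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive throughout (TAIR convention), fixed by
  the worked PR1 arithmetic (6,241,704..6,243,463 = 1760 bp); BED export is
  0-based half-open.
- Threshold comparisons are inclusive ($\ge$), as stated.
- An empty track yields an empty region set, not an error; an unsorted
  track is a validation error (the reader sorts, so this only arises with
  hand-built inputs).
- Zero called regions make bp-per-nucleosome `Inf` with a warning rather
  than an error, so sweeps over strict thresholds complete.
- Interaction sums-of-squares are floored at 0 against round-off.
- Promoter intervals clip at chromosome bounds with a warning; a TSS with
  zero upstream room is an error.
- p-value adjustment caps q at 1 and is exactly BH when Storey's
  $\hat\pi_0 = 1$.

# Known limitations

- The caller is rule-based; it neither deconvolves overlapping nucleosomes
  within fuzzy regions nor estimates dyad positions.
- The distinct/fuzzy bands assume ~35-bp pitch; heavily irregular pitch
  pushes runs below 131 bp, which are discarded (and counted) rather than
  reclassified.
- The moderated-statistics machinery of the original expression analysis is
  substituted by a plain t-test; borderline SI/SR calls can differ.
- Motif statistics reproduce the source's formula family, including its
  $/N$ constant; absolute corrected frequencies are therefore comparable
  within this package, not across tools.
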