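---
title: "Methods: combinatorial NF-kB occupancy and regulation modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial NF-kB occupancy and regulation modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfkbmap)
```

## The scientific problem

NF-kB signalling acts through dimers assembled from a small set of subunits.
The canonical pathway centres on p50–RelA, the non-canonical (NIK/IKKa-driven)
pathway on p52–RelB, but in cells with constitutive NF-kB activity — Hodgkin
lymphoma being the extreme case — all four subunits are nuclear at once and
bind the genome in overlapping, combinatorial configurations. The question
this package addresses is: *given where each subunit binds (four ChIP-seq
cistromes) and which genes respond to knocking down each pathway (two
knockdown transcriptomes), which combinations of subunits, at which genomic
positions, predict that a gene is regulated — and do those in vitro target
genes behave consistently in primary lymphoma expression data?*

The package implements that integration as a reusable pipeline with six
analysis stages plus a synthetic-data generator that plants a known ground
truth through all of them.

## Occupancy coding

Per-subunit peak sets are unified by single-linkage merging: any group of
intervals (from any subunit) connected by pairwise overlaps of at least
`min_overlap` bp (default 1) becomes one region. Each unified region gets a
4-bit pattern code in the fixed subunit order p50, p52, RelA, RelB — `"1100"`
is p50+p52, `"1010"` p50+RelA, `"0101"` p52+RelB. Merging the union, rather
than anchoring on one subunit, treats every region that is a peak for at
least one subunit symmetrically. The summit of a merged region is the summit
of its strongest contributing peak (by score), falling back to the midpoint;
coordinates are 0-based half-open everywhere, with GFF3 converted on load.

Occupancy profiles (enrichment in 20 bp bins over summit ± 500 bp, per
subunit) can be attached and clustered with k-means, `k = 8` by default.
`stats::kmeans` with 10 random restarts (best within-cluster SSE kept) under
a fixed seed is used; restarts play the role a careful seeding strategy
(k-means++) would, and the result is deterministic given the seed.

## Region-to-gene assignment

A region is linked *proximally* to every gene whose TSS lies within
`proximal_window` (default 5 kb) of its summit, and *distally* to a gene
when it overlaps one anchor of a chromatin loop whose other anchor lies
within `proximal_window` of that gene's TSS, with
`proximal_window < |distance| <= max_distal` (default 250 kb). When DHS
sites are supplied, distal links additionally require the region to fall in
open chromatin; proximal links stand on TSS distance alone, since distance
to the promoter is already strong evidence. Distances are signed (upstream
negative, strand-aware). Multi-gene links are retained — downstream models
aggregate per (gene, stratum), so no "nearest gene wins" heuristic is
needed. The window defaults are configurable and recorded in every run log;
they are pragmatic choices for a toy-scale genome, not biological constants.

## Knockdown differential expression

The knockdown design has four groups: Group1/Group2 are control/knockdown
for p50+RelA (canonical), Group3/Group4 for p52+RelB (non-canonical), each
experiment tested strictly within itself, never with pooled controls. Per
transcript cluster a two-sample t-test is computed (Welch by default — the
safer choice when variances may differ; a pooled-variance flag exists), and
Benjamini–Hochberg adjustment is applied per experiment across all tested
clusters. A gene is *regulated* when at least one of its transcript
clusters has FDR < 0.05 **and** at least a 10 % expression difference. The
10 % rule is interpreted on the linear intensity scale, implemented as
`|dlog2| >= log2(1.1) ~ 0.1375`, since arrays are analysed in log2 but an
"expression difference" reads most naturally as linear; both thresholds are
arguments. Direction follows the sign of control minus knockdown: a gene
whose expression falls upon knockdown is *activated* by NF-kB.

A *direct target* is a regulated gene bound by the pathway-defining subunit
among its assigned regions: p50 for canonical, p52 for non-canonical.

## The combinatorial logistic model

The core model asks which (pattern, stratum) combinations predict
regulation. For each gene with at least one assigned region, binary
features indicate "has at least one linked region with exactly this 4-bit
pattern in this stratum" (at most 15 patterns x 2 strata). Four contrasts
are modelled: non-canonical vs none, canonical vs none, canonical vs
non-canonical, and activated vs repressed. For the *-vs-none contrasts the
negatives are *bound but unregulated* genes — the model asks what separates
bound-and-regulated from bound-only, not bound from unbound (an all-genes
alternative is a one-line change). Genes regulated by both pathways count
as canonical in the canonical-vs-noncanonical contrast, and genes whose two
pathways disagree in direction are excluded from activated-vs-repressed.

One joint maximum-likelihood logistic regression per contrast is fitted
with intercept (`stats::glm`); coefficients are log odds ratios with Wald
95 % confidence intervals and P values, significance at P < 0.01. Features
never observed among the contrast's rows are reported as *missing* rather
than extrapolated, and features causing perfect separation are likewise
reported missing (detected via exploded standard errors) instead of
returning a divergent estimate; an optional ridge-stabilised fit (quadratic
penalty, penalised-Hessian standard errors) is available when a finite
answer for a separated feature is wanted.

Stability is scored by the nonparametric bootstrap: genes are resampled
with replacement `B` times (default 1000), the model refitted, and each
feature's stability is the fraction of resamples with P < 0.01; features
at or above 90 % are flagged stable. Note that a null feature's stability
is centred on its *sample* estimate, not on zero — its expected stability
is ~0.07 rather than 0.01 — so stability summaries across simulated
replicates should average over datasets.

The prototypic-dimer readout extracts the `1010` (p50–RelA alone) and
`0101` (p52–RelB alone) features as the headline negative control: in data
generated with those coefficients at zero they must come out
non-significant.

## What the synthetic generator emulates

`simulate_genome()` places genes on a toy chromosome (single chromosome by
default — all interval logic is chromosome-wise anyway) with alternating
strands, 1–3 transcript clusters per gene and a simple exon/intron body.
`simulate_cistrome()` plants regions with configurable pattern frequencies
(defaults echo the qualitative spectrum seen in HL cells: p50/p52 dominate,
the two singletons together near 41 %, RelA least frequent), places them
proximally (uniform ± 2 kb of the target TSS) or distally (uniform
10–100 kb, with an emitted loop to the target promoter), and draws each
bound gene's regulation per pathway from a logistic model on its true
features — the generative coefficients default to the qualitative structure
the pipeline is meant to detect (p50+p52 with RelB and the full complement
drive regulation; canonical effects proximal-only; prototypic dimers null).
Regulation is drawn only for genes with at least one planted region, so
every planted regulated gene is bound. `simulate_knockdown_expression()`
plants the corresponding shifts on a Normal(8, 1) log2 baseline;
`simulate_lymphoma_panel()` plants a deterministic fraction of direct
targets as concordant (shifted with their NF-kB direction in HL samples)
and the rest anti-concordant, with a fraction of background genes below the
log2 = 6 expression floor.

Placement is deliberately unambiguous so planted truth is exactly
checkable: TSSs are at least 20 kb apart, proximal placements cannot reach
a neighbour's 5 kb window, distal placements are rejected within 6 kb of
any TSS, and planted regions never come within 200 bp of each other (more
than twice the 25 bp peak-boundary jitter), so unified regions map 1:1 to
planted regions. What the generator does *not* emulate: read-level noise,
fragment-length or GC effects, peak-calling artefacts, correlated probe
noise, batch effects, or multi-mapping ambiguity. Passing tests therefore
demonstrate that the analysis logic is correct and calibrated, not that it
is robust to upstream artefacts real data would carry.

## Numerical and design choices

* **Validation fixture noise.** The end-to-end fixture (220 genes, 370
  regions, on the order of 80 direct targets and 40 concordant genes) uses
  near-noiseless expression (sigma = 0.02 log2 for the knockdown, 0.05 for
  the panel, effects of 2–3 log2 units). At realistic noise an FDR-based
  caller has a nonzero false-positive rate and exact truth recovery would
  be a coin flip; the fixture validates bookkeeping, while calibration
  under realistic noise (sigma = 0.25, effect 1) is tested separately.
* **Simulation scales.** Calibration runs use 2000 transcript clusters at
  6 vs 6 samples; parameter recovery uses 50 replicates of 2000 genes;
  bootstrap stability uses B = 200 in the test suite (B = 1000 remains the
  analysis default). These sizes give Monte-Carlo error comfortably inside
  the asserted bounds while keeping the suite quick.
* **Coverage accounting.** Empirical CI coverage is pooled over features
  and replicates; per-feature coverage from 50 replicates is too granular
  to bound tightly (a perfectly calibrated feature hits 50/50 about 8 % of
  the time).
* **Ties and degenerate input.** Region sorting breaks ties by (chrom,
  start, end); expression rows constant in both groups get P = 1 when means
  agree and P = 0 when they differ; the best-evidence cluster for a gene is
  the lowest q, then largest |difference|; all-zero occupancy rows cannot
  occur by construction.
* **Determinism.** Every stochastic step takes an explicit seed; the
  pipeline fans a master seed out per stage by a stable string hash (kept
  below 2^31), run directories are write-once, and run logs record
  parameters and input MD5 hashes but no timestamps, so a rerun with the
  same configuration is byte-identical.

## Known limitations

Open questions inherited from the problem setting are resolved as explicit
conventions rather than recovered facts: the loop-anchor interpretation of
3D-architecture evidence, the 5 kb/250 kb window defaults, linear-scale
reading of the 10 % rule, Welch rather than pooled t-tests, and the joint
(rather than per-feature) logistic fit are all package choices, each behind
an argument. The *-vs-none contrasts condition on the other pathway's
status; when the two pathways share predictive features this selection
shifts the identified coefficients away from the generative ones, which is
why quantitative parameter-recovery checks use the single-outcome design
generator and the cistrome-driven end-to-end check asserts sign and
significance only. The concordance stage matches array-era expression
panels; probe-set remapping across platforms is out of scope.

## A minimal run

```{r example, eval = FALSE}
dir <- tempfile()
files <- write_synthetic_dataset(file.path(dir, "data"), seed = 1)
out <- run_pipeline(files$config, file.path(dir, "run"))
res <- attr(out, "results")
summary(res$`fit_noncanonical-vs-none`)
head(as.data.frame(res$targets))
head(as.data.frame(res$concordance))
```
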