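# nfkbmap

Integration of multi-subunit NF-κB ChIP-seq cistromes with knockdown
transcriptomes and lymphoma expression signatures.

## The problem

NF-κB acts through dimers of a small subunit family — p50, p52, RelA, RelB —
activated by two routes: the canonical pathway (p50–RelA) and the
non-canonical, NIK-driven pathway (p52–RelB). In cells with constitutive
NF-κB activity, such as Hodgkin-lymphoma cells, all four subunits bind
chromatin simultaneously and combinatorially, and the pathway a gene answers
to cannot be read off from which single subunit sits at its promoter.
`nfkbmap` is for computational biologists who have, per subunit, a ChIP-seq
peak set, plus expression data from pathway-specific knockdowns, and want to
know *which subunit combinations, at which positions relative to the TSS,
predict regulation* — and whether the resulting target genes behave
concordantly in independent tumour expression panels.

## What it computes

1. **Occupancy coding** — per-subunit peak sets are merged (single linkage,
   ≥ `min_overlap` bp) into unified regions, each coded by a 4-bit pattern
   in the fixed order p50 p52 RelA RelB (`"1100"` = p50+p52); pattern
   frequencies, subunit sharing, TSS-distance and genomic-feature
   annotation, k-means clustering (k = 8) of summit ± 500 bp profiles, and
   cross-cistrome/DHS comparisons.
2. **Region→gene assignment** — proximal links through a TSS window (5 kb
   default) and distal links through chromatin-loop anchors, optionally
   gated on DHS overlap (10 kb–250 kb).
3. **Knockdown DE** — per-cluster Welch t-tests on the 4-group design
   (control vs p50/RelA-KD; control vs p52/RelB-KD), Benjamini–Hochberg
   FDR < 0.05 plus a ≥ 10 % expression-difference rule at gene level;
   a gene whose expression falls on knockdown is *activated* by NF-κB.
4. **Direct targets** — regulated genes bound by p50 (canonical) or p52
   (non-canonical) among their assigned regions.
5. **The core model** — logistic regression of regulation mode on binary
   (pattern × proximal/distal) features:

   logit P(regulated) = β₀ + Σ β(pattern, stratum) · x(pattern, stratum)

   with log-odds-ratio coefficients, Wald 95 % CIs, P < 0.01 significance,
   missing estimates for unobserved or separated combinations, and
   bootstrap stability (fraction of B gene-resampled refits with P < 0.01;
   stable at ≥ 90 %).
6. **Lymphoma concordance** — low-expression filtering (log2 signal < 6),
   HL-vs-rest DE by the same method, and intersection with direct targets
   keeping genes whose NF-κB direction matches the HL direction.

A synthetic-data generator plants ground truth (patterns, placements,
regulation drawn from a known logistic model, concordant panel genes)
through all six stages, so the whole pipeline is testable end to end.

## Worked example

```r
library(nfkbmap)
dir <- tempfile()
files <- write_synthetic_dataset(file.path(dir, "data"), seed = 1)
out <- run_pipeline(files$config, file.path(dir, "run"))
res <- attr(out, "results")

res$occupancy
#> occupancy_matrix: 370 unified regions on 1 chromosome(s)
#> subunit region counts: p50=254, p52=274, RelA=68, RelB=118

head(pattern_frequencies(res$occupancy), 3)
#>   pattern count      pct
#> 1    0100    74 20.00000
#> 2    1000    70 18.91892
#> 3    1100    64 17.29730

summary(res$`fit_noncanonical-vs-none`)
#> Combinatorial binding-pattern logistic regression: noncanonical-vs-none
#> 190 genes; coefficients are log odds ratios; Wald 95% CIs
#>  pattern  stratum estimate            ci        p significant observed
#>     1101   distal    2.255  [1.01, 3.50] 4.01e-04        TRUE     TRUE
#>     1100 proximal    1.986  [0.75, 3.22] 1.67e-03        TRUE     TRUE
#>     1101 proximal    2.472  [1.30, 3.65] 3.82e-05        TRUE     TRUE
#>     1111 proximal    2.350  [0.66, 4.05] 6.58e-03        TRUE     TRUE
#>     1010 proximal   -0.178 [-2.78, 2.43] 8.93e-01       FALSE     TRUE
#>     ...
```

The significant features are exactly the planted ones — p50+p52 with or
without RelB/RelA drives non-canonical regulation, while the exclusive
prototypic dimer features (`1010`, `0101`) stay at zero; `0111:distal` was
never observed and is reported with a missing estimate rather than a number.
This run recovers 104 regulated genes into the direct-target table and 46
concordant genes in the lymphoma-panel stage, matching the planted truth in
`data/truth.json` exactly. Each stage writes TSV tables plus a JSON run-log
(parameters, stage seed, input MD5 hashes) into the run directory, and a
rerun with the same configuration is byte-identical.

A command-line wrapper lives at `inst/scripts/nfkbmap.R`
(`simulate` and `run` subcommands).

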