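# ncpart

Quantitative species delimitation from nest-sampled morphometric data:
**N**est-**C**entroid clustering combined with **PART** (Partitioning
Algorithm based on Recursive Thresholding), confirmatory leave-one-out
cross-validated LDA, and discriminant identification functions. The
package is written for taxonomists working on morphologically difficult
(often cryptic) social-insect species, and ships the published parameters
of the *Nesomyrmex madecassus* species group — four Malagasy/Mauritian
twig-nesting ants, two of which (*N. flavus*, *N. nitidus*) are true
cryptic species — as its worked example and synthetic benchmark.

## The method

Input is a specimen-level table: 18 worker traits in µm (CL, CW, CWb, EL,
FRS, ML, MW, MPST, NOH, NOL, PEH, PEL, PEW, PoOC, PPH, PPL, PPW, SL), a
specimen code and a nest code; `CS = (CL + CWb)/2` is the derived size
reference. The pipeline is hypothesis-free first, confirmatory second:

1. **NC clustering** — LDA with *nest samples* as groups (nestmates are
   close relatives), shrinkage-regularized within-scatter
   (`W* = (1−γ)W + γ tr(W)/p·I`, `γ = p/(p + (n − G))`); nests are placed
   at the centroid of their members' LD scores and a Ward dendrogram is
   built on Euclidean centroid distances.
2. **PART** — the number of clusters via recursive application of the Gap
   statistic (`W_k = Σ_r D_r/(2 n_r)`, reference `log W` from uniform
   draws, smallest *k* with `gap(k) ≥ gap(k+1) − s_{k+1}`), recursing
   into every subset with ≥ `2·min_size` cases; run with both a Ward
   (`hclust`) and a `kmeans` backend, `B = 1000` reference draws.
3. **Consensus + LOOCV-LDA** — congruently classified nests become the
   species hypothesis; incongruent or outlier nests are *wild-cards*.
   The hypothesis is validated by leave-one-out cross-validated LDA at
   the individual level; wild-cards are assigned by maximum posterior.
4. **Identification** — the published two-trait function
   `D2 = +0.0847·SL − 0.0625·MW − 15.038` (flavus +, nitidus −), the
   four-trait `D4`, the `CW/PoOC > 1.85` couplet and the full worker key
   are available as functions; new reduced-character discriminants can be
   extracted by greedy forward selection.

## Worked example

```r
library(ncpart)

report <- run_pipeline(pipeline_config(seed = 1, B = 100))
report
#> pipeline_report
#> morph_dataset: 231 specimens in 172 nest samples
#> species labels: flavus (61), gibber (7), madecassus (84), nitidus (79)
#> PART hclust: 4 cluster(s); kmeans: 4 cluster(s)
#> wild-card nests: 1/172
#> confirmatory LOOCV overall: 99.1%
#> final labels:
#>  C1  C2  C3  C4
#>  60  80   7  84
```

Both backends recover four clusters from the synthetic study-scale data
(231 workers / 172 nests generated from the published trait-ratio
distributions); one of 172 nests is a wild-card, and the confirmatory
LOOCV success (99.1% here) is in line with the 98% reported for the real
material. `write_report(report, "results")` writes the Newick dendrogram,
label tables, the confusion matrix in the published layout, species-wise
summaries and a JSON manifest. Identification without any refitting:

```r
evaluate_discriminant(discriminant_D2(), c(SL = 482, MW = 361))
#> [1] 3.2249           # inside the published flavus range [+0.98, +5.33]
key_classify(c(CW = 865, PoOC = 500, SL = 482, MW = 361),
             hump = FALSE, color = "yellow-light")$label
#> [1] "flavus"
```

A thin command-line front end mirrors the stages
(`inst/cli/ncpart.R {simulate,cluster,part,confirm,key,run}`).

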