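# lncperturb

Identification of **lncRNA-perturbated miRNA–mRNA triplets** in matched
expression cohorts, with triplet survival signatures.

Long noncoding RNAs can weaken the repressive coupling between a miRNA and
its mRNA target: in samples where the lncRNA is highly expressed, the
negative miRNA–mRNA correlation relaxes. `lncperturb` detects trios
(lncRNA, miRNA, mRNA) showing exactly this conditional-correlation
*rewiring*, and evaluates whether the detected triplets carry prognostic
information.

For each candidate triplet the cohort is sorted by the lncRNA; the top and
bottom quartiles form the H- and L-groups. After directional
differential-expression gates (miRNA down in H, mRNA up in H; p < 0.05,
fold-change > 1.5) and correlation gates
(R<sub>low</sub> < −0.4, R<sub>high</sub> ≥ R<sub>low</sub>,
|R<sub>low</sub> − R<sub>high</sub>| > 0.3, Spearman), the rewiring score is

> score = Φ( (F(R<sub>high</sub>) − F(R<sub>low</sub>)) /
> √(1/(n<sub>low</sub>−3) + 1/(n<sub>high</sub>−3)) ),
> F(R) = ½ ln((1+R)/(1−R)),

assessed against 100 random re-groupings (empirical p < 0.01). Candidates
come from a hypergeometric shared-miRNA screen (BH FDR < 0.05) over a
miRNA-target pair table, gated on a globally negative miRNA–mRNA Spearman
correlation. Detected triplets are scored per sample as
α·lncRNA + β·miRNA + γ·mRNA with Cox proportional-hazards coefficients; a
mean split of the risk score is tested by log-rank, and triplets that
separate survival jointly while no single member does are labelled
*functions together*.

Because the framework's original inputs are controlled-access tumor
cohorts, the package ships a first-class synthetic-cohort generator that
plants triplets with the assumed structure among independent decoys,
emitting expression, interaction, purity, survival and truth tables.

## Worked example

The numbered scripts under `analysis/` run the full study; the same flow in
a session:

```r
library(lncperturb)

cfg   <- generator_config(seed = 1)   # 400 samples, 20 planted, 500 decoys
coh   <- generate_cohort(cfg)
pp    <- preprocess_layers(list(lnc = coh$lnc_layer, mir = coh$mir_layer,
                                mrna = coh$mrna_layer), purity = coh$purity)
layers <- pp[c("lnc", "mir", "mrna")]

cands <- build_candidates(coh$interactions, layers)      # 520 candidates
neg   <- negative_pair_filter(cands, layers)             # 31 survive R<0 gate
det   <- detect_triplets(neg, layers, seed = 1)
sum(det$passed)
#> [1] 18
```

One sample fails the purity filter (399 of 400 retained); all 520 generated
genes per layer pass the expression filters by construction. The
shared-miRNA screen keeps all 520 wired triplets; the global
negative-correlation gate reduces them to 31 (the 20 planted triplets plus
decoys that are negatively correlated by chance), and the rewiring detector
reports 18 — all of them planted triplets, so recovery is 18/20 with zero
decoys reported. Prognosis over the 18 detected triplets:

```r
clin <- coh$clinical[coh$clinical$sample_id %in% layer_samples(layers$lnc), ]
prog <- triplet_prognosis(det[det$passed, ], layers, clin)
table(prog$category)
#> functions_together    not_significant
#>                  1                 17
```

Survival in this cohort is driven by a single planted triplet, and the
screen flags exactly one joint signature.

A hand-checkable 12-gene toy cohort ships with the package:

```r
toy <- read_cohort(system.file("extdata", "toy", package = "lncperturb"))
res <- run_pipeline(run_config(fdr_threshold = 0.7, seed = 1), cohort = toy)
res$report
```

Every count in that report (20 matched samples, 16 after the purity filter,
2/3/3 genes per layer after filtering, 3 candidates, 1 negative pair, 1
evaluated triplet with R<sub>low</sub> = −0.8 and R<sub>high</sub> = +0.8)
is hand-computed and asserted in the test suite.

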