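# tnbctype4

Molecular subtyping of triple-negative breast cancer (TNBC) from bulk
gene-expression matrices, with the four-subtype refinement that treats
immune and stromal signal as per-sample descriptors rather than subtypes.

TNBC — breast cancer lacking ER and PR expression and HER2 amplification —
splits into six expression subtypes (BL1, BL2, IM, M, MSL, LAR) by maximal
Spearman correlation of each tumor profile to subtype centroids. Two of the
six reflect the tumor microenvironment rather than the malignant cells:
immunomodulatory (IM) calls track infiltrating lymphocytes, and
mesenchymal stem-like (MSL) calls track tumor-associated stroma. This
package implements the complete analysis chain behind the refinement to
four tumor-intrinsic subtypes (**TNBCtype-4**: BL1, BL2, M, LAR):

- **Receptor calling** — per-marker (ESR1/PGR/ERBB2) two-component
  Gaussian mixtures fitted by EM across samples; a sample is triple
  negative when the posterior probability of the low-expression component
  is ≥ 0.5 for all three markers.
- **Centroid subtyping** — Spearman correlation of each sample to each
  centroid over shared genes; argmax call with a fixed tie order and an
  unclassified (UNS) threshold; refinement reassigns IM/MSL calls to the
  best-correlated tumor-intrinsic centroid while keeping `im_score` and
  `msl_score` as descriptors.
- **Matched tumor/stroma analysis** — paired differential expression
  (FC > 2, BH FDR < 0.01), hypergeometric over-representation of gene
  sets, per-compartment subtype concordance, and an exact Wilcoxon
  signed-rank test (full sign-assignment null for n ≤ 25, midranks for
  ties).
- **TIL association** — mild/moderate/intense binning of pathologist TIL
  percentages and rank-correlation of the IM descriptor with infiltrate.
- **Clinical statistics** — chi-square/Fisher contingency tests, pCR odds
  ratios of each subtype versus the whole unselected cohort (Woolf CIs,
  Haldane–Anscombe correction), Wilson/Clopper–Pearson binomial CIs,
  Kaplan–Meier with logrank and each-vs-rest comparisons, and Cox
  regression on the continuous IM score (Breslow ties, LRT).
- **Synthetic cohorts** — a generator with known truth (receptor
  bimodality, centroid-structured signal, immune/stromal admixture,
  copula-linked TIL scores, per-subtype pCR rates and survival hazards)
  validating every stage end to end.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated cohort of 1000 samples (`Rscript analysis/01_simulate.R` through
`analysis/06_clinical_stats.R`). Stage 2 and 3 print, for example:

```
ESR1: mu_neg 4.95 mu_pos 9.87 w_neg 0.55 (converged TRUE)
TNBC called: 288 of 1000 (28.8%); recall 0.993, precision 0.997
refined TNBCtype-4 calls:
BL1 BL2 LAR   M
105  62  39  82
call4 accuracy vs truth: 1.000
IM vs M descriptor correlation (Spearman): -0.34
```

meaning: the EM recovered the generating mixture for each marker, 288 of
1000 samples were called triple-negative (28.8%, against a generating rate
of 30%), every refined subtype call matched the generator truth, and the
IM and M descriptor scores anti-correlate across samples, as expected when
immune infiltrate and the mesenchymal state are antagonistic. Stage 6
prints the per-subtype pCR table with Wilson CIs and odds ratios versus
the whole cohort:

```
  group   n n_pcr rate_pct ci_low ci_high   or or_low or_high
1   BL1 105    37     35.2   26.8    44.7 1.24   0.77    1.98
2   BL2  62    14     22.6   14.0    34.4 0.66   0.35    1.26
```

The same machinery is driven programmatically:

```r
library(tnbctype4)

co <- generate_cohort(cohort_config(n_samples = 500, seed = 11))
fits <- sapply(c("ESR1", "PGR", "ERBB2"), function(m)
  list(fit_mixture_1d(co$expression[m, ], seed = 1, marker = m)))
calls <- call_receptor_status(co$expression, fits)
tnbc <- identify_tnbc(calls)
sub <- subtype_samples(co$expression[-(1:3), tnbc], co$centroids)
table(sub$call4)
```

or through `run_pipeline()` with a YAML config (see `?run_pipeline`).

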