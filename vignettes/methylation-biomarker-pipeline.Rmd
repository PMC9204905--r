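---
title: "Methods: a five-criterion methylation-biomarker screening and surveillance pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a five-criterion methylation-biomarker screening and surveillance pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methfunnel)
```

## Scientific setting

Aberrant promoter methylation of a tumor-suppressor gene does three things a
biomarker developer can exploit. It is *binary-ish* at the locus level
(tumors either acquire dense promoter methylation or they do not), it
*silences expression* (so a methylation call predicts a functional
consequence), and methylated tumor DNA *circulates in plasma* (so the same
assay that scores a biopsy can monitor a patient longitudinally from blood
draws). `methfunnel` implements the complete analysis path from genome-wide
array data to a blood-based surveillance call for one such marker in breast
cancer, together with a synthetic-data generator that makes every stage
testable end to end.

Two measurement technologies are modelled throughout:

* **Methylation arrays.** Each CpG probe reports a beta value
  $\beta = M/(M+U) \in [0,1]$, the fraction of methylated signal. Gene-level
  promoter methylation is the mean beta over the gene's promoter-region
  probes, and the tumor effect is
  $\Delta \mathrm{Avg}_\beta = \bar\beta_{\text{tumor}} - \bar\beta_{\text{normal}}$.
* **Quantitative (methylation-specific) PCR.** A sample's relative level is
  $E^{\,\overline{Cq}_{\text{ref}} - \overline{Cq}_{\text{target}}}$ with
  amplification efficiency $E = 2$ by default and ACTB as the reference for
  methylation assays (GAPDH for expression). Replicate Cq values are averaged
  on the Cq scale before exponentiation (`replicate_mode = "mean_cq"`),
  matching standard ΔΔCq practice; a geometric-mean-of-levels alternative is
  available. A reaction that never crosses threshold is recorded at the
  sentinel Cq equal to the cycle count (50), which maps to level 0 and an
  `undetected` flag; a *reference* assay at the sentinel is an error, because
  no relative level is defined without reference amplification.

## The five-criterion screening funnel

`run_funnel()` intersects five independent filters over a gene universe.
Cutoffs are arguments of `funnel_config()`; the defaults below are the study
conditions, chosen to be stringent enough that the intersection is small:

1. **Discovery hypermethylation**: $\Delta \mathrm{Avg}_\beta > 0.4$
   (strict) in a paired tumor/normal discovery cohort. A 0.4 beta shift is a
   large, unambiguous effect — far above array noise and batch wobble.
2. **Replication**: the same rule in an independent cohort, so a single
   cohort's artifacts cannot nominate a gene.
3. **Treatment-response contrast**: the top `top_k_response = 20` genes by
   mean-beta difference between progressive-disease (PD) and
   complete-response (CR) tumors under hormone therapy. This is a rank rule,
   not a threshold, because the PD−CR contrast has no natural unit; ties are
   broken lexicographically by gene id so the selection is deterministic.
4. **Normal-tissue silence**: in a panel of normal tissues, *every* tissue's
   mean beta must be `< 0.1` (strict). The all-tissue rule (rather than a
   grand mean) is what makes the marker specific: one methylated normal
   tissue would contaminate plasma measurements.
5. **Expression silencing**: tumor/normal expression ratio `≤ 0.5`
   (inclusive — "halved or lower"). Genes with zero normal expression give an
   undefined ratio; they are flagged and excluded rather than silently passed.

The final list is the intersection, ordered by the criterion-3 response rank,
so the most response-discriminating candidate leads. The report retains the
per-criterion gene sets and Venn counts so the funnel's attrition is
inspectable.

Strictness conventions are deliberate and tested: array cutoffs (0.25, 0.4,
0.1, 0.002, 5, 25) are *strict* inequalities — a value exactly at the cutoff
is not a call — while fold-change rules ("at least twofold", "halved") are
*inclusive*, matching how such rules are stated.

## QMSP calling and treatment effects

`calibrated_fold()` divides a tumor's relative level by its paired normal's;
`call_hypermethylation_qmsp()` calls hypermethylation at fold ≥ 2 and
`call_low_expression()` calls silencing at fold ≤ 0.5. A detected tumor over
an undetected normal yields an infinite fold, flagged as such rather than
capped: it is a positive call, and any cap would be arbitrary.
`treatment_effect()` summarizes demethylating-agent experiments as
percent-of-control $100\,\bar x_T/\bar x_C$ with a delta-method standard
deviation for the ratio of means — the form in which such experiments are
conventionally reported.

## Plasma surveillance

`classify_patient()` scans a patient's longitudinal methylated-marker series.
A draw is abnormal when its level exceeds `cutoff = 0.002` (strict) — the
assay's practical detection floor in plasma. The first `clearance_window + 1`
draws (baseline plus one post-operative draw by default) are excluded from
calling, because residual tumor DNA from surgery clears over roughly one
monitoring interval and would otherwise produce false progression calls; a
series with no eligible draws is `indeterminate`, never silently negative.
The ROC score is the maximum post-window level. `benchmark_markers()` applies
the same machinery to serum CEA (> 5 ng/mL) and CA15-3 (> 25 U/mL) so the
methylation marker is compared against the clinical incumbents on identical
patients.

## Statistics

Association, rank and survival statistics delegate to the reference
implementations — `stats::fisher.test` (minimum-likelihood two-sided
p-value), `chisq.test(correct = FALSE)`, `wilcox.test`,
`cor.test(method = "spearman", exact = FALSE)`, `survival::survfit`,
`survdiff` and `coxph(ties = "efron")`, and `pROC::roc` — wrapped in thin,
validated interfaces with explicit conventions (the sample odds ratio
$ad/bc$ is reported alongside Fisher's conditional MLE; Cox
non-convergence is an error, not a warning). The test suite checks each
wrapper against an independent hand-written oracle: full hypergeometric
enumeration for Fisher, all-pairs concordance for AUC, a hand product-limit
estimator for Kaplan–Meier, and a direct Efron partial-likelihood grid for
Cox.

## The synthetic generator

The generator's job is to reproduce the statistical *structure* of each
input, not any particular dataset, so that planted truths are recoverable.

* **Beta values** are drawn on the logit scale, where methylation noise is
  natural (bounded support, variance shrinking near 0 and 1):
  $\beta = \operatorname{logit}^{-1}(a + \sigma Z)$ with the delta-method
  scale $\sigma = s/(\mu(1-\mu))$ for target sd $s$. Because the inverse
  logit is nonlinear, a naive location $a = \operatorname{logit}(\mu)$
  biases the mean upward near the boundary — enough to push background genes
  over the 0.1 normal-panel cutoff. The location is therefore *calibrated*
  numerically (integration plus root-finding) so that
  $E[\beta] = \mu$ exactly; cutoff behaviour then matches the nominal means.
* **Planted genes** (default 20 of 1000, 0.5 beta effect on a 0.1
  background) are hypermethylated in tumors, carry an extra PD-specific
  effect in the response cohort (base effect 0.2 + 0.4 PD delta, so the
  PD−CR contrast is 0.4 without clipping at 1), stay at a 0.05 background in
  the normal panel, and have expression divided by `expression_coupling = 4`.
  Coupling of exactly 2 would park planted genes *on* the inclusive 0.5
  boundary, where noise flips the call ~50% of the time; 4 separates signal
  from the rule's edge, which is a property of the truth being planted, not
  of the rule.
* **The normal panel** uses 10 tissues × `samples_per_tissue = 32` ≈ 320
  normals, the scale at which per-tissue means are stable enough for an
  all-tissue rule to be meaningful.
* **Plasma trajectories** follow geometric post-operative clearance
  (half-life 0.5 monitoring intervals — tumor cfDNA clears fast relative to
  3-month draws) from a baseline of 0.016; progressors (30%) regrow
  exponentially (rate 2/interval) from a reseeding level of twice the
  detection floor at a random onset. Multiplicative lognormal assay noise
  (CV 0.3) is applied and values below the 0.002 floor are recorded as 0,
  mimicking a real QMSP limit of detection. Draws are scheduled every
  3 months for two years, then semiannually. Serum CEA and CA15-3 rise late
  (two draws after onset) in only half of progressors — they are designed to
  be the weaker marker, as observed clinically.
* **Survival** times are exponential with a planted hazard ratio on the
  hypermethylated group and administrative censoring at 120 months
  (10 years), the follow-up horizon used throughout.

## Problem sizes and numerical choices

Study-scale runs — 1000 genes × 2–3 probes × 40 paired arrays, a 320-sample
normal panel, a 200-patient monitored cohort, 500-patient survival tables —
complete in well under a second each, so the acceptance checks can afford
replication: funnel recovery over 10 independent seeds, log-rank type-I
calibration over 500 null simulations, Cox recovery of a hazard ratio of 6
over 100 simulations. All randomness flows from a single integer seed per
configuration object; derived datasets use fixed offsets from it, so a
bundle is exactly reproducible. File interchange is plain TSV/CSV with a
manifest of MD5 digests.

## Limitations

The generator plants clean, homogeneous effects: it does not model
cell-type-mixture deconvolution, array normalization or batch effects,
copy-number interference with beta values, inter-patient heterogeneity in
clearance kinetics, or informative censoring. The funnel treats criteria as
independent filters, whereas on real data discovery and replication cohorts
share platform artifacts. These simplifications are intentional — the
package validates the *analysis logic* under known truth; biological realism
of any particular dataset is out of scope.
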