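---
title: "Methods: fabric metrics, calibrated regulation and transcriptomic distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fabric metrics, calibrated regulation and transcriptomic distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefabric)
```

## The problem and the model

A transcriptome is more than a vector of mean expression levels. Two genes
with identical averages can differ radically in how tightly the cell
controls their fluctuations, and in how their fluctuations couple to other
genes. `genefabric` characterizes each gene in each condition by three
mutually independent measures computed from biological replicates of a
replicated, redundantly probed expression experiment (the motivating design
is a microarray study of control and three disease rat models, 4 biological
replicates each, with a variable number of spots per gene):

* **AVE**, the average expression level: the mean over a gene's redundant
  spots of the per-spot replicate means, after each condition has been
  divided by the median of all its spot × replicate intensities. Units are
  therefore "median gene expression" and comparable across conditions.
* **REV**, the relative expression variability: the pooled coefficient of
  variation over the gene's spots,
  $\mathrm{CV}_i = \sqrt{\tfrac{1}{R_i}\sum_k (s_{ik}/\mu_{ik})^2}$,
  multiplied by the chi-square mid-interval factor
  $F(r) = \tfrac12\left(\sqrt{r/\chi^2_{r;0.975}} +
  \sqrt{r/\chi^2_{r;0.025}}\right)$ with $r = nR_i - 1$ degrees of freedom,
  expressed in percent. $F$ corrects the small-sample underestimate of a CV:
  it is ~2.15 at $r = 3$ and decreases monotonically to 1.
* **COR**, the Pearson correlation of two genes' log2 expression across the
  replicates of one condition. Pairs with $|COR| \ge 0.95$ are significantly
  synergistic (positive) or antagonistic (negative); $|COR| \le 0.05$ marks
  independently expressed pairs; anything between is unclassified. A gene
  set's coordination score is $SYN\% + ANT\% - IND\%$ over its within-set
  pairs.

From a reference → case contrast the package derives the signed expression
ratio $x$ ($|x| \ge 1$, negative for down-regulation), the per-gene
fold-change cutoff $CUT = 1 + \sqrt{(REV_{ref}^2 + REV_{case}^2)/2}/100$, the
Welch-test p-value, the weighted individual regulation
$WIR = AVE_{ref}\,(|x|-1)\,\mathrm{sign}(x)\,(1-p)$, and the transcriptomic
distance $TD$, the Euclidean norm of the three normalized changes
(ΔAVE, ΔREV, ΔCOR) described below. The point of the three-measure view is
that regulation hierarchies by $|x|$, by $WIR$ and by $TD$ genuinely
disagree: a 50-fold induction of a barely expressed gene can matter less to
the transcriptome than a variability and coordination upheaval of a highly
expressed one.

## Key parameter choices

* **Significance threshold 0.95, boundary inclusive.** At $n = 4$
  replicates the null density of the Pearson coefficient is uniform on
  $[-1, 1]$, so $P(|r| \ge 0.95) = 0.05$ exactly: the fixed threshold is a
  5% test. The threshold is applied to the computed value as-is (0.95
  classifies as synergistic).
* **Independence threshold 0.05.** A numerical definition of "independently
  expressed" is needed; we use $|COR| \le 0.05$, mirroring the
  $p<0.05 \leftrightarrow |COR|\ge 0.95$ duality at $n = 4$ (under the
  uniform null, $P(|r| \le 0.05) = 0.05$ as well). Configurable in every
  entry point.
* **COR on log2 scale by default.** Correlating log2 expression damps the
  leverage of single high-intensity replicates. The didactic four-gene
  example reproduces its published correlations on the linear scale, so
  worked-example code passes `log2 = FALSE`; real analyses should keep the
  default.
* **COR mode `gene_means`.** A gene's spots are averaged within each
  replicate before correlating, because spots are technical replicates. The
  literal spot-level double-sum (`pooled_spots`) is retained for
  comparison; for unequal spot counts its quotient can leave $[-1,1]$ and
  is clamped with a warning.
* **REV factor variant `sqrt`.** The confidence-interval endpoints of a
  variance must be square-rooted to live on the CV scale; the `linear`
  variant (midpoint on the variance scale) is available for sensitivity
  analysis. At $r = 3$ the two give 2.15 vs 7.11 — the choice matters, and
  the sqrt form keeps REV commensurable with the CV it corrects.
* **CUT pooling `rms`.** With equal REVs it degenerates to the readable
  $1 + REV/100$, i.e. "a fold-change must beat the gene's own noise"; the
  `sum2` reading (factor 2 inside the radical) is available as a config
  switch.
* **WIR form.** The departure factor is $(|x|-1)\,\mathrm{sign}(x)$: zero
  exactly at no change, sign carrying the regulation direction, confidence
  weighting by $1-p$. Degrees of freedom for $p$ come from the Welch test
  on gene-level replicate means ($n$ per side), not on pooled spot values —
  spots are not biological replicates. A per-spot variant exists behind
  `welch_on = "spots"`.
* **No multiple-testing correction** in the default pipeline, matching the
  fixed-threshold methodology this package implements; `p.adjust` can be
  applied to the regulation table downstream if a study needs it.

## Trajectory normalizers

The three TD components are scaled by reference-condition averages over a
*gene universe*: $\Delta AVE / \langle AVE_{ref}\rangle$,
$\Delta REV / \langle REV_{ref}\rangle$, and the root-mean-square COR change
over partners divided by the root-mean-square reference COR. The universe
defaults to all genes quantified in both conditions, and the COR partner
set to that universe minus the focal gene; both can be restricted to a
pathway. Published per-pathway TD values depend on which universe produced
them, and that choice is rarely stated — so TD values are comparable within
one analysis, not across papers. Pairs whose correlation is undefined in
either condition (constant profiles) are excluded from both mean-square
sums, keeping numerator and denominator on the same support.

## The synthetic-data generator

`synthetic_spec()` + `generate_dataset()` emulate the study design the
package targets: 4 conditions (CO, HO, CM, HM) × 4 biological replicates,
redundant spot counts drawn with $P(R_i = 1,2,3) = (0.70, 0.25, 0.05)$
(typical of a 4×44k array), baseline log2 expression $\sim N(2, 3^2)$ so
that AVE spans roughly 0.2–300 median units, per-gene biological CVs drawn
log-uniformly on [3%, 160%], 5% technical spot noise, and 15% of genes
regulated with fold magnitudes log-uniform on [1.2, 250] — all matching the
ranges observed in the motivating dataset. Replicates are generated on the
log2 scale as baseline + condition effect + factor loading × latent
replicate factor + biological noise; spots add independent technical noise;
values are exponentiated and median-normalized. A log-normal model is the
natural choice because intensities are positive and right-skewed and COR is
defined on log2 values.

Three modelling decisions deserve emphasis:

* **Biology is drawn per replicate and shared across a gene's spots.** This
  is exactly what makes redundant probing informative: spot-to-spot scatter
  estimates technical noise, replicate-to-replicate scatter the biological
  CV that REV targets.
* **Correlation is planted through latent factors.** Genes in a block load
  on a shared factor with loading $\pm\sqrt{\rho}\,s_i$, giving pairwise
  log-scale correlation $\pm\rho$ (same-sign vs opposite-sign loadings),
  while zero-loading genes are independent. The loading construction is
  positive semi-definite by design.
* **Condition effects are applied before normalization**, so strong
  regulation shifts the condition median slightly, as on real arrays;
  ground-truth folds are recorded after normalization from the realized
  medians.

What the generator does *not* emulate: scanner background, dye and spatial
artifacts, probe-sequence effects, outlier replicates, heavy-tailed noise.
Passing recovery tests therefore demonstrates correctness of the estimators
under the stated stochastic model, not robustness to every failure mode of
real arrays. One interaction worth knowing: technical spot noise attenuates
observed correlations for genes whose biological CV is small (for a 3% CV
gene probed with 5% technical noise most of the replicate variance is
noise), so correlation-recovery checks use specs whose biological signal
dominates; with the defaults this attenuation is a realistic feature, not a
bug.

## Numerical and degenerate-input conventions

* Zero-variance profiles have undefined correlation, reported as `NA` and
  classified `not_significant` — never coerced to 0, which would mean
  "independently expressed".
* A Welch test with both sides constant returns $p = 1$ for equal means and
  0 otherwise.
* Zero spot means make CV undefined (error at the single-profile level,
  `NA` row in bulk summaries); zero AVEs make the expression ratio
  undefined.
* Median normalization refuses a condition whose median is 0.
* Rows with missing or non-numeric intensities are dropped at parse time
  and counted; within `gene_profiles()` a spot missing any replicate value
  in a condition is excluded from that condition only.
* Gene symbols match case-insensitively between expression tables and GMT
  sets (mixed-case rat symbols such as `Pmm1` vs `LOC500959`).
* Problem sizes in the shipped tests and in `scripts/acceptance.R` are
  chosen to make each statistical check sharp at desk scale: 10,000+ pairs
  for the null-calibration rate, 1000 replicates for fold recovery, 200
  genes × 50 replicates for the REV–CV rank correlation, 100 random
  instances per oracle-equivalence check.

## Worked example

```{r quad}
tab <- probe_table(
  data.frame(spot_id = paste0("s", 1:4), gene = c("A", "B", "C", "D"),
             CO_1 = c(96, 87, 105, 103), CO_2 = c(98, 83, 102, 97),
             CO_3 = c(102, 110, 98, 97), CO_4 = c(104, 120, 95, 103)),
  layout = data.frame(sample = paste0("CO_", 1:4), condition = "CO"))
fabric_summary(tab, "CO")
cor_pairs(tab, "CO", log2 = FALSE)
```

Four genes with the same AVE = 100: B is loosely controlled (CV 17.87%,
REV 38%), A and C fluctuate in perfect opposition (COR −0.997), A and D are
independent (COR 0). Mean expression alone distinguishes none of them.

```{r pipeline, eval = FALSE}
ds <- generate_dataset(synthetic_spec(), seed = 17)
run_pipeline(ds$table, ds$truth$pathways, out_dir = "fabric_out")
```

## Known limitations

* The spot-level `pooled_spots` correlation is not a bona fide correlation
  coefficient for unequal spot counts; it exists for methodological
  comparison only.
* TD values depend on the normalizing universe (see above) and on the
  replicate count through COR noise; compare TDs only within a fixed
  configuration.
* The fixed |COR| threshold is calibrated for $n = 4$; for other replicate
  counts the same threshold implies a different test size, and
  `sig_threshold` should be adjusted by the user if a 5% test is wanted.
* PSR inherits every weakness of thresholded counting; it is provided as
  the traditional baseline the richer quantifiers are compared against.
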