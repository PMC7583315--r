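---
title: "Scoring regulatory SNPs by TBP-promoter affinity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring regulatory SNPs by TBP-promoter affinity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbpsnp)
```

## The scientific problem

The TATA-binding protein (TBP) nucleates the transcription
preinitiation complex at essentially every RNA-polymerase-II promoter,
and its canonical recognition element — the AT-rich TATA box — lies
within roughly 70 bp upstream of the transcription start site. A
single-nucleotide substitution inside or near a TATA box changes the
equilibrium dissociation constant $K_D$ of the TBP–DNA complex, and
expression of the downstream gene is, to a useful approximation,
proportional to that affinity. `tbpsnp` operationalises this premise:
it estimates $-\ln K_D$ (ln-molar units; larger = tighter binding) for
the reference and minor allele of each promoter SNP, tests the
difference, and aggregates the significant calls into
selection-pressure statistics.

## The affinity estimator

A 26-bp window $s$ — the length of the synthetic duplexes used in the
package's EMSA calibration panel — is scored as

$$-\ln K_D(s) \;=\; c_0 \;+\; c_{stop} S_{stop}(s) \;+\;
  c_{slide} S_{slide}(s) \;+\; c_{bend} S_{bend}(s) \;+\;
  \sum_{d \in \{AA,\dots,TT\}} n_d(s)\, D_d ,$$

mirroring the three elementary steps of TBP binding:

* **Recognition ("stop")** — $S_{stop}$ is the best score over all
  15-bp cores of a fixed TATA-box position weight table: the 8-bp
  consensus `TATAWAWR` occupies core positions 4–11 with weight 1 for
  invariant bases and 0.5 for each base allowed at a degenerate
  position (`tata_pwm_prior()`). The 15-bp frame pads the element so it
  is scanned in context.
* **Sliding** — $S_{slide}$ is the maximal A/T count over all 9-bp
  subwindows, a proxy for the one-dimensional diffusion of TBP along
  AT-rich tracts. Nine base pairs is roughly the DNA footprint engaged
  by the TBP saddle.
* **Bending** — $S_{bend}$ counts TA and AT dinucleotide steps, the
  pyrimidine–purine kink sites at which TBP bends the helix by ~80°.
* **Fine energies** — $n_d$ are the counts of the sixteen dinucleotide
  steps in the window and $D_d$ calibrated per-step adjustments
  absorbing stacking and shape effects the three coarse terms miss.

A promoter (length $\ge$ 26) is scored by its best window — one $K_D$
per entered allele, the strongest TBP site — with ties broken to the
leftmost window. The per-allele standard error is a single model
constant $\sigma$, the calibration residual scale, not a per-sequence
quantity.

### Calibration

The packaged panel (`odn_table2()`) provides ten 26-bp alleles (five
SNPs × two alleles) with reference predictions of $-\ln K_D$.
`fit_affinity_model()` fits $(c_0, c_{stop}, c_{slide}, c_{bend}, D)$
by *minimum-norm exact least squares*: among all parameter vectors that
reproduce the ten panel values exactly, it selects the one closest to
the structural prior (unit combination coefficients, zero fine
energies) in a weighted Euclidean norm, computed via the Moore–Penrose
pseudoinverse. The position weight table and the window definitions are
fixed structure, not fitted.

With ten calibration points and twenty parameters this is deliberate
interpolation, so in-sample residuals say nothing about accuracy.
The honest accuracy measure is `loo_affinity_model()`: the full
calibration is repeated with each ODN held out and the held-out
prediction error recorded. On the shipped configuration the maximum
absolute leave-one-out residual is about 0.14 ln units — roughly a
15% error in $K_D$ — and users should regard per-sequence predictions
as accurate to a couple of tenths of an ln unit, not to the
interpolated decimals. The prior's design constants (9-bp slide
window, 0.5 degenerate-position weight, unit penalty weights) were
selected once by minimising exactly this leave-one-out criterion over
a small structured grid; richer unstructured families (free
dinucleotide regressions, generic composition features) generalise
two- to five-fold worse.

### Numerical and behavioural notes

* The pseudoinverse solve is deterministic; refitting reproduces the
  shipped YAML configuration (`inst/extdata/affinity_model_calibrated.yaml`)
  to full precision.
* Edits that move a window's best core toward the TATA consensus
  increase the three coarse terms by construction, but the fine-energy
  table can offset a small recognition gain: in random-sequence
  experiments roughly 1% of consensus-ward edits decrease the total
  score, always by less than the two-step fine-energy budget
  $2(\max D - \min D)$. The test suite pins this behaviour.
* Because scoring takes the best window, a 26-bp probe embedded in a
  longer sequence can be out-scored by a window shifted a few bases
  (the shifted window drops edge steps with negative fine energies);
  the packaged synthetic promoters document this, and allele-effect
  *signs* are unaffected.
* Scoring is sense-strand only, matching the input convention in which
  the user supplies the promoter as written; there is no
  reverse-complement scan. Substitutions only; indels are rejected.

## Marker calls

For alleles with estimates $\hat a_{wt} \pm \sigma$ and
$\hat a_{min} \pm \sigma$ the effect is
$\Delta \ln K_D = \hat a_{min} - \hat a_{wt}$
($= \ln K_D^{wt} - \ln K_D^{min}$), with Fisher statistic
$Z = \Delta/\sqrt{2}\sigma$ and one-sided normal tail $\alpha$. The
direction of the test is taken from the sign of $\Delta$, so one
$\alpha$ accompanies one directed decision: `deficiency_significant`
($\Delta < 0$, predicted underexpression), `excess_significant`, or
`insignificant` at the 0.05 threshold. The expression change is
reported as the ratio $e^{\Delta}$ under the proportionality premise.

The default $\sigma = 0.20$ ln units is chosen so that the smallest
allele effect in the validated panel ($|\Delta| = 0.51$) is significant
at $\alpha < 0.05$ ($Z = 1.80$, $\alpha = 0.036$) — i.e. the
uncertainty scale is anchored to the panel that the in vitro
experiments confirmed, and it is configurable.

The prioritisation rank $\rho$ (A best … E worst) bins $\alpha$ at
$10^{-6}, 10^{-4}, 10^{-3}, 10^{-2}$ and the significance threshold.
The bins are a heuristic triage aid, exposed in configuration; only
their monotonicity is meaningful.

No multiple-testing correction is applied across a screen's SNPs; the
downstream selection statistics operate on the raw significant-call
counts, and users comparing individual markers should correct as their
design requires.

## Selection-pressure statistics

`tally_selection()` reduces a call table to per-class counts
($n_{res}$ significant calls, split $n_{gt}/n_{lt}$ by affinity
direction and $n_{up}/n_{dn}$ by annotated phenotype effect);
`selection_report()` tests two nulls with *exact* binomial tails
(direct mass summation — count rows can have $n_{res}$ as small as
12, where a normal approximation would be badly wrong):

* **Neutrality against the genome-wide norm.** Genome-wide, SNPs
  damaging TBP sites outnumber improving ones about fourfold, so under
  neutral drift an affinity-increasing call has probability
  $p_0 = 0.2$. The headline probability is the right tail
  $P(X \ge n_{gt})$ when $n_{gt}$ exceeds its null expectation and the
  left cumulative otherwise; both tails are always reported explicitly,
  because a table of counts can be interesting in either direction.
* **Equal split of phenotype directions.** The two-sided exact
  probability (minimum-likelihood rule, as in `binom.test`) of the
  observed $n_{up}/n_{dn}$ split at $p = 1/2$ — the operational test of
  disruptive (both-extremes) selection.

On the packaged count table the headline row (261 calls, 176
affinity-increasing) rejects the genome norm at $P < 10^{-61}$ while
the phenotype split (119 vs 142) is even ($P = 0.17$).

## Saturation-kinetics fitting

`fit_kd()` fits the one-site model $v = V_{max} c/(K_D + c)$ to
(concentration, rate) points by Levenberg–Marquardt least squares with
positivity bounds, initialised at $V_{max}^{(0)} = \max v$ and
$K_D^{(0)} =$ the concentration nearest half-max. Standard errors come
from the curvature of the objective at the optimum. When the fitted
$K_D$ exceeds the largest tested concentration the data never
approached saturation and the estimate is flagged as poorly identified.
On noiseless data the fit recovers the generating parameters to
$10^{-6}$ relative; across 500 simulated four-point designs spanning
0.25–4 × $K_D$ at 5% noise, the median $K_D$ bias is below 1%.

## The synthetic-data generators

The generators exist so every pipeline stage can be exercised with
known ground truth and no external downloads:

* `sim_promoter_snp()` plants a 15-bp consensus-sampled TATA element in
  a GC-biased background (default GC fraction 0.6, the character of
  human proximal promoters; element 5' end at offset −31, placing the
  box ~25–30 bp upstream of the TSS where TATA elements sit) and
  introduces one substitution with verified effect direction: damaging
  (consensus base → non-consensus inside the element), improving
  (repairs a planted consensus violation; impossible by construction on
  a perfect element), or neutral (outside every element-containing
  window, verified to leave the score exactly unchanged).
* `sim_counts()` draws marker count tables with binomial splits at
  chosen improve:damage and up:down rates.
* `sim_kinetics()` draws saturation-curve datasets with multiplicative
  Gaussian noise, clipped at zero rate.

All generators consume a single integer seed and are byte-reproducible.
What they deliberately do **not** emulate: real base-composition
heterogeneity, multiple or overlapping TBP sites, chromatin context,
allele-frequency spectra, or linkage between SNPs. Passing the recovery
tests therefore demonstrates that the pipeline's inference is correct
*for its own model of the data*, not that the model captures every
property of real promoters.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run, per invocation: the
ten-ODN calibration plus ten leave-one-out refits; exhaustive binomial
oracle comparison for all $n \le 30$ with large-$n$ spot checks; 500
seeded kinetics recoveries; and 100 seeded damage-SNP end-to-end scans.
These sizes give stable statistics (binomial standard error on the
sign-recovery rate $\approx 2\%$) at interactive runtimes.

## Known limitations

* The affinity estimator is calibrated on ten points; its leave-one-out
  accuracy (~0.14 ln units, worst case) bounds what per-sequence
  predictions can claim. Absolute $K_D$ values inherit the calibration
  scale of the panel's reference predictions, which differs from raw
  EMSA scales obtained at other active-TBP concentrations.
* Best-window scoring reports one site per promoter; cooperative or
  tandem TBP sites are not modelled.
* Sense strand only; substitutions only.
* The selection statistics are count-ratio tests against a fixed
  genome-norm proportion, not population-genetic selection inference.
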