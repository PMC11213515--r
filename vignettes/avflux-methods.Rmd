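---
title: "Methods: arteriovenous flux statistics and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: arteriovenous flux statistics and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avflux)
```

## The model

Arteriovenous metabolomics measures, for each organ, the abundance of each
metabolite in the blood entering it ($C_A$) and leaving it ($C_V$). Under
the assumption that the sampling interval is short relative to changes in
systemic state (a quasi-steady state), the sign of
$\log_2(C_V/C_A)$ identifies the organ's net handling of the metabolite:
positive means net release, negative net uptake. This is a
*concentration-gradient* statistic, not a mass-balance flux: without blood
flow rates it cannot be converted into molar transport, and the package
deliberately never attempts that conversion.

Per organ $\times$ metabolite $\times$ genotype, the per-animal
$\log_2(C_V/C_A)$ values form one sample tested against location zero.
The test dispatch mirrors common practice in small-cohort physiology:

1. Shapiro-Wilk on the sample; treat as normal when its p-value is
   $\ge$ 0.05 (i.e. normality is not rejected).
2. One-sample t test when normal; otherwise the one-sample Wilcoxon
   signed-rank test, computed exactly for $n \le 25$ (no normal
   approximation at the cohort sizes this package targets, $n = 8$–$10$).
3. Benjamini-Hochberg q-values within each organ $\times$ genotype series;
   the release/uptake call itself uses the raw p-value at level
   $\alpha = 0.05$, and both numbers are always reported.

Some study protocols describe the normality gate in inverted wording
("normal distribution observed, P < 0.05"); since the Shapiro-Wilk null
hypothesis *is* normality, the conventional reading is the default and an
`invert_gate` flag exists purely so such descriptions can be replicated
verbatim. Similarly, a "1-sample Mann–Whitney U test" (a test that does
not exist under that name) is implemented as the standard nonparametric
one-sample location test, the Wilcoxon signed-rank against zero. Both
decisions are configuration, not hard-coded guesses.

Paired genotype contrasts (littermate WT vs CF) gate on the paired
differences and use the paired t or signed-rank test; unpaired contrasts
(urine/artery ratios) gate on both groups and use Student's t or
Mann-Whitney.

## Organ plumbing

Arterial references differ by organ and are declared in an editable organ
map rather than code:

* **Liver** — dual inflow, mixed in concentration space before logging:
  $C_A^{liver} = 0.22\,C_{\mathrm{hepatic\ artery}} +
  0.78\,C_{\mathrm{portal\ vein}}$. Mixing concentrations (not log values)
  is the physically meaningful average of two converging blood streams.
* **Lung** — fed by mixed venous blood; the statistic is oriented as
  $\log_2(C_{\mathrm{arterial}}/C_{\mathrm{right\ ventricle}})$ so the
  same outflow-over-inflow formula covers every organ.
* **All other organs** — the mean of the aorta and femoral-artery
  measurements. These are two measurements of essentially the same
  systemic arterial blood, so averaging reduces measurement noise; when
  only one was sampled the map's `renormalize` flag lets it stand alone.
  This symmetric default is a design choice: nothing in a typical study
  report fixes which arterial site feeds which organ comparison.

Nonpositive ion counts are treated as missing for ratio purposes (the
animal is dropped from that cell and the exclusion logged). No imputation
is performed anywhere: imputed values would fabricate gradients.

## Exchange graph

For each metabolite and genotype, a directed edge is drawn from every
organ with significant release to every organ with significant uptake
(both at raw $p < \alpha$, matching how such chord analyses are gated in
practice; q-values remain in the flux table). Self-edges are impossible by
construction. The relaxed fatty-acid variant ($\alpha = 0.1$, $\pm 2.5$ SD
outlier removal before testing) is the same code path under different
configuration. Counting is per directed organ pair per metabolite, so an
organ's total exchange is outgoing plus incoming edges.

## Homeostasis screen

For each calibrated metabolite and organ, the screen computes Spearman's
correlation between the per-animal *inflow* concentration and the
per-animal $\log_2(C_V/C_A)$, separately per genotype (never pooled). The
liver uses its weighted inflow mixture as the concentration axis; using
the resolved inflow for every organ generalizes that rule consistently.
An inverse correlation — release falling as the circulating level rises —
is the signature of set-point regulation. Per-cell p-values are reported
uncorrected, as in star-annotated heatmap displays where each cell is its
own hypothesis; BH q-values across the screen are attached for
transparency but do not drive the direction call. The practical
consequence, quantified in the acceptance suite, is that a pure-noise
28-metabolite $\times$ 8-organ panel flags about $0.05 \times 224 \approx
11$ cells per genotype: users should read screen counts with that
background rate in mind.

One caveat inherent to the design: the inflow concentration appears in the
denominator of the flux statistic, so shared arterial measurement error
induces a small spurious negative correlation (of order $-0.1$ at the
default noise levels). This ratio artifact exists in any AV correlation
analysis; it is far too small to mimic a programmed homeostat
($|\rho| \gtrsim 0.9$) but contributes to the false-positive background.

## Renal indices

Reabsorption is read from the creatinine-normalized urine/artery ratio
$(U_m/U_{\mathrm{crea}})/A_m$: creatinine normalization cancels urine
concentration, and the arterial denominator cancels the ion-count unit
once all quantities are internal-standard normalized. Genotype contrasts
are computed on the *log* of the ratio, since ratios are multiplicative.
Tracer leakage, $(U^{13C}/U_{\mathrm{crea}})/A^{13C}$, is reported
descriptively only — with two animals per genotype, as is typical for
tracer infusions, a p-value would be theater.

## The synthetic cohort generator

`generate_cohort()` draws virtual cohorts whose every programmed effect is
known, so each pipeline stage has a recovery-testable input:

* Arterial concentrations are lognormal around genotype set-points
  (biological CV 20%) with a litter-shared multiplicative effect (CV 10%)
  — the component littermate pairing is designed to absorb.
* Each organ's outflow is its resolved inflow times
  $2^{f - s\,\log_2(C_A/\mathrm{setpoint})}$, where $f$ is the programmed
  base flux and $s$ a homeostatic slope (zero for uncoupled cells).
* Urine is arterial $\times (1-\mathrm{efficiency}) \times$ a
  concentration factor; the factor cancels from every index.
* Every emitted count — samples, the constant internal-standard spike, and
  pooled-QC injections — carries independent multiplicative lognormal
  measurement noise (default technical CV 5%, a typical value for
  HILIC-orbitrap peak areas; five filler metabolites carry 120% CV so the
  QC filter has genuine exclusions to make).

The default `"cf_piglet"` scenario programs the headline biology of a
newborn CF-pig cohort: arterial tyrosine divided by 3 and glutamate
doubled in CF; broad WT liver amino-acid release largely lost in CF; lung
LCFA uptake attenuated in CF except arachidonic acid, whose uptake in
concentration units is amplified about 3-fold; 12 kidney homeostats (10
amino acids, glucose, 3-hydroxybutyrate) in WT only; CF amino-acid and
lactate reabsorption efficiency halved; 5-fold CF tracer leakage.

What the generator deliberately does **not** emulate: LC-MS batch drift
and retention-time shifts (the preprocessing module's scope ends at the
internal standard), between-metabolite correlation structure, missingness
mechanisms other than nonpositive counts, and any mechanistic physiology
(flow rates, enzyme kinetics). Passing recovery tests therefore
demonstrates that the *statistical* pipeline inverts the *statistical*
generative structure it assumes — not that it is robust to every artifact
of real instruments.

## Numerical choices

* QC CV uses the sample (n−1) standard deviation — injection counts are
  small — and the exclusion boundary is a strict `>` at threshold 50.
  CVs are computed after internal-standard normalization of the QC series.
* Replicate collapsing is the median (midpoint for even counts) and
  precedes every ratio computation.
* Samples whose range is within $10^{-10}$ of zero at their scale are
  treated as constant: equal to the null location gives $p = 1$;
  off-null constants fall through to the signed-rank test. This guards
  the noise-free limit, where floating-point residue would otherwise
  reach `t.test` as "essentially constant" data.
* Zero paired differences are dropped before the signed-rank test
  (standard convention); exact distributions are used whenever the data
  are tie-free and $n \le 25$.
* The $\pm k$ SD outlier rule is single-pass: mean and SD come from the
  full input and are not re-estimated after removal.

## Validation problem sizes

The test suite verifies the exact signed-rank p-values against full
$2^n$ sign enumeration for $n \le 12$ and BH q-values against the
brute-force step-up definition on 1,000 random vectors; type-I error of
the gated location test over 5,000 null samples at $n = 8$; flux-sign and
edge recovery over 100 simulated cohorts at 5% technical CV (a dense
all-cells-programmed scenario with $|f| \ge 1$, where recovery measures
detection rather than the $\alpha$-rate background of sparse panels); and
the full CF-piglet scenario end to end at one fixed seed. These sizes are
the package's chosen compromise between statistical resolution and a test
suite that runs in a couple of minutes.

## Known limitations

* Gradient statistics, not flows: organs with high blood flow and small
  gradients are systematically harder to detect than low-flow organs with
  large gradients.
* The exchange graph is qualitative; edge counts are sensitive to
  $\alpha$ and to panel size through the false-call background.
* Exact "count equals programmed truth" statements about screens are
  intrinsically probabilistic at realistic noise — the expected
  false-positive background of an uncorrected 224-cell screen is ~11
  cells, and no seed-free procedure can promise zero.
* The Shapiro-Wilk gate at $n = 8$ has little power; in practice most
  cells route to the t test. This matches the field's convention rather
  than any optimality claim.
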