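---
title: "Dose-response modelling for single high-dose BNCT: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response modelling for single high-dose BNCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnctcp)
```

## The problem

Boron neutron capture therapy (BNCT) delivers most of its tumor dose in one
or two large fractions through the ^10^B(n,&alpha;)^7^Li capture reaction, and
the dose inside a tumor is markedly non-uniform (drug uptake and a single
neutron portal both vary across the volume). Two consequences drive this
package's design:

1. the linear-quadratic (LQ) model, calibrated on ~2 Gy photon fractions,
   extrapolates badly to 15-30 Gy-w single deliveries, so a high-dose-valid
   survival model is needed before any isoeffect conversion; and
2. a single dose number cannot summarize a non-uniform tumor distribution,
   so tumor control probability (TCP) must be computed from the full
   dose-volume histogram (DVH).

The package chains four stages: cell-survival modelling, isoeffect (BED /
EQD2) conversion of the weighted dose, gEUD reduction of the EQD2 DVH, and a
logistic TCP with response classification.

## Cell-survival models

Four ln-survival forms are implemented (`ln_survival()` dispatches on the
parameter class):

* **LQ**: $\ln S = -(\alpha d + \beta d^2)$;
* **USC** (universal survival curve): LQ up to a transition dose $D_T$, then
  the multi-target line $\ln S = -(d - D_q)/D_0$;
* **LQL**: LQ up to $D_T$, then the straight line of slope
  $\gamma = \alpha + 2\beta D_T$ through the LQ value at $D_T$;
* **PLQ** (Padé LQ): $\ln S = -(\alpha d + \beta d^2)/(1 + \gamma d)$.

Requiring the USC's two branches to agree in value *and* slope at $D_T$
forces

$$D_T = \frac{2 D_q}{1 - \alpha D_0}, \qquad
  \beta = \frac{(1 - \alpha D_0)^2}{4 D_q D_0}.$$

The squamous-cell reference coefficients shipped as `usc_params_scc()`
($\alpha = 0.2111$ Gy$^{-1}$, $\beta = 0.0890$ Gy$^{-2}$, $D_0 = 0.9603$ Gy,
$D_q = 1.8588$ Gy, $D_T = 4.6628$ Gy) satisfy both relations to printed
precision, which is why `fit_survival_model(..., "usc")` treats
$(\alpha, D_0, D_q)$ as the free parameters and *derives* $\beta$ and $D_T$:
the fitted curve is then C1 at the join by construction, and the fit has 3
free parameters, comparable to LQL and PLQ.

A consequence worth knowing: under this constraint the USC tail is the
tangent line to the LQ parabola at $D_T$ — exactly the LQL construction — so
USC and LQL describe the same curve family and their fits tie to optimizer
precision. `compare_models()` ranks by the standard error of the estimate
(SEE) and breaks ties by fewer free parameters, then by listing order (USC
before LQL).

### Fitting choices

* **Objective**: unweighted least squares in $\ln S$ space (optional per-point
  weights). The source datasets report no replicate SDs, and multiplicative
  lognormal assay noise is additive on $\ln S$.
* **SEE**: $\sqrt{\sum r_i^2 / (N - p)}$ in $\ln S$ space with $p$ free
  parameters (2 for LQ, 3 otherwise). The statistic is named but not defined
  in the source literature; this is the standard residual-standard-error
  definition, in the same space as the objective.
* **Optimizer**: box-constrained L-BFGS-B from a data-driven start (LQ
  regression on the low-dose half, straight-line tail for $D_0, D_q$) plus 10
  Latin-hypercube restarts (seed 20240229, configurable), then a Nelder-Mead
  + L-BFGS-B polish. The piecewise objective has local minima, and
  finite-difference gradients alone stalled a few percent short of the
  optimum in development, hence the polish. USC is optimized in
  $(\alpha,\, x = \alpha D_0,\, D_q)$ with $x < 0.99$ so the multi-target
  branch stays valid throughout.
* **Zero-dose points** ($S = 1$) are retained: they anchor the intercept.

## Weighted dose and isoeffect conversion

The BNCT weighted dose (Gy-w) is
`cbe_boron * boron + rbe_neutron * (thermal + fast) + gamma_weight * gamma`
(`weighted_dose()`), with defaults RBE 3.2, tumor CBE 3.8 (1.3 for normal
tissue), gamma weight 1.0.

For a single delivery $D_{BNCT}$ at or above $D_T$ the USC biologically
effective dose is $BED = (D_{BNCT} - D_q)/(\alpha D_0)$, and equating it with
the LQ BED of $n$ 2-Gy fractions gives

$$EQD_2 = \frac{BED_{BNCT}}{1 + 2\beta/\alpha}.$$

Two numerical policies here were genuinely open:

* **Doses between $D_q$ and $D_T$** still follow the multi-target line, with
  a warning, rather than silently switching branch: the single-delivery
  formula is stated unconditionally for BNCT, and a branch switch would make
  the DVH conversion non-monotone at the boundary. Below $D_q$ (negative
  BED) conversion is an error.
* **The $2\,\mathrm{Gy} \ge D_T$ regime** (never reached with the SCC
  coefficients, whose $D_T = 4.66$ Gy) is implemented in `eqd2_from_bnct()`
  as $EQD_2 = D_{BNCT} + (n-1) D_q$ with $n$ the smallest whole number of
  2-Gy fractions covering the result, resolved by fixed-point iteration and
  flagged via the `branch` attribute. `eqd2_dvh()` refuses this regime
  outright rather than guessing a per-bin $n$.
* **Fractions**: `eqd2_dvh(..., fractions = n)` reads bin doses as
  per-fraction doses delivered identically $n$ times and sums BED before the
  isoeffect division. The default is 1 — the single-delivery reading under
  which the published per-target gEUD/TCP values are reproducible — although
  the underlying trial delivered two fractions; whether published minimum
  doses are per-fraction or totals is not stated in the source, and the
  default leaves that interpretation to the caller.

## gEUD and the logistic TCP

The generalized equivalent uniform dose of a differential DVH
$\{(v_i, D_i)\}$ is the power mean
$gEUD = (\sum_i v_i D_i^a)^{1/a}$. For tumors $a < 0$ ($-13$ for squamous
cell carcinoma), which weights the distribution toward its coldest part:
the error of the $a \to -\infty$ limit is bounded by
$gEUD \le D_{min} \, v_{min}^{1/a}$, so the minimum dose dominates to the
extent that its bin carries volume. `geud()` computes the sum in log space
(log-sum-exp); at $a = -13$ and clinical dose levels the naive power sum is
already within ~15 orders of magnitude of underflow, and the log-space path
agrees with the naive oracle to $10^{-10}$ relative where the latter is
representable. Bins with dose $\le 10^{-6}$ under $a < 0$ are an error — a
diverging term, never clamped.

TCP is the logistic
$$TCP = \frac{100}{1 + (TCD_{50}/gEUD)^{4\gamma_{50}}} \ [\%],$$
with photon-derived $TCD_{50} = 46.8$ Gy and $\gamma_{50} = 2.0$ for
squamous cell carcinoma. Because those parameters live on the EQD2 scale,
**gEUD is computed on the EQD2-converted DVH**, never on raw Gy-w — this is
what makes the published per-target values reproducible. The quoted
$TCD_{50}$ uncertainty (±6.4 Gy) is stored in `tcp_params()` but not
propagated; a sensitivity sweep is a one-liner over `tcp_params(TCD50 = ...)`.
TCP ≥ 60% is classified complete-response level, ≥ 25% partial-response
level (inclusive boundaries, matching "at least" phrasing), else sub-PR.
Full precision is kept internally; `format_tcp_report()` rounds half-up to
one decimal at the reporting layer only.

A reproducibility caveat the tests encode: published per-target TCP values
were evidently computed from unrounded gEUDs, so re-evaluating the logistic
at the *printed* (1-decimal) gEUD reproduces them only to the printed
precision — up to ~0.13 pp of drift on 14 targets. The tests therefore
assert agreement to one unit in the last printed decimal, not bitwise
rounding equality.

## What the synthetic generators emulate

Clinical DVHs and the original clonogenic dataset are not redistributable,
so seeded generators stand in for both.

**`simulate_survival_data()`** draws
$S_i = \exp(\ln S(d_i) + \varepsilon_i)$, $\varepsilon_i \sim N(0,
\sigma^2)$, clipped to $(0, 1]$ — multiplicative lognormal noise on $S$,
i.e. homoscedastic noise in the fitting space. Defaults: the SCC USC
parameters, a 0.5-12 Gy grid in 0.5 Gy steps (24 points spanning both
branches of $D_T = 4.66$ Gy, a typical clonogenic-assay range) and
$\sigma = 0.1$, a realistic assay scatter. Under these defaults a
200-replicate calibration run fixed the fitting bounds the tests assert:
median relative $\alpha$ error below 15%, and the USC ranked first by SEE in
≥ 90% of replicates.

**`simulate_dvh()`** is built around the two quantities that decide TCP in
practice: the exact minimum dose and the cold-spot volume. The cold tail on
$[D_{min}, \text{cold edge})$ has cumulative volume growing as the *cube* of
the dose distance from the minimum — the volume of an approximately
point-like underdosed region grows like the cube of its linear extent — plus
an atom of $10^{-3}$ of the cold volume exactly at $D_{min}$ (a single-voxel
scale: a ~50 cm³ tumor on a 2 mm grid has several thousand voxels). The
remaining volume is a discretized scaled Beta (or two-component Beta
mixture) with a chosen mode, at 0.1 Gy-w resolution, optionally jittered
bin-wise. The cubic exponent and atom size were chosen once, from geometry,
before any acceptance measurement. By construction
`volume_fraction_below(h, cold_edge)` equals the requested cold volume
exactly and `min_dose(h)` the requested minimum.

What a green test does *not* establish: real DVH shapes (multimodal uptake,
necrotic cores, bin-width artifacts of planning systems) are not emulated,
and nothing here validates the photon-derived TCP parameters for BNCT's
different microdosimetry — the generators test the *machinery*, not the
clinical calibration.

## Known limitations

* The TCP parameters ($TCD_{50}$, $\gamma_{50}$, $a$) are photon-derived;
  their transfer to BNCT is an assumption of the approach, not something the
  package can test.
* The USC/LQL equivalence under the smooth-join constraint means SEE cannot
  distinguish them; rankings place USC first by convention.
* No DICOM-RT input (the text DVH dialect is the only one), no
  normal-tissue (NTCP) modelling, no treatment-plan optimization, no
  propagation of the $TCD_{50}$ uncertainty.
* The subvolume-based alternative to EUD-based TCP is out of scope.
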