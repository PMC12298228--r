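---
title: "A genotype-stratified model of losartan pharmacokinetics and pharmacodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A genotype-stratified model of losartan pharmacokinetics and pharmacodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(losartanpkpd)
```

## The model and its assumptions

Oral losartan passes through five compartments — stomach, intestine,
enterocyte, central, peripheral — connected by first-order reactions. The
dose enters the stomach as an initial assignment (in nmol:
`dose_mg · 10⁶ / 461.01`, the molecular weight of losartan potassium).
Three mechanistic features distinguish the model from a plain catenary
absorption chain:

* **Pulsatile gastric emptying.** The pyloric valve opens and closes
  periodically; the emptying rate is the nonnegative sinusoid
  `a (1 + sin(2πt/b)) / 2` with amplitude `a` (h⁻¹) and period `b` (h).
  Over one cycle the mean rate is `a/2`. The functional form is pluggable
  (`valve = "constant"` recovers a fixed-rate stomach, used by the
  closed-form regression tests).
* **Enterocyte efflux.** Absorbed drug enters the enterocyte pool, from
  which it either proceeds into the circulation (`k_ent_cc`) or is pumped
  back into the lumen by the ABCB1 transporter (`k_ent_int`). Because the
  default model has no luminal loss, efflux does not destroy drug — it
  recirculates it, slowing absorption. This is why the low-activity
  TT/TT diplotype shows a *higher, earlier* losartan peak than GG/CC
  while all diplotypes share the same total exposure. An optional
  first-order luminal loss `k_int_ex` (default 0) is provided; with it,
  efflux also reduces total exposure.
* **Delayed conversion.** CYP2C9 turns losartan into E-3174 with a fixed
  delay `T`: the conversion flux at time `t` is `k_m · A_cc(t − T)`, zero
  before `T` (discrete switch-on, zero pre-dose history). The flux is
  applied symmetrically — the same term leaves central losartan and
  enters central E-3174 — so total drug mass is conserved at every
  instant.

All reactions being first order, curves scale exactly with dose; the
package exploits this in tests and in the dose-linear shortcut for the
E-max anchors.

### Well-posedness of the delayed flux

A symmetric delayed loss can overdraw its substrate: if central losartan
declines quickly (fast absorption, high `k_m`), the flux scheduled from
the level `T` hours ago may exceed what is left, driving the state
negative. This is a genuine property of the pure delayed form, not a
solver artifact (it reproduces at `rtol = 1e-10`; between-subject draws
for the TT/TT diplotype reach several hundred nmol below zero). The
package therefore damps the conversion flux with the factor
`clamp(A_cc/ε, 0, 1)`, `ε = 10⁻⁴ ×` dose: the factor is exactly 1
whenever the substrate exceeds ε (so ordinary trajectories are unchanged,
bit for bit), and shuts the flux off linearly as the compartment empties.
Because the same damped flux feeds the metabolite, mass balance is
untouched. Residual solver undershoot is clamped to zero on output only
if it is tiny; states below `−100·atol·dose` abort with an error rather
than being silently repaired.

## Parameters

| name | meaning | unit | default |
|------|---------|------|---------|
| `a` | gastric-valve amplitude | 1/h | 1.5 |
| `b` | gastric-valve period | h | 1 |
| `k_int_ent` | intestine → enterocyte absorption | 1/h | 1.5 |
| `k_ent_int` | enterocyte → intestine ABCB1 efflux | 1/h | 151.485 |
| `k_ent_cc` | enterocyte → central absorption | 1/h | 40 |
| `k_m` | losartan → E-3174 conversion (CYP2C9) | 1/h | 2.817 |
| `T` | conversion delay | h | 0.5 |
| `CL_m` | apparent E-3174 clearance | L/h | 6.373 |
| `Vm` | apparent E-3174 volume | L | 37.7 |
| `CL_p` | apparent losartan clearance | L/h | 43.867 |
| `Vp_1` | apparent central losartan volume | L | 12.966 |
| `Q` | central↔peripheral clearance | L/h | 2 |
| `Vp_2` | apparent peripheral volume | L | 20 |

The disposition block (`CL_p`, `Vp_1`, `CL_m`, `Vm`) is calibrated
algebraically to the exposures reported clinically for wild-type Korean
subjects after 50 mg: in this loss-free model the losartan exposure is
`AUC = dose / (k_m·Vp_1 + CL_p)`, so the wild-type and poor-metabolizer
exposures (≈1.35·10³ and ≈2.44·10³ nmol·h/L) pin down `Vp_1` and `CL_p`
jointly; the metabolite exposure (≈7.7·10³ nmol·h/L) then fixes
`Vp_1/CL_m`, and a metabolite terminal half-life near 4 h fixes `Vm`.
The absorption block (`a`, `b`, `k_int_ent`, `k_ent_cc`, `T`, `Q`,
`Vp_2`) is not identified by exposures alone; the defaults were chosen
once for physiological plausibility — gastric emptying on the hour
scale, enterocyte exchange fast relative to emptying so that the efflux
ratio `k_ent_cc/(k_ent_cc + k_ent_int)` governs the genotype contrast —
and kept fixed thereafter. They reproduce the qualitative genotype
ordering (TT/TT: highest losartan peak, earliest peak times for both
analytes) rather than any particular subject's curve.

Genotype stratification replaces exactly one constant per gene:
`k_m` for the two homozygous CYP2C9 genotypes, `k_ent_int` for the three
ABCB1 diplotypes. Heterozygotes and rare diplotypes are rejected rather
than interpolated — the constants exist only for the fitted set. When a
CYP2C9 genotype is simulated, the unknown ABCB1 background is taken to be
GT/CT (the most frequent diplotype in the population the constants come
from); ABCB1 simulations assume a wild-type CYP2C9 background.

## PK metrics

`pk_summary()` computes, per analyte: the peak `C_max` and its earliest
time `t_max` on the dense grid (default output step 0.01 h, fine enough
that grid quantization is below the reporting precision); the exposure
`AUC(0→horizon)` carried as an auxiliary solver state (`dAUC/dt = C`),
with windowed values obtained as differences of clipped integrals; the
terminal half-life from an ordinary least-squares line through
`(t, log C)` at the fixed anchors 6, 8 and 10 h (`t½ = ln 2 / −slope`),
with spline interpolation to the anchors when the grid misses them and
explicit errors for nonpositive anchor concentrations or a nondecreasing
line; and for losartan the apparent oral clearance
`CL/F = dose·10⁶ / (AUC · 461.01)`, defined as 0 while plasma losartan is
identically zero. The "infinite" AUC horizon defaults to the simulation
horizon; 48 h covers more than five terminal half-lives of both analytes
at the default parameters, and a convergence check can flag truncated
integrals. The curve-comparison statistic `D` is the Euclidean distance
over time points common to two sampled curves, per analyte or stacked.

The 6/8/10 h anchors deserve a caveat: they sit in the true terminal
phase of losartan, but for slowly-absorbing genotypes the metabolite is
still near its peak at 6 h, so the metabolite "terminal" half-life from
these anchors is biased long. The anchors are kept fixed because the
quantity is defined by them; they are configurable.

## The E-max coupling

Metabolite exposure maps to a fractional AT1-receptor-blocking
coefficient through `k_block = E_max·AUC^α / (ED_50^α + AUC^α)`, with
`k_block = E_max/2` at `AUC = ED_50` exactly. The shipped reference
coefficients (`E_max = 0.955`, `ED_50 = 5304.326` nmol·h/L,
`α = 6.785`) reproduce the three anchor effect levels: a 25 mg daily dose
is clinically placebo-like (`k_block = 0.1`), 50 and 100 mg correspond to
0.886 and 0.954. The anchors' exposures are the 50 mg GG/CC metabolite
exposure and its half/double (exact dose linearity of the first-order
model). `fit_emax()` refits the coupling by unweighted least squares on
`k_block`; steep Hill fits have a well-known local-minimum trap, so the
optimizer is a multi-start (25 seeded starts) bounded L-BFGS-B on
`(E_max, log ED_50, log α)` with `α ∈ [0.5, 20]`. The refit recovers the
reference `ED_50` and `E_max` to well under 1%. `kblock_table()` produces
the genotype × dose hand-off table by full simulation (48 h horizon).

## Calibration, identifiability, sensitivity

The objective is the equally-weighted sum of squared concentration
residuals over both analytes and all genotype groups (relative and
log-residual variants are available); the loss was an open design choice
and ordinary least squares is the default a practitioner would expect.
`losartan_fit()` searches the log-parameter box with a compact seeded
particle swarm (inertia 0.7298, cognitive/social 1.49618, reflecting
bounds; swarm size `10 + 2d`), then polishes with L-BFGS-B. Failed or
non-finite evaluations get a large finite penalty so the swarm can cross
infeasible regions. Everything is reproducible under `--seed`/`seed`.
The two-stage protocol (`losartan_fit_staged()`) mirrors the staged
stratification: first `k_m` per CYP2C9 genotype with shared globals, then
`k_ent_int` per ABCB1 diplotype with the stage-1 `k_m` fixed.

Identifiability is profiled by fixing one fitted parameter on a grid
bracketing the optimum, re-optimizing the rest, and asking whether the
loss rises significantly on both sides (identifiable), one side
(partially identifiable — e.g. a near-zero efflux rate is only bounded
from above), or neither. "Significant" means a rise above 5% of the
fitted loss, floored by the numerical noise of the objective
(`100·n·(rtol·RMS(obs))²`): with noise-free data the fitted loss is
essentially zero, and without the floor the solver's step-size jitter
would make every flat direction look informative.

Sensitivities are forward-difference elasticities,
`SS = (C(α+Δα) − C(α))/Δα · α/C(α)`, with an absolute perturbation
`Δα = 10⁻⁶` by default; for parameters far below `10⁻⁶` (the TT/TT
efflux constant) a relative-step mode is used and flagged in the output.
At the wild-type parameterization the signs follow the mechanism:
raising `k_m` lowers losartan exposure and raises metabolite exposure;
raising `CL_p` lowers both; raising `k_ent_int` lowers the losartan peak.

## Virtual population and group comparison

Between-subject variability draws every parameter independently from
`Normal(median, 0.10 × median)` — the optimized values are treated as
medians — truncated to positive values *by resampling*, which preserves
the distribution's shape near the mode better than clipping (at SD = 10%
of the median, truncation is astronomically rare anyway; it matters for
user-supplied larger spreads). The default design draws 100 subjects per
ABCB1 diplotype (300 parameter sets) at 50 mg and summarizes `C_max`,
`t_max` and AUC per draw. Each genotype gets independent draws of every
parameter, as in a design that samples each genotype group separately; a
`matched` mode shares the global-parameter draws across genotypes for
variance-reduced contrasts.

Group comparison follows the gated procedure standard in clinical PK
reporting: Shapiro–Wilk normality per group and a Brown–Forsythe
(median-centred Levene) equal-variance check, both at p < 0.05, choose
between the pooled-variance t-test and the Mann–Whitney rank-sum test for
pairwise contrasts; the omnibus test is a Kruskal–Wallis one-way ANOVA on
ranks; pairwise significance uses the Bonferroni cutoff
`0.05 / number of groups` (0.0167 for the three diplotypes). P-values use
the asymptotic approximations with continuity correction, recorded in the
report. Under a simulated null the pairwise rejection rate at the 0.0167
cutoff stays at or below 2.5%.

## Synthetic data

The generator emulates the structure of sparse single-dose PK studies:
sampling at 0.25–24 h (including the 6/8/10 h half-life anchors), two
analytes, and multiplicative noise. Noise is mean-one lognormal with
`σ² = log(1 + CV²)` and `meanlog = −σ²/2`, so the per-point coefficient
of variation equals the nominal CV *exactly* and the sample mean is an
unbiased estimator of the true curve (mean curves converge to the truth
as subjects accumulate). What it deliberately does not emulate: assay
quantification limits and censoring, correlated residuals within a
subject, digitization error of published figures, and covariate
structure beyond genotype. Passing the closed-loop recovery tests
therefore demonstrates that the estimation machinery works when the
model is true and the error model is benign — not that the model is
identified by any particular clinical dataset.

## Numerical choices

Solver tolerances default to `rtol = 10⁻⁸`, `atol = 10⁻¹⁰` (the
calibration objective uses `10⁻⁶`/`10⁻⁸` for speed); the delay equation
is integrated by `deSolve::dede` with a compiled right-hand side, and its
agreement with an independent method-of-steps integration is a test
invariant (relative sup-norm below 10⁻⁵ over three delay spans). Ties in
`t_max` resolve to the earliest grid time. `AUC(x→y)` with `x = y` is 0;
`x > y` errors. Zero dose yields identically zero curves without
touching the solver.

Test problem sizes are chosen to keep the default suite fast while still
exercising the claimed properties: the population ordering check runs 100
subjects per diplotype; the null-calibration check runs 1000 simulated
null datasets of three groups of 30; parameter-recovery replicates run
twenty seeded repetitions of a one-parameter refit on 5%-noise curves,
plus one multi-parameter (shared `k_m`, per-genotype `k_ent_int`)
noise-free recovery.

## Known limitations

* Single oral dose only; no accumulation or multiple-dose regimens.
* The absorption-side parameters are plausible rather than identified;
  only their exposure-relevant combinations are pinned by the
  calibration targets.
* Heterozygous CYP2C9 and rare ABCB1 diplotypes are rejected by design;
  nothing in the constants table supports interpolation.
* The terminal-half-life metric inherits the fixed 6/8/10 h anchors'
  bias for curves still rising at 6 h.
* The blocking coefficient is the hand-off artifact; simulating blood
  pressure itself requires an external cardiorenal model and is out of
  scope.
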