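---
title: "Correlation networks of exercise-induced fatigue: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation networks of exercise-induced fatigue: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatiguenet)
```

## The scientific problem

Fatigue during exhaustive exercise is not driven by a single variable: force
production, running velocity, power output, blood lactate kinetics, heart
rate and individual fitness capacities change together as a subject
approaches exhaustion. `fatiguenet` treats one bout of exhaustive exercise at
a fixed intensity as a system of interacting variables and asks which
variable is most *influential* at each intensity. Variables become nodes of
a network; a link connects two variables when their Pearson correlation
across participants is at least moderate in magnitude; link weights are
correlation magnitudes. Comparing networks across intensities then shows how
the dominant node shifts as efforts become harder and times to exhaustion
shorter.

The package covers the full analysis chain:

1. a synthetic cohort generator with configurable means, SDs and
   inter-variable correlation structure (so that every downstream stage is
   testable without access to raw measurements);
2. the hyperbolic critical-power model $T_{lim} = AWC/(P - CP)$ relating
   sustainable power to time to exhaustion;
3. thresholded, weighted, undirected correlation networks per intensity;
4. node influence metrics: degree, eigenvector influence, betweenness
   centrality, and the discrete influence dynamics $S(t) = C^t S(0)$;
5. one-way ANOVA with Student–Newman–Keuls (SNK) post hoc letters across
   intensities;
6. a deterministic end-to-end pipeline with CSV/JSON reporting.

## The variables

Twelve network nodes: five mechanical (force N, velocity m/s, mean power W,
peak power W, work kJ) and seven physiological or subject-level variables
(heart rate bpm, peak blood lactate mmol/L, lactate time s — the time until
the post-exercise lactate peak — lean mass %, aerobic capacity W, anaerobic
capacity kJ, and a physical-activity questionnaire score in MET·min/week).
The time limit (time to exhaustion, s) is the fatigue outcome and is not a
node. Subject-level variables are measured once per participant and are
constant across intensities; within one intensity slice they still vary
*across* participants, which is what makes them correlatable with the
per-intensity measurements.

## The synthetic cohort generator

### Sampling model

The generator's distributional family is a multivariate normal backbone:
per intensity, latent standard normal vectors with the target correlation
matrix are rescaled affinely to the configured means and SDs. The defaults
are calibrated to a nine-participant, four-intensity tethered-running
protocol (e.g. mean time limit 626.08 ± 149.27 s at the lowest intensity
falling to 173.75 ± 62.68 s at the highest; see `default_means()` /
`default_sds()` and the subject-level defaults in
`default_subject_means()`). The normal family is the simplest one matching
the mean/SD/correlation structure the downstream analysis consumes; it was
chosen once and is not revisited.

Subject-level variables are drawn once per participant. To keep the full
target correlation valid at *every* intensity while holding these variables
fixed within participant, the per-intensity block is drawn conditional on
the subject-level latents: with the target partitioned into subject block
$\Sigma_{ss}$, cross block $\Sigma_{ps}$ and per-intensity block
$\Sigma_{pp}$, the per-intensity latents are
$z_p \mid z_s \sim N(\Sigma_{ps}\Sigma_{ss}^{-1} z_s,\;
\Sigma_{pp} - \Sigma_{ps}\Sigma_{ss}^{-1}\Sigma_{sp})$.

No observed inter-variable correlation matrix is published for the
calibration data, so the default target (`default_correlation()`) is an
explicitly labelled *plausible* matrix — strong mechanical
inter-correlations (0.6), moderate physiological coupling (0.35), moderate
capacity-to-mechanical coupling (0.4), weak residual background (0.15) —
not an empirical estimate. Users supply their own target per intensity when
they have one.

### Positivity and its bias

All physical quantities must be strictly positive. The generator enforces
this by resampling offending draws (up to 200 rounds), i.e. by truncating
the normal at zero. For variables whose mean is several SDs above zero this
is invisible; where the mean/SD ratio is small the truncation biases the
moments by a known closed form (for a normal truncated below at zero the
mean shifts by $\sigma\,\varphi(\mu/\sigma)/\Phi(\mu/\sigma)$). With the
default calibration this matters for exactly three cells — lactate time at
the highest intensity ($\mu/\sigma = 1.72$, mean shift ≈ +5%), anaerobic
capacity and the questionnaire score ($\mu/\sigma \approx 1.8$, ≈ +4%) —
and the test suite checks those cells against the truncated-normal closed
form rather than the raw configured values. Setting `positive_only = FALSE`
recovers the exact configured moments at the cost of occasional negative
draws.

### Physics consistency

With `physics_consistency = TRUE` the generator overwrites three variables
with their mechanical identities, in order: mean power as force × velocity,
the time limit as $AWC/(P - CP)$ using the participant's own anaerobic
capacity (converted kJ → J) and aerobic capacity as CP, and work as
mean power × time limit / 1000 (kJ). Each identity is perturbed by relative
Gaussian noise of scale `noise_scale` (default 0.05; 0 gives machine-exact
identities). Records whose sampled mean power falls at or below CP have no
finite hyperbolic time limit; they keep a positive resample of the
configured marginal instead, and persistent failures raise an error naming
the participant. This option makes the cohort internally consistent with
the critical-power model, at the price of distorting the configured
marginal distributions of the three recomputed variables — hence it is off
by default and the Table-calibration and physics modes are tested
separately.

### Planted hubs and PSD repair

`planted_hub_config()` builds the recovery fixture: one variable correlated
at `hub_strength` with all others, all remaining pairs at `background`. A
hand-built hub matrix is usually *not* positive semi-definite — with zero
background and hub strength $s$ over $k$ variables the smallest eigenvalue
is $1 - s\sqrt{k-1}$, clearly negative for the interesting regimes — so the
matrix is repaired by clipping negative eigenvalues to $10^{-8}$ and
re-normalising the diagonal to one. The repair is recorded in the config and
shrinks the planted contrast (0.8/0.1 over 13 variables becomes roughly
0.46/0.14 after repair), which still separates hub from background cleanly
at the 0.3 link threshold. Non-PSD matrices passed directly to
`generate_cohort()` are rejected with the offending eigenvalue rather than
silently repaired.

## The critical-power model

$T_{lim} = AWC/(P - CP)$: CP (W) is the power asymptote sustainable without
fatigue, AWC (J) the fixed work budget available above it. Two canonical
estimators are provided, because the estimation procedure is a free choice
in this literature:

* `fit_cp_linearized()` — ordinary least squares of $P$ on $1/T_{lim}$
  (intercept CP, slope AWC in watt-seconds);
* `fit_cp_hyperbolic()` — direct nonlinear least squares on the hyperbola
  (Levenberg–Marquardt via `minpack.lm`), initialised from the linearization
  and constrained to CP below the smallest observed trial power. This is the
  default in the pipeline; the two agree to $10^{-6}$ relative on noiseless
  data.

AWC is stored in joules throughout and converted explicitly at I/O
boundaries (reports carry kJ alongside). Trials outside the 2–10 min
exhaustion window trigger a validation warning, not an error — group-mean
times at the hardest intensity sit near the lower bound, so a hard error
would reject realistic data. Group-mean fits are well-posed but are *not*
expected to reproduce the mean of individual fits (fitting is nonlinear),
and the package makes no such claim.

## Network construction

Within one intensity, every unordered pair of node variables is correlated
across participants (Pearson). Magnitude classification: weak below 0.3,
moderate from 0.3 up to 0.7, high from 0.7. The defining inequalities are
strict on both sides, leaving the boundary points unassigned; this package
assigns boundaries to the stronger class — a deterministic convention with
measure-zero effect on continuous data. Thresholds are configurable, which
also supports the monotonicity property (raising the moderate threshold can
only remove links).

Moderate and high pairs become undirected links; correlation is symmetric,
so influence is modelled as bidirectional and the connection matrix $C$ is
symmetric with zero diagonal. Two weighting modes exist because two natural
conventions exist: `"raw"` (default) weights a link by $|r|$ — a correlation
of 0.75 is a 75% influence — while `"max_normalized"` divides by the largest
$|r|$ over surviving links so the strongest link has weight 1. The mode is
recorded in every report. Negative correlations link by magnitude; the sign
is kept in the per-pair records for reporting but does not affect topology
or weight. Constant variables (zero variance) have undefined correlations;
they are retained as isolated nodes with a warning rather than dropped, so
the node set is stable across intensities.

With nine participants, sample correlations of independent variables exceed
0.3 easily by chance (the SD of $r$ under independence is about 0.35), so
small-cohort networks contain spurious links. The package surfaces this as
a documented caveat rather than correcting for it: no multiple-testing
correction is applied, matching the analysis the package operationalises.

## Influence metrics

* **Degree** — the number of incident links; the maximum-degree node is the
  hub.
* **Eigen-influence** — the absolute components of the eigenvector of the
  largest eigenvalue of $C$, rescaled to maximum 1 (for a nonnegative
  symmetric $C$ this is the Perron eigenvector). Attributing one eigenvalue
  to each node is not mathematically well defined — eigenvalues belong to
  the matrix — so the package operationalises per-node influence as
  eigenvector centrality and reports the full eigenvalue list and the
  spectral radius at network level. This choice is forced by the dynamics:
  the asymptotic direction of $S(t) = C^t S(0)$ *is* the dominant
  eigenvector, and the growth rate is the spectral radius.
* **Betweenness** — on the binarized graph, each node accrues, over all
  unordered source–target pairs excluding itself, the fraction of shortest
  paths passing through it (Brandes-style fractional splitting; an integer
  counting mode is available via `mode = "count"`). Disconnected pairs
  contribute nothing. Weighted shortest-path betweenness is deliberately
  not offered: the correlation weights carry no distance semantics, and
  inventing a transform (e.g. $1/w$) would add an undocumented modelling
  choice.
* **Dynamics and stability** — `propagate_influence()` iterates
  $S(t+1) = C\,S(t)$; `stability_class()` labels the network growing,
  decaying or marginal by its spectral radius against 1 with tolerance
  $10^{-9}$. The per-node asymptotic statement "$s_i = v_i^t s_i(0)$" holds
  only along eigendirections; the package therefore reports the network
  growth rate rather than pretending each node has a private eigenvalue.
* **Ranking** — argmax nodes per metric, with ties reported in full, sorted
  by node name; never a silent first-wins.

## Group statistics

One-way fixed-effects ANOVA per variable across intensities (the design
re-uses the same participants at every intensity, but the analysis this
package operationalises treats intensities as independent groups, so a
plain one-way layout is used), followed by the SNK stepwise procedure on
the ordered means: the widest span is tested first against
`qtukey(1 - alpha, p, df)` for its stretch `p`; significant spans are split
and recursed, and every pair inside a retained (non-significant) span is
blocked as non-different. Unbalanced groups use the harmonic mean group
size, a standard SNK adaptation (the calibration design is balanced at
n = 9, so this is a robustness extra). Results carry the compact letter
scheme "a/b/c = different from intensity 1/2/3". Studentized-range
quantiles come from `stats::qtukey`. Literally identical groups (zero
error variance, equal means) are reported as "no differences"; zero error
variance with *different* means is a certain separation and is flagged
as such.

## Numerical choices and degenerate inputs

* PSD validation tolerance: eigenvalues ≥ −10⁻¹⁰ accepted; repair floor
  10⁻⁸.
* Conditional-covariance round-off in the generator is clipped at zero
  before sampling.
* Eigen residuals: every eigenpair satisfies
  $\lVert Cv - \lambda v\rVert \le 10^{-10}\lVert C\rVert$ (tested).
* The empty network has spectral radius 0 (decaying) and all
  eigen-influence 0 — the max-1 normalisation is undefined there and 0 is
  reported instead.
* Report JSON prints 6 significant digits; full-precision values live in
  the CSV sidecars, and tests compare against the in-memory report.
* Determinism: the generator seed fully determines the cohort, and a fixed
  configuration yields byte-identical report files.

## What the tests do and do not show

The test suite and the planted-hub recovery study run on data *from this
generator*: multivariate normal, linear dependence structure, exact
marginal calibration. Real exhaustion data are non-normal (times and
lactate measures are right-skewed), contain measurement error with
non-Gaussian tails, and their dependence is not fully linear — so a passing
hub-recovery suite demonstrates that the pipeline correctly recovers
structure *of the kind it assumes*, not that nine-participant field data
identify hubs reliably. Problem sizes used by the suite, chosen to make
sampling error negligible relative to the tested tolerances: moment
calibration at 10⁴ participants, correlation fidelity at 2000, hub recovery
at 200 participants × 100 seeds, critical-power recovery at 1000 noisy
replicates, ANOVA type-I calibration at 10⁴ replicates, metric/oracle
equivalence on 200 random graphs of up to 8 nodes plus exhaustive
path-enumeration cross-checks on smaller ones.

## Known limitations

* No partial correlations or causal direction: links are marginal
  correlations, bidirectional by construction.
* No repeated-measures modelling across intensities.
* No weighted-geodesic betweenness (see above).
* Exact reproduction of any specific published network (its link counts and
  figures) is impossible without the underlying raw measurements and is not
  attempted; the pipeline reproduces the *procedure* and recovers planted
  structure.
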