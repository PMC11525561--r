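---
title: "From a conformational distance to predicted LCAT activation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a conformational distance to predicted LCAT activation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

Lecithin-cholesterol acyltransferase (LCAT) esterifies cholesterol on
lipoproteins; small-molecule positive allosteric modulators (PAMs) that bind
its membrane-binding domain (MBD) increase its activity. In molecular
dynamics simulations of PAM-bound LCAT, the separation between the
alpha-carbons of two MBD residues -- CYS50 and ASN65, on the bottom and top
loop of the domain -- tracks how strongly a bound compound activates the
enzyme: activators push ASN65 away from CYS50. `lcatpam` implements the
quantitative chain built on that observation:

1. summarize the CYS50-ASN65 distance over trajectories (with honest SEMs);
2. calibrate a linear model of in vitro activity (percent of the no-PAM
   control) against that distance, and predict activities of new compounds;
3. triage screening libraries before docking/MD (charge, mass window,
   docking-score cut-off);
4. process plate assays into Michaelis-Menten and EC50 parameters;
5. test treatment effects with ANOVA + Dunnett many-to-one comparisons.

A synthetic-data module generates every input with known ground truth, so
the whole chain is testable without any trajectory or plate downloads.

## Distance summarization

Distances are plain Euclidean CA-CA separations per frame (for single-atom
groups this equals the minimum group distance that MD tools report).
Coordinates are held in Angstrom (the PDB convention); distances are
reported in nm by default, with the unit tagged on every series and summary
so calibration can refuse mixed units.

Two summarization protocols are supported, matching the two ways replicate
structure arises in practice:

* **Block averaging** (`block_summary`): one long run is split into
  `n_blocks` contiguous blocks of equal frame count (default 10, the
  ten-blocks-of-a-1-microsecond-run protocol); the summary is the mean of
  block means with SEM = sd(block means)/sqrt(n). When blocks are longer
  than the correlation time, block means are nearly independent and the SEM
  is honest despite autocorrelation. Remainder frames on non-divisible
  splits go to the *last* block -- truncation was rejected because it would
  silently drop data.
* **Replicate means** (`replicate_summary`): each replicate run is windowed
  (default `"last_half"`, i.e. the last 100 ns of a 200 ns run) and averaged;
  mean and SEM are taken *across replicates*. SEM across replicates (rather
  than pooled over frames) is the reading consistent with
  "mean and SEM of five replicate simulations".

Windows are half-open `[t_start, t_end)` so "the last 100 ns of 200 ns" is
unambiguous; passing `t_end = "end"` extends the end by a relative epsilon
so the final frame is included. SEMs use the n-1 sample SD throughout.

## Activity calibration and prediction

`fit_calibration` is unweighted ordinary least squares of activity (percent
of control, 100 = no-PAM level) on the mean distance. The reference
analysis fits a plain slope through points that carry SEMs on both axes
without describing any weighting or errors-in-variables treatment, so
unweighted OLS is the minimal faithful choice; inverse-variance weighting
by the activity SEM is available behind `weighted = TRUE`. The model stores
slope, intercept, Pearson r, R^2, residual SE (n-2 dof) and the leverage
terms. `predict_activity` adds a t-based prediction interval
(`residual_se * sqrt(1 + 1/n + (x - xbar)^2/Sxx)`, n-2 dof): the source
analysis reports no intervals, but ranking candidates needs an uncertainty
contract. Calibration and prediction refuse to mix nm and Angstrom rather
than converting silently.

Calibration activities are taken as user-supplied percents of the no-PAM
control: the upstream normalization of the historical reference activities
is not restated anywhere recoverable, so the package does not guess it.
For the same reason the published calibration R^2 (0.81) is not a
reproducible target; the package's calibration checks are
parameter-recovery properties on synthetic data instead.

## Virtual-screen triage

`apply_filters` applies, in order: (1) remove compounds with any formal
charge at the prepared protonation state (the charge flag is consumed as a
precomputed boolean -- ionization-state assignment is out of scope); (2)
remove masses below 100 or above 600 g/mol, bounds *inclusive-pass*
(exactly 100 or 600 survives, since only "below"/"above" are removed); (3)
keep SP docking scores at or below -7.0 (more negative = better; -7.0
itself passes). A compound failing several criteria is labelled by the
first failed filter only; total rejections are order-independent. Survivors
holding an XP score are MD candidates; `shortlist_md_candidates` replaces
manual scaffold-diversity picking with a deterministic rule (best XP score,
at most one per diversity group, ties broken lexicographically) so screens
are reproducible. Masses can be computed from Hill formulas with a built-in
IUPAC atomic-weight table covering drug-like elements.

Note an asymmetry the package reports but does not resolve: the reference
activators' own SP scores span -5.2 to -7.2, so some of them would fail the
-7.0 cut-off applied to libraries.

## Plate kinetics

The assay arithmetic is `rate = (signal - background) / slope / time`: the
standard curve is fitted with an intercept but only its slope is used, so
background handling stays explicit rather than being absorbed into an
intercept. Negative net signals clip to rate 0 with a flag.

`fit_michaelis_menten` solves `v = Vmax*S/(Km+S)` by Levenberg-Marquardt
least squares (initialization Vmax0 = 1.2*max(v), Km0 = concentration
nearest half-max; relative tolerance 1e-12; max 500 iterations; SEs from
the Jacobian). Rates are normalized by their maximum before fitting and
Vmax rescaled afterwards, which conditions the problem and makes the fit
exactly equivariant under rescaling of the rate axis. On degenerate data
(e.g. a fully saturated, flat profile) where the Jacobian is singular, a
bounded direct SSE minimization takes over and Km is pinned at its
boundary, which raises a warning rather than an error. Km estimates at
<= 1e-6 or >= 100*max(S) are flagged as boundary artifacts.

Triplicates are fitted per replicate and parameters summarized as
mean +/- SEM (one curve per assay), matching the stated statistical
protocol; a pooled fit sits behind a flag. `catalytic_efficiency` computes
kcat = Vmax/[E] and kcat/Km; the enzyme molar concentration is a user
input (converting a mass concentration needs a molecular weight that is
not part of the data), and all percent-change outputs are defined to be
independent of it. `percent_change` rounds half-away-from-zero to the
nearest 10% by default -- the convention behind prose statements like a
Vmax rising from 6.76 to 15.70 micromolar/h being "+130%".

`fit_dose_response` is a four-parameter logistic on log10 concentration:
`resp = bottom + (top-bottom) / (1 + 10^((log10 EC50 - log10 C) * hill))`.
Zero-dose wells initialize the bottom but are excluded from the log-scale
regression. The bottom is free by default (whether the reference analysis
fixed it at 100% is unstated) with a `fix_bottom` option; when responses
are control-normalized, anchoring the bottom at 100 noticeably tightens
EC50 sampling spread at the five-dose design. A response whose dynamic
range is below `flat_tol` (default 5 percent points) is reported as
`no_effect` without attempting the degenerate fit -- the behaviour expected
of an inactive compound such as a negative control. EC50s outside the
tested range carry an extrapolation warning.

## Statistics

`anova_oneway` is the standard between/within decomposition.
`dunnett_test` computes per-comparison t statistics on the pooled
within-group mean square and adjusts two-sided p-values over the family
via the equicorrelated multivariate t distribution (correlation
lambda_i*lambda_j, lambda_i = sqrt(n_i/(n_i+n_c)); 0.5 for balanced
designs), evaluated by randomized quasi-Monte-Carlo integration under a
fixed internal seed so results are reproducible to ~5e-4. With one
treatment group the adjusted p is the exact pooled two-sample t p-value.
Adjusted p-values are clamped to never fall below the unadjusted t
p-value. Star labels use the strict printed thresholds (*p<0.05, **p<0.01,
***p<0.001; p = 0.05 exactly is ns). Pooled variance is assumed, as in
classical Dunnett; a >10-fold spread of group variances triggers a warning
(with n = 3 per group this ratio is noisy, so the warning is advisory).
`dunnett_by_stratum` runs the ANOVA+Dunnett pair independently at each
substrate concentration, the per-point testing protocol.

## Synthetic data: what it emulates, what it does not

`gen_trajectory` draws an exactly discretized Ornstein-Uhlenbeck process
-- the minimal stationary Gaussian model with tunable mean, SD and
correlation time -- and embeds it as two pseudo-residues (CYS 50, ASN 65)
on the x-axis of a multi-model PDB, so rigid-body invariance can be tested
by transforming frames. Defaults (mean 2.0 nm, SD 0.1 nm, correlation time
5 ns, 200 frames at 1 ns, 5 replicates) mimic the replicate production
protocol: 200 ns runs in five replicates. The 2.0 nm mean is a plausible
CA-CA separation chosen for the generator, *not* a published reference
value -- the source reports distances only graphically. `gen_mm_assay`
builds plates at the published control kinetics (Vmax 8.66 uM/h, Km 11.59
uM) and the seven-well concentration series (0, 6.4, 9.6, 14.4, 21.6,
32.5, 50.6 uM), with signal = background + slope*v*t plus Gaussian noise
and a noiseless standard-curve block. `gen_dose_response` uses the
five-dose design (0.001-10 uM); its default EC50 of 0.1 uM and top of 250%
match the measured potency scale of the activators. All generators draw
sub-seeds from one master integer seed, so outputs are byte-identical
under a repeated seed and generators can be re-seeded independently.

What the generators do **not** emulate: physically realistic protein
dynamics (no force field, no multivariate conformational coupling),
docking-pose geometry, fluorescence artifacts (inner-filter effects,
compound interference), or plate-position effects. Passing tests therefore
demonstrate that the *analysis chain* is correct and well-calibrated under
its stated statistical model -- not that the biological conclusions
transfer to any particular real dataset.

## Numerical choices and problem sizes

* OU discretization is exact (`d_{t+dt} = mu + (d_t-mu)e^{-dt/tau} +
  sd*sqrt(1-e^{-2dt/tau}) z`), not an Euler step, so stationarity holds at
  any dt.
* PDB coordinates are written at the format's 0.001 Angstrom precision;
  round-trip tests use that tolerance.
* The multivariate t integration uses 25k quasi-random evaluations
  (mvtnorm's default) under a fixed seed; the k=1 path is closed-form.
* Test and acceptance problem sizes were chosen to make statistical checks
  sharp but quick: 500 regressions for slope recovery, 2000 null
  simulations for the familywise error rate (6 treatments, n = 3 -- the
  study's design shape), 200 seeded datasets for kinetic parameter
  recovery, 100-frame brute-force distance checks.
* "10% response noise" in the EC50 recovery check is implemented as an SD
  of 10 percentage points on the percent-of-control scale, and that check
  anchors the 4PL bottom at the control level, because generated responses
  are control-normalized by construction.

## Known limitations

* The published absolute kinetic parameters and EC50s, the efficiency
  percentages, and the published calibration scatter cannot be reproduced
  from printed information alone (raw plates and per-replicate values are
  unpublished); the package covers them with parameter-recovery and
  closed-form properties on synthetic data instead, and with the printed
  Vmax percent-change arithmetic, which *is* exactly reproducible.
* Dunnett p-values match a reference implementation to ~5e-4, not to
  machine precision; SPSS's exact values are not a target.
* The trajectory reader handles multi-model PDB (plus delimited distance
  tables); native compressed MD formats (XTC/TPR) are out of contract.
* Charge flags are consumed, not computed: protonation-state assignment
  belongs to structure-preparation tools.
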