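---
title: "A lumped piecewise-linear stiffness model of epimuscular force transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped piecewise-linear stiffness model of epimuscular force transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimusc)
```

## The problem

Skeletal muscles are usually modelled as mechanically independent actuators
that deliver force only through their tendons. In reality a muscle belly is
embedded in a continuous connective-tissue network — intermuscular tissue at
the interface with neighbouring bellies, and the collagen-reinforced tracts
that carry nerves and blood vessels — and part of the force generated by the
fibres can leave the muscle through these *epimuscular* pathways. The
observable consequence is that the forces measured simultaneously at a
muscle's proximal and distal tendons need not be equal, and that the
difference depends on the position of the muscle *relative to its
neighbours*, even at constant muscle-tendon length.

`epimusc` implements a lumped-parameter model of this exchange for the rat
soleus (SO) and lateral gastrocnemius + plantaris (LG+PL) pair, a
preparation in which all three quantities of interest can be measured: SO
distal tendon force, LG+PL proximal tendon force and LG+PL distal tendon
force. Three pathways are modelled as elastic elements between the two
muscle actuators and their surroundings:

* **INT** — the intermuscular connective tissue at the SO/LG+PL belly
  interface (proximal and distal parts lumped into one element);
* **NV1** — the neurovascular tract running between the SO and LG bellies;
* **NV2** — the neurovascular tract from the popliteal fossa to the
  gastrocnemii, leading force outside the muscle pair.

## Model

Each muscle is a Hill-type actuator (contractile element with series and
parallel elastic tissue) whose proximal and distal tendons attach at two
nodes. With isometric contractions at fixed muscle-tendon length the lumped
muscle force \(F_{m} = F_{CE} + F_{PE}\) is constant across conditions and
the system reduces to a static force balance at the two LG+PL nodes:

\[
F^{prox}_{LGPL} - F_{NV2} - F_{m} = 0, \qquad
F^{dist}_{LGPL} - F_{m} + F_{INT} + F_{NV1} = 0 .
\]

`node_residuals()` evaluates exactly these two balances. Subtracting them
shows that the measured proximal-distal force difference
\(\Delta F_{LGPL} = F^{prox} - F^{dist}\) equals the summed pathway force
\(F_{INT} + F_{NV1} + F_{NV2}\): the tendon force discrepancy *is* the net
epimuscularly transmitted force.

Collagenous tissue recruits fibres of different initial orientation
progressively with extension, so each pathway's force-extension relation is
represented as piecewise linear in the relative position \(P_R\) between
the muscles: one signed stiffness value \(K_j\) (mN/mm) per 1-mm
displacement band \([0,1], [1,2], [2,3]\) mm, extended to negative
positions by odd symmetry \(F(-P) = -F(P)\). Two conventions are worth
making explicit because the calibration protocol does not determine them
uniquely:

* **Segments are anchored at the reference position** (0 mm, the 90°–90°
  knee-ankle configuration), not at the end of the travel. This is forced
  by the observation that \(\Delta F_{LGPL}\) passes through zero at the
  reference and reverses sign there, which an anchor at −3 mm would not
  reproduce.
* **Stiffness values are signed.** The NV2 transmission vector opposes
  INT/NV1 over most of the protocol, so the bundled estimates store NV2
  with a negative sign rather than tracking a separate direction flag.

Evaluation outside the calibrated ±3 mm span raises an error rather than
extrapolating: the piecewise-linear form has no empirical support there.

## Calibration: the three-condition estimator

The pathway forces cannot be separated in a single experiment, so the
calibration uses three conditions: *intact*, *post I* (intermuscular tissue
resected) and *post II* (additionally NV1 resected), each measured over the
full position protocol. Solving the node balances across conditions gives

\[
\hat F_{INT} = \Delta F^{intact} - c\,\Delta F^{postI} + (c-1)\,\Delta F^{postII},
\qquad
\hat F_{NV1} = \Delta F^{postI} - \Delta F^{postII},
\qquad
\hat F_{NV2} = \Delta F^{postII},
\]

implemented in `estimate_pathway_forces()`. The dimensionless parameter
\(c\) (default 0.9) is the ratio of NV1 length before vs after resection of
the myofascial linkages: cutting the intermuscular tissue lets the NV1
tract lengthen slightly, so its intact-state loading is a fraction \(c\) of
its post-I loading. Two consequences matter:

* the \(\hat K_{NV1}\) fitted from \(\hat F_{NV1}\) describes NV1 in its
  *post-resection* state — which is also the state the three-condition
  protocol can observe;
* \(\hat F_{INT}\) is affine in \(c\), so the sensitivity of the INT
  estimate to this (not directly measured) parameter has the closed form
  \(RMSE(c) = |c - c_{ref}|\cdot RMS(\hat F_{NV1})\), reported by
  `c_sensitivity()` as a percentage of the mean \(|\hat F_{INT}|\). The
  package's tests verify the numeric curve against this closed form at
  1e-9.

By default the three input series are re-referenced to their value at 0 mm
before the equations are applied, so all estimates are exactly zero at the
reference even on noisy data; `re_reference = FALSE` gives the raw
equations.

`fit_piecewise_stiffness()` converts the per-position force estimates into
segment stiffness, \(K_j = (\hat F(b_j) - \hat F(b_{j-1}))/(b_j -
b_{j-1})\), and with `symmetry = TRUE` (the default) averages each
positive-side slope with its mirrored negative-side slope. Group-level
values (`estimate_group_stiffness()`) are means of per-animal stiffness
fits, not slopes of mean curves; the alternative would weight animals by
their force range. The post-II condition is accepted as a *group-level*
series, because complete surgical isolation is typically feasible in very
few animals (and not at all once scar tissue makes the neurovascular tract
inseparable); the estimator simply reuses the pooled post-II series for
every animal of the group.

Estimation refuses passive-state forces by default. In the passive state
the LG+PL force difference is not balanced by the SO distal tendon force
(force escapes through the intact SO proximal tendon and other unmeasured
structures), so the model's central force-matching assumption fails;
`allow_passive = TRUE` overrides with a warning, for exploration only.

## Prediction and validation

The calibration repositions both LG+PL tendons together. To predict the
force difference when *only the proximal tendon* moves — the testing
protocol, and the situation closest to a knee-angle change in vivo — the
INT stiffness is scaled per segment by a factor \(r_j\) (the ratio of
myofascially transmitted force under proximal-only vs full loading,
`estimate_r()`), while NV1 and NV2 act with their calibrated stiffness:

\[
\Delta F^{mod}_{LGPL}(\Delta P^{prox}_R) = \Delta F^{mod}(P_{REF})
 + \sum_j \left( r_j \hat K_{INT,j} + \hat K_{NV1,j} + \hat K_{NV2,j} \right) w_j .
\]

The offset at the reference defaults to 0 (the calibration defines
\(\Delta F = 0\) there) and can be set to a measured reference value when
validating against experimental data. With all \(r_j = 1\) the prediction
reduces exactly to the calibration forward model — a consistency limit the
test suite checks at 1e-12.

Agreement between measured and predicted series is summarised by
`bland_altman()`: bias = mean(measured − predicted) and limits of agreement
bias ± 1.96·SD. The SD is the sample (n−1) standard deviation — standard
Bland-Altman practice. `percent_of_range()` provides the per-group
normalisation used to pool animals with different force ranges on one
agreement plot.

The bundled `r` values (0.07, 0.13, 0.21) were estimated in a
normal-connectivity subset with distal-only resection; applying them to the
enhanced-connectivity group assumes the proximal/full loading ratio is a
property of the loading geometry rather than of the tissue — a stated model
assumption, not a verified fact.

## The synthetic experiment generator

`synthetic_spec()` + `generate_calibration_dataset()` /
`generate_testing_dataset()` emulate the in situ protocol end to end so the
whole pipeline can be exercised without animal data. The defaults *are*
the protocol conditions: 7 positions from −3 to +3 mm in 1-mm steps;
tetanic plateaus of 11.5 N (LG+PL proximal) and 1.3 N (SO distal) at the
reference; a 500-ms tetanus at 1 kHz sampling, preceded by two twitches
1.5 and 1.0 s earlier (kept clear of the 50-ms passive extraction window by
construction); 7 animals per group; additive i.i.d. Gaussian noise of SD
0.05 N on each extracted force — the order of the reported between-animal
spread, since no within-measurement noise model is available. Passive
baselines (0.3 N LG+PL, 0.1 N SO) are position-independent: passive
mechanics are deliberately not modelled.

Three generator conventions deserve emphasis:

* **Condition composition.** The intact condition carries
  \(F_{INT} + c\,F_{NV1} + F_{NV2}\), post I carries \(F_{NV1} +
  F_{NV2}\), post II carries \(F_{NV2}\), where \(F_{NV1}\) is the
  post-I-state NV1 force (the state whose stiffness the estimator
  recovers). This makes the generator exactly consistent with the
  estimator: a noiseless round trip recovers every ground-truth stiffness
  to 1e-9 mN/mm. The intact net force difference therefore differs from
  the plain pathway sum by the small term \((1-c)F_{NV1}\) (about 1% at
  +3 mm for the normal group) — the same model error the three-condition
  estimator itself carries.
* **SO coupling.** The SO distal channel receives a fraction
  (`so_coupling`, default 0.35) of the force routed towards SO (INT and
  NV1; NV2 leads outside the pair). The fraction is less than 1 because
  part of the transmitted force leaves through the intact SO proximal
  tendon and other unmeasured structures — and because full routing would
  drive the SO distal force (≈1.3 N) negative under the enhanced-connectivity
  forces (≈2 N). Any positive coupling preserves the strong positive
  SO-vs-LG+PL regression that motivates the model.
* **Post-II sampling.** By default only the first animal per group
  receives the post-II condition (`n_postII = 1`), mirroring how rarely
  complete isolation succeeds; the estimator consumes post II as a pooled
  group series. `postII_source = "borrow_no"` lets the
  enhanced-connectivity pipeline reuse the normal group's post-II series,
  for the case where the neurovascular tract cannot be isolated at all.

What the generator does **not** emulate: physiological twitch/tetanus
kinetics (transients are schematic; only the extraction windows carry
information), passive nonlinearity, history effects, between-animal
variation in the true stiffness (all animals share the group ground truth;
only measurement noise varies), or local tissue deformation. Passing tests
therefore demonstrate correctness of the estimation machinery under the
model's own assumptions — not that the model captures every feature of
real tissue.

## Numerical choices and defaults

* Forces are in N, positions in mm, stiffness in mN/mm throughout (the
  reporting convention); the only conversion (×1/1000) happens inside the
  cumulative-force evaluation and is covered by exact round-trip tests.
* Equality tolerances in tests default to 1e-9 N (1e-12 where the check is
  purely algebraic).
* The position↔knee-angle map (`position_to_knee_angle()`) fixes only the
  anchor — 0 mm ↔ 90° — empirically; the default slope of 10 deg/mm places
  the calibrated span over a plausible 60–120° knee range and is
  configurable.
* Monte-Carlo checks in the test suite use 200 seeded replicates at the
  default study size (7 animals per group) for the unbiasedness check, and
  200 replicates of a 1-vs-4-animal contrast for the \(\sigma/\sqrt{n}\)
  dispersion check; both sizes keep the full suite under a minute while
  leaving the statistical assertions comfortably powered.
* `run_pipeline()` writes a provenance record (configuration, package
  version, seed) beside its outputs, and identical seeds give
  byte-identical result bundles.

## Worked example

```{r example}
no <- bundled_stiffness("NO")
ti <- bundled_stiffness("TI")
forward_delta_f(no, -3:3)

# noiseless synthetic calibration, full pipeline, exact recovery
spec <- synthetic_spec(noise_sd_N = 0, n_animals = 2)
tabs <- generate_calibration_dataset(spec, "TI")
fit <- estimate_group_stiffness(tabs)
segment_stiffness(fit$mean)

# proximal-only prediction and closure against synthetic testing data
pred <- predict_delta_f(ti, r = c(0.07, 0.13, 0.21), dp_mm = -3:3)
testing <- generate_testing_dataset(spec, "TI")
measured <- rowMeans(vapply(testing, delta_f_lgpl, numeric(7)))
bland_altman(measured, pred$delta_f_mod_N)
```

## Limitations

The model is quasi-static and describes the active state only; it has no
contractile dynamics, no force-length/velocity behaviour and no
sarcomere-level detail — these are assumed constant across conditions,
which holds for isometric contractions at fixed muscle-tendon length. The
piecewise-linear stiffness is a phenomenological summary of the calibrated
span, not a constitutive law; the `c` parameter is set, not inferred from
anatomy; and `r` transfers from normal to enhanced connectivity by
assumption. Predictions outside the calibrated displacement range, at
other activation levels, or for muscle groups with a different
connective-tissue architecture require recalibration.
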