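---
title: "Estimating ground reaction forces, centre of pressure and knee moments from gait kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ground reaction forces, centre of pressure and knee moments from gait kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitwrench)
```

## The problem

Knee joint loading — and in particular the distribution of tibiofemoral
contact force between the medial and lateral compartments — is a central
quantity in knee osteoarthritis research and rehabilitation. The standard
way to obtain it is a musculoskeletal simulation driven by laboratory
motion capture and force-plate recordings. Wearable inertial sensors can
replace the motion capture for kinematics, but they provide no ground
reaction forces and moments (GRFM) and no centre of pressure (COP), both
of which the simulation needs.

gaitwrench implements the estimation chain that fills this gap:

1. **GRFM from kinematics** with a probabilistic principal component
   analysis (PPCA) model trained on cycles where both kinematics and
   force-plate GRFM were measured;
2. **COP from the estimated GRFM** with the zero-moment-point (ZMP)
   equations, plus a degree-10 polynomial repair of the endpoint regions
   where the ZMP ratio degenerates;
3. **external knee moments** (flexion, adduction, rotation) by bottom-up
   link-segment inverse dynamics;
4. **agreement statistics** between two workflows: RMSE, R², mean
   absolute differences of the first peak, second peak and stance
   impulse, exact Wilcoxon signed-rank tests and Benjamini–Hochberg FDR
   control.

A full musculoskeletal contact simulation (muscle redundancy, ligaments,
cartilage contact) is outside this package's scope: the pipeline exports
its inputs in OpenSim ASCII formats for such tools, and offers only a
clearly labelled frontal-plane proxy for compartmental contact forces.

## Conventions

Right-handed lab frame with X anterior, Y vertical (up), Z to the
subject's right. Forces are stored in body-weight units (BW), moments in
Nm/kg, angles in radians, positions in metres; `g = 9.81` m/s². Every
waveform analysis uses the 101-point gait-cycle normalization (0, 1, …,
100 % between consecutive ipsilateral heel strikes), with the stance
fraction recorded alongside.

## The PPCA estimator

Each gait cycle is stacked into one feature vector `x`: the 101-point
joint-angle waveforms of both legs, the per-foot GRFM waveforms, and the
scalar stance fraction (the stance-timing feature that disambiguates
double support). The model is the isotropic latent linear Gaussian model

$$x = W z + \mu + \varepsilon,\qquad z \sim N(0, I_q),\quad
\varepsilon \sim N(0, \sigma^2 I),$$

fit in closed form by maximum likelihood: `mu` is the feature mean, the
sample covariance is eigendecomposed (through the `n × n` Gram matrix
when `n ≤ D`), `sigma2` is the mean of the discarded portion of the
nonzero spectrum, and `W = U_q (Λ_q − σ²I)^{1/2}`. We chose the
closed-form fit over EM because it is deterministic and needs no
convergence tuning; an EM iteration would converge to the same stationary
point.

Prediction is Gaussian conditioning of the GRFM block on the kinematic
block, computed in the q-dimensional latent space — with
`M = W_o' W_o + σ² I`, the conditional mean is
`μ_t + W_t M⁻¹ W_o'(x_o − μ_o)`, algebraically identical to the dense
`μ_t + C_to C_oo⁻¹ (x_o − μ_o)` but never forming a `D × D` matrix. The
conditional covariance diagonal, `σ²(1 + diag(W_t M⁻¹ W_t'))`, is
returned as a per-sample posterior standard deviation. Predicted forces
and moments are masked to the cycle's stance window.

Numerical choices: channels are standardized by their pooled training
standard deviation before stacking (so radian and BW channels are
commensurable; the scales travel with the model); `M` is solved through
an SVD pseudo-inverse so the noiseless `σ² → 0` limit stays well-defined;
the default `q` is the smallest component count reaching 95 % cumulative
explained variance, overridable everywhere.

Validation is leave-one-subject-out (LOSO) cross-validation — train on
all subjects but one, predict the held-out subject's GRFM from its
kinematics, score per cycle with RMSE and the coefficient of
determination about the reference mean, and report per-cycle means ± SD.
Leave-one-cycle-out (LOCO) is provided as the easier, in-subject
reference point; feature scales are recomputed inside every training
fold so nothing leaks from held-out data. R² is the coefficient of
determination (not squared Pearson), computed per cycle and averaged,
which is why aggregate SDs can be large even when the mean is near 1.

## The synthetic cohort

No public gait recordings ship with the package; instead
`generator_config()` / `generate_dataset()` produce a synthetic treadmill
cohort with the statistical structure the PPCA stage assumes, so every
downstream stage is testable end to end:

* **Cohort**: 18 subjects by default, mass 80.5 ± 15.3 kg, height
  1.65 ± 0.12 m, self-selected speed 0.75 ± 0.23 m/s (all truncated at
  ±3 SD), stance fraction 0.6, 100 Hz sampling — a typical slow,
  knee-osteoarthritis treadmill cohort.
* **Templates**: a shallow double-hump vertical GRF (humps near 25 % and
  75 % of stance), a braking/propulsion anterior-posterior S-curve scaled
  by walking speed, a small medio-lateral force directed toward the
  contralateral side, and Fourier/Gaussian joint-angle curves.
* **Shared low-rank variability**: five latent modes (SD
  `0.06·0.75^(k−1)` BW on the vertical force) perturb the kinematic and
  GRFM channels with the *same* per-cycle coefficients. This is the
  structural assumption that makes conditional prediction of GRFM from
  kinematics possible at all; the generator makes it explicit and
  controllable rather than incidental.
* **Subject offsets**: each subject draws random coefficients on 12 fixed
  smooth offset modes, applied consistently to kinematics and GRFM
  (total ≈ 0.035 BW on the vertical force, ≈ 0.03 rad on angles). With
  fewer training subjects than offset modes, part of a new subject's
  offset is outside the training span — this is what makes LOSO strictly
  harder than LOCO, mirroring the difficulty of generalizing to unseen
  patients.
* **Noise**: white measurement noise (0.02 BW on forces, 0.01 rad on
  angles), tapered to zero at stance edges so forces stay exactly zero in
  swing.
* **Exact bookkeeping**: every variability mode is projected to zero
  cycle-mean (by removing a multiple of the windowed template, which
  stays inside the mode span), and the cycle is rescaled by its realized
  mean, so the whole-cycle mean of the summed vertical GRF is exactly
  1 BW — as physics requires of steady gait — while noise-free data
  remain exactly low-rank.
* **Consistency**: ground reaction moments are built from the generated
  forces and a known heel-to-toe COP path, so the ZMP inversion is exact
  on this data; the COM acceleration channel equals
  `g·F_total + g⃗`, so the whole-body wrench check closes exactly.

Variability magnitudes are package choices made once (none are reported
by gait studies at this granularity); they produce LOSO errors of the
same order as published kinematics-to-GRFM estimators, but results on
synthetic data are properties of this regime, not reproductions of any
measured cohort. Real gait differs in ways the generator deliberately
omits: nonstationary stride timing, nonlinear kinematics–kinetics
coupling, soft-tissue artefact, sensor drift, and asymmetric pathology.
Passing tests therefore demonstrate correctness of the machinery and
consistency of the statistical assumptions, not clinical accuracy.

For the acceptance-scale study (10 subjects × 50 cycles, 5 latent modes,
0.02 BW noise) we fix `q = 25`: enough for the 5 latent + 12 offset + 1
speed-scaling directions with headroom, chosen a priori rather than by
per-fold selection so LOSO and LOCO are compared on the same footing.

## ZMP centre of pressure and the endpoint repair

About a ground-plane reference point, the COP of a wrench `(F, M)` is

$$x_{AP} = p_x + M_z / F_y,\qquad
z_{ML} = p_z - M_x / F_y .$$

(Worked sign example: `F = (0, 700, 0)` N, `M = (−35, 0, 70)` Nm about
the origin → COP `(0.10, 0.05)` m.) Near heel strike and toe off the
vertical force vanishes and the ratio blows up, so samples below a 20 N
threshold (the same force-plate convention used for event detection) are
flagged undefined, and the 0–15 % and 85–100 % stance regions are
replaced by a degree-10 polynomial per coordinate.

The polynomial is parameterised as the straight line through two anchor
points plus `u(1−u)` times a degree-8 Chebyshev expansion (Chebyshev for
conditioning, the `u(1−u)` factor so the anchors hold *exactly*), and
least-squares fitted to the trusted 15–85 % core. The heel-strike anchor
is the musculoskeletal model's calcaneus origin — at initial contact the
COP is under the heel. The toe-off anchor is the calcaneus origin
advanced by 0.8 × foot length (0.20 m default): the COP leaves the
ground under the forefoot, and anchoring the late-stance fit back at the
heel would drag it several centimetres posterior. Across the junctions
the fit is blended linearly into the raw values over 2 %-wide windows on
the fitted side, so the output is continuous and the 15–85 % core is
never modified. Fewer than 12 valid core samples make the fit
underdetermined and raise an error.

## Inverse dynamics

External knee moments come from a bottom-up Newton–Euler recursion over
the two distal segments only (foot, then shank): knee moments need
nothing above the knee, so thigh and pelvis dynamics are unnecessary.
Segment masses, COM locations and radii of gyration come from the
bundled Winter anthropometric table scaled by subject mass and height
(`scale_subject()`), the table-based stand-in for marker-based model
scaling. Segment linear accelerations and the shank's sagittal angular
acceleration are computed by 5-point central finite differences
(second-order one-sided at the ends); the foot is treated as flat on the
ground during stance. The resulting external moment — the moment of all
loads distal to the knee about the knee centre — is resolved in a shank
anatomical frame (long axis knee→ankle, medio-lateral axis orthogonalized
from lab Z) and normalized by body mass.

Sign conventions (the "external moment" convention of the knee-adduction
literature): flexion positive, adduction positive with side-aware
mirroring, internal rotation positive. A vertical force anterior to the
knee is therefore an external *extension* (negative flexion) moment, and
a vertical force medial to the knee is a positive adduction moment on
both sides.

The frontal-plane contact-force proxy (`proxy_kcf()`) solves the
two-contact-point static balance `medial − lateral = 2|KAM|/d`,
`medial + lateral = F_axial` with intercondylar distance
`d = 0.045` m by default (a common adult literature value). When one
compartment would go negative it is clamped to zero (condylar lift-off)
and flagged. This proxy ignores muscle forces, ligaments and cartilage
mechanics; it exists so the pipeline has an end-to-end compartmental
output without an external contact-model simulation, and every file
written from it is suffixed `_proxy`.

## Statistics

`wilcoxon_signed_rank()` drops zero differences, mid-ranks ties, and for
n ≤ 25 computes the exact two-sided p from the null distribution of W⁺
over all 2ⁿ sign assignments (evaluated by dynamic programming over
doubled rank sums — identical to full enumeration, verified against a
literal 2ⁿ oracle in the tests); larger samples use the normal
approximation with continuity and tie corrections. `bh_fdr()` wraps
`stats::p.adjust(method = "BH")` with rejection flags at q ≤ 0.05.
`extract_features()` splits stance at 50 % for the two peaks (preferring
interior local maxima, falling back to the window maximum with an audit
flag for monotone shapes) and integrates the stance impulse by the
trapezoidal rule — exact integration region for forces, a stated choice
for moments. Waveforms of any length are accepted; 101 points is the
convention, and denser grids converge to analytic integrals.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(n_subjects = 10, cycles_per_subject = 50, seed = 1)
nd <- normalize_dataset(generate_dataset(cfg))
loso <- loso_cv(nd, default_layout(), q = 25)
glance(loso)
autoplot(loso)

model <- train_ppca(build_features(nd$normalized, default_layout()), q = 25)
subj <- generate_subject(cfg, 3)
trial <- generate_cycle(subj, cfg, 999)
out <- run_pipeline(trial, model, subj, pipeline_config(proxy_kcf = TRUE))
out$report
autoplot(out$cycles$grfm[[1]])
autoplot(out$cycles$cop[[1]])
```

The problem sizes used by the test suite and the acceptance script (10
subjects × 50 cycles for cross-validation; single cycles elsewhere) are
the package's documented study conditions; the same code runs unchanged
on larger cohorts.

## Known limitations

* The PPCA model is linear-Gaussian; strongly nonlinear
  kinematics–kinetics relationships (e.g. stair negotiation) would need a
  richer conditional model.
* The ZMP repair assumes the COP progresses heel-to-toe under a single
  foot; atypical roll-over patterns violate the anchor placement.
* The inverse dynamics assumes a flat foot during stance and planar
  segment rotation for the angular terms.
* The compartmental contact-force proxy is a static frontal-plane
  balance, not a musculoskeletal contact simulation, and should never be
  reported as one.
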