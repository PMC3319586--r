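---
title: "Predicting postoperative fistula flow with a lumped-parameter pulse wave model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting postoperative fistula flow with a lumped-parameter pulse wave model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avfplan)
```

## The clinical question

Creating an arteriovenous fistula (AVF) short-circuits an arm artery into a
vein so that, weeks later, the matured vein can be needled for hemodialysis.
The surgical choice — radiocephalic at the wrist (RC), brachiocephalic (BC)
or brachiobasilic (BB) at the elbow — trades maturation failure from too
little flow against steal syndrome and cardiac overload from too much.
`avfplan` estimates the immediate postoperative brachial artery flow for
each candidate configuration from preoperative measurements, quantifies the
uncertainty of that estimate, and applies a transparent decision rule: a
configuration is an option when its predicted flow lies in 400–1500 ml/min,
and the most distal option wins (RC > BC > BB).

## Model structure

The computational domain covers 20 named vessels: the ascending aorta, the
aortic arch with its primary branches (innominate, both carotids, both
subclavians, vertebral, thoracic aorta), the arm arteries on the surgical
side (axillary/brachial, radial, proximal and distal ulnar, interosseus)
and, postoperatively, the venous outflow trajectory of the chosen
configuration (distal/proximal cephalic, median cubital, basilic,
axillary/subclavian vein).

Each vessel is divided into equal-length lumped segments no longer than
5 cm. A segment is the electrical analog of a short transmission line:

* viscous resistance $R = 8\mu\ell/(\pi r^4)$,
* blood inertance $L = \rho\ell/(\pi r^2)$,
* wall compliance $C = 3\pi r^3 \ell/(2 E h)$ (thin-walled, incompressible),

with $\mu = 3\times10^{-3}$ Pa·s, $\rho = 10^3$ kg/m³, and half of each
segment's compliance lumped to each end node. Venous segments additionally
carry a leakage resistance $R_L$ to the venous reference, representing the
small side branches that are not modelled in detail; $R_L$ is
parameterized as a multiple (default 100×) of the segment's own $R$ and the
multiplier is exposed to the uncertainty layer. Internally the element
formulas are evaluated in SI units and converted once; the solver and all
reports use clinical units (mmHg, ml/s or ml/min, s).

Peripheral beds and arteries outside the domain terminate in three-element
windkessels ($Z_{wk}$, $R_{wk}$, $C_{wk}$). The anastomosis joins the host
artery to the vein through two nonlinear resistors — venous limb and distal
arterial limb — each producing a Borda–Carnot-type junction loss
$\Delta p = K(\theta)\,\rho\,q|q|/(2A^2)$. The loss coefficient
interpolates linearly between $K(30^\circ) = 0.6$ and $K(60^\circ) = 1.2$;
these endpoints are configurable, since published junction-loss data vary
with geometry. A short (1 cm) Poiseuille tube of the limb's area is placed
in series so the junction keeps a finite conductance at zero flow.

Boundary conditions: the measured aortic flow waveform is prescribed at the
aortic root, and a central venous pressure of 10 mmHg at the subclavian
vein outflow and behind every windkessel.

## Personalization

* **Diameters.** Duplex-ultrasound stations per vessel (veins measured with
  a tourniquet) become piecewise-linear diameter profiles; missing
  positions are linearly inter-/extrapolated, a single station extends as a
  constant, and extrapolated diameters are floored at 0.5 mm to prevent
  nonphysical tapers. Vessels and veins above 2 mm minimum calibre (strict)
  pass the suitability screen.
* **Central geometry.** Aortic-branch diameters are literature values
  scaled by the measured-to-literature subclavian ratio; lengths come from
  a generic adult geometry; venous lengths equal the arterial lengths at
  the same anatomical level.
* **Wall thickness.** Fixed thickness-to-radius ratios: 15% for
  subclavian/axillary/brachial, 20% for radial/ulnar/interosseus, 10% for
  veins, literature ratios elsewhere.
* **Stiffness.** Brachial distensibility
  $D = \Delta A/(A\,\Delta p)$ from the wall-tracking and finger-pressure
  waveforms gives the arm arterial Young's modulus through the thin-wall
  relation $E = 3/(2 D (h/r))$, applied to every arterial arm segment;
  aorta and veins use literature moduli.
* **Windkessels.** Terminal mean-flow targets are the measured radial and
  ulnar flows (rescaled to sum exactly to the measured brachial flow), a
  20% literature share of the ulnar trunk for the interosseus artery, and a
  literature-weighted split of the remaining cardiac output over the
  central terminals. Branch flows then follow from conservation on the
  preoperative tree, node pressures from the serial viscous drops below the
  measured mean arterial pressure, and each terminal resistance from Ohm's
  law over its remaining pressure head. The total splits as
  $Z_{wk} = 0.1\,R_{tot}$, $R_{wk} = 0.9\,R_{tot}$, with
  $C_{wk} = 1.5\,\mathrm{s}/R_{wk}$ — conventional windkessel settings,
  both exposed to the uncertainty layer. Because the network is linear
  preoperatively, its cycle-averaged behaviour equals its DC behaviour, so
  this construction reproduces the measured mean flows almost exactly (the
  test suite requires 5%; the observed error is below 0.2%).
* **Anastomosis.** 5 cm proximal to the wrist on the radial artery (RC) or
  5 cm proximal to the elbow bifurcation on the brachial artery (BC/BB);
  45° angle by default, with 30–60° as the plausible range.

## Numerical scheme

States are the node pressures, the segment flows (on inertances) and the
windkessel pressures; the system is $M\dot x = Ax + b(t)$ with diagonal
$M$. Integration uses backward Euler with a fixed step of one thousandth of
the cardiac period. The implicit operator is factored once per simulation,
so each step is a single matrix–vector product; the two anastomosis
conductances, which depend on their own flows, enter through a rank-2
Sherman–Morrison–Woodbury correction that is Picard-refreshed within each
step to a relative tolerance of $10^{-6}$. This choice has three useful
consequences: the discrete per-node mass balance is satisfied to solver
precision at every step; purely resistive networks are solved exactly in
one step (giving a sharp cross-check against an independent direct linear
solve, observed agreement $\sim 10^{-13}$); and results are bit-for-bit
deterministic.

Each run starts from the network's DC solution at the mean inflow and
integrates whole cycles until the relative cycle-to-cycle change of mean
aortic pressure and mean brachial flow falls below $10^{-3}$ (at most 50
cycles; non-convergence is flagged, never silently accepted). The
**baroreflex** finds the inflow scale $s \ge 1$ restoring the preoperative
mean aortic pressure to $10^{-3}$ relative, by a bracketed secant iteration
on $[1, 5]$ warm-started between evaluations; mean pressure is monotone in
$s$, and 3–6 evaluations typically suffice. If even $s = 5$ cannot restore
the pressure the run is flagged as a baroreflex failure. Veins are kept
linear (no collapse law), and vessel curvature, kinking and stenoses are
not represented.

## Uncertainty propagation

Every uncertain input is uniform on nominal ± half-width: ±10% arterial and
±20% venous diameters, ±10% lengths, ±20% Young's moduli, ±20% windkessel
resistances, anastomosis angle 45° ± 15°, venous pressure ± 5 mmHg, leakage
multiplier ±50%. These are measurement-precision-scale defaults, editable
per record via `uncertainty_spec()`. The joint space is sampled by Latin
Hypercube sampling — every parameter occupies each of the $n$
equal-probability strata exactly once — and one full prediction runs per
sample. Non-converged runs are counted and excluded; the distribution is
summarized as the median and 25th–75th percentile interval, with
percentiles interpolated linearly between order statistics (R's default
type-7 convention, used everywhere). A perturbed vessel length stretches
its measurement stations proportionally, keeping them at fixed anatomic
fractions. The production default is 256 runs; the shipped tests and the
acceptance script use 8–16 runs, which stabilizes the quartiles of these
tight unimodal distributions well enough for their checks while keeping a
full cohort run on a laptop in minutes.

## Decision rule

The decision statistic is the Monte-Carlo **median** — the central value
plotted in clinical flow-prediction studies. Eligibility is the inclusive
window 400–1500 ml/min; below it a low-flow (non-maturation) flag is
raised, above it a high-flow flag, and flows exceeding 30% of cardiac
output (strict) raise a steal/cardiac flag. Among eligible configurations
the most distal wins. The maturation projection (immediate flow is ~60–70%
of matured flow in the forearm, ~90–100% at the elbow) is reported as
context only and never enters eligibility. Predicted-versus-measured
comparisons intersect the closed 25th–75th interval with the
profile-corrected Doppler interval (0.5–1.0 × velocity × area).

## The synthetic cohort

The generator emulates the statistical structure of a pre-dialysis
population: brachial arteries 3.5–6 mm and forearm arteries 1.5–3.4 mm with
distal taper, veins 1.5–4.5 mm (so a 25-patient cohort spans both adequate
and inadequate cephalic calibres), MAP 70–120 mmHg, cardiac period
0.7–1.2 s, cardiac output 3.5–7 l/min with 4–9% to the arm. The aortic
waveform is a systolic half-sine with zero diastolic flow whose mean equals
the cardiac output exactly; distension and pressure waveforms are built
from a prescribed distensibility so the stiffness inversion is exact by
construction. Because a real patient's measured flows are produced by their
anatomy, the generator enforces the same consistency: the radial/ulnar
split follows Poiseuille calibre weights, and the arm flow is capped so the
serial viscous drop along each path stays below 60% of the perfusion
pressure — leaving room for the peripheral beds and for the uncertainty
layer's diameter perturbations. Degraded records
(`degrade_patient()`) reproduce the documented clinical failure modes:
thrombosed cephalic veins make cephalic configurations unsimulable, small
radial arteries fail the calibre screen, and missing stations exercise the
interpolation fallback.

What passing tests on this cohort do **not** show: fidelity to any real
patient's waveform shapes, venous collapse behaviour, vessel wall
adaptation and flow-mediated dilatation during maturation, or the
accuracy of the literature geometry for a given individual. The synthetic
cohort validates the machinery — conservation, personalization
consistency, baroreflex behaviour, sampling properties, rule logic — not
clinical accuracy, which requires measured cohorts.

## Problem sizes and runtime

A personalized network has roughly 60 segments and 130–150 states; one
periodic simulation takes a fraction of a second, a full three-configuration
plan with 16 Monte-Carlo runs per configuration about two minutes. The test
suite runs the 25-patient default cohort through the preoperative
round-trip and the radiocephalic baroreflex; the acceptance script uses
5 patients for the oracle checks and 16 Monte-Carlo runs per configuration
on one patient. These sizes were chosen to keep a complete desk run in
minutes; all of them scale up by changing a single argument.

## Known limitations

* Immediate postoperative flow only: no maturation, remodelling or
  autoregulation, so late outcomes are out of scope by design.
* The anastomosis loss coefficients stand in for geometry-resolved junction
  data; their angle dependence is linear between documented endpoints.
* Whole missing arm arteries are an error (only veins may be absent, which
  disables the configurations needing them); missing stations within a
  measured vessel are interpolated.
* Prosthetic grafts are not modelled.
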