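# avfplan

Patient-specific planning of arteriovenous fistula (AVF) surgery by
lumped-parameter (0D) pulse wave simulation.

Hemodialysis patients need a vascular access, preferably a native AVF in the
arm. Too little flow after surgery leads to non-maturation and early
thrombosis; too much flow risks hand ischemia ("steal") and cardiac failure.
`avfplan` predicts the **immediate postoperative brachial artery flow** for
the three common configurations — radiocephalic (RC, wrist), brachiocephalic
(BC, elbow) and brachiobasilic (BB, elbow) — from routine preoperative
measurements, and turns the predictions into a surgical recommendation. It
is aimed at researchers in cardiovascular biomechanics and at vascular
access study groups.

## The model

The upper-extremity circulation (aorta and primary branches, arm arteries,
cephalic/basilic venous outflow) is a transmission-line network. Every
vessel is split into lumped segments of at most 5 cm; each segment relates
local pressure *p* and flow *q* through

- viscous (Poiseuille) resistance **R = 8μℓ/(πr⁴)**,
- blood inertance **L = ρℓ/(πr²)**,
- thin-wall vessel compliance **C = 3πr³ℓ/(2Eh)**,

with optional side-branch leakage resistance R_L on venous segments. Distal
vascular beds are three-element windkessels (Z_wk, R_wk, C_wk). The
anastomosis is a pair of flow- and angle-dependent nonlinear resistors with
quadratic junction loss Δp = K(θ)·ρ·q|q|/(2A²). Boundary conditions are the
measured aortic inflow waveform and a prescribed central venous pressure
(10 mmHg).

Per patient, the model is personalized from duplex-ultrasound diameters
(linear inter-/extrapolation between stations), brachial distensibility
(Young's modulus via E = 3/(2·D·(h/r))), mean arterial pressure and
MR mean flows (windkessel resistances via serial-drop-corrected Ohm's law).
After virtual surgery, a **baroreflex** iteration rescales the aortic inflow
until the preoperative mean aortic pressure is restored. Input uncertainty
(diameters, lengths, stiffness, windkessels, angle, venous pressure) is
propagated by **Latin-Hypercube Monte-Carlo** and reported as the median
with the 25th–75th percentile interval. A configuration is an option when
its median flow lies in **400–1500 ml/min**; among options the preference is
**RC > BC > BB** (most distal first), with flags for low flow, high flow and
flow above 30% of cardiac output.

No measured patient data ship with the package: a synthetic-patient
generator (`generate_patient()`, `generate_cohort()`) emulates the full
measurement record so the pipeline runs end to end.

## Worked example

```r
library(avfplan)

rec <- generate_patient(default_cohort_spec(seed = 42), 1)
print(rec)
#> <patient_record> synthetic-1 (left arm): MAP 102 mmHg, CO 3836 ml/min, T 0.99 s
#>   DUS stations: 19 on 10 vessels

assessments <- list()
for (cfg in c("RC-AVF", "BC-AVF", "BB-AVF")) {
  fd <- run_monte_carlo(rec, cfg, n_runs = 16, seed = 1)
  assessments[[cfg]] <- assess_configuration(fd,
    cardiac_output = rec$mean_flows[["aorta"]])
}
recommend_configuration(assessments, surgeon_choice = "BC-AVF")
#> <recommendation>
#>  configuration   median      p25      p75 eligible
#>         RC-AVF 329.4334 285.1404  359.883    FALSE
#>         BC-AVF 838.8141 769.1697 1011.498     TRUE
#>         BB-AVF 910.8018 820.3584 1039.869     TRUE
#> selected: BC-AVF
```

This patient's forearm vessels are small (the calibre screen marks the
radial artery and distal cephalic vein inadequate, ≤ 2 mm), so the predicted
radiocephalic flow, median 329 ml/min, falls below the 400 ml/min floor —
a non-maturation risk. Both elbow configurations land inside the window and
the most distal of them, the brachiocephalic fistula, is selected, in
agreement with the hypothetical surgeon's choice. A single nominal
prediction is available as
`predict_postop_flow(rec, "RC-AVF")` (here: 329 ml/min with baroreflex
inflow scale s = 1.025), and `maturation_projection(329, "RC-AVF")` puts the
projected matured flow at 471–549 ml/min.

A command-line front end with `synth`, `simulate`, `mc`, `plan` and
`report` subcommands is installed at
`system.file("cli", "avfplan.R", package = "avfplan")`.

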