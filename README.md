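# fieldQSAR

3D-QSAR for congeneric small-molecule series: CoMFA / CoMSIA molecular
interaction fields, column-filtered NIPALS partial least squares with
leave-one-out cross-validation, and Golbraikh–Tropsha external validation —
implemented as a tested, reusable R pipeline.

The package ships a complete worked dataset: 26 tricyclic agonists of the
human TRPA1 cation channel (11H-dibenz[b,e]azepines, with
dibenz[b,f][1,4]oxazepine and thiazepine bridge variants), a series in which
a single substituent position and the bridge atom at ring position 11 tune
potency over four orders of magnitude (pEC50 6.030–10.301). 21 compounds
train the models and 5 are held out for external validation.

## The method

Every compound is built from its scaffold/substituent descriptor, embedded
in 3D, MMFF94-minimized and Gasteiger-charged (via Open Babel), then rigidly
superimposed onto the most active analogue (compound **10**) by
least-squares fitting of the shared (Z)-N-benzylidenebenzenamine fragment
(two phenyl rings joined by CH=N, 14 heavy atoms). On a regular lattice
(1 Å spacing, 4 Å margin) an sp³ carbon probe with charge +1e samples:

* **CoMFA steric**: Lennard-Jones 6–12 energy
  `E(q) = Σᵢ εᵢ[(R*ᵢ/rᵢ)¹² − 2(R*ᵢ/rᵢ)⁶]`, truncated at +30 kcal/mol;
* **CoMFA electrostatic**: Coulomb energy
  `E(q) = Σᵢ 332.0636 qᵢ q_probe / (D(rᵢ) rᵢ)` with distance-dependent
  dielectric `D(r) = r`, clamped to ±30 kcal/mol, column-mean–substituted at
  sterically truncated points;
* **CoMSIA** similarity indices
  `A(q) = −Σᵢ w_probe wᵢ exp(−α rᵢ²)`, α = 0.3 Å⁻², for five properties
  (steric wᵢ = r³_vdw, electrostatic wᵢ = qᵢ, hydrophobic log P increments,
  H-bond donor/acceptor flags).

The fields are column-filtered (minimum sigma 2.0, applied after block
scaling), regressed on pEC50 by NIPALS PLS, and the component count is set
by leave-one-out cross-validation (`q² = 1 − PRESS/SStot`, ONC = argmax q²).
Internal diagnostics (r², SEE, F, per-field contributions), external
validation (`r²pred = (SD − PRESS)/SD` about the training mean, slopes k/k′
of the regressions through the origin, r0², Roy's
`rm² = r²(1 − √|r² − r0²|)`, and the acceptability battery
q² > 0.5, r² > 0.6, (r² − r0²)/r² < 0.1, 0.85 ≤ k ≤ 1.15, rm² > 0.5)
and STDEV*COEFF contour fields (80 % / 20 % contribution levels, OpenDX
export) complete the pipeline.

## Worked example

Statistics layer on the packaged activity/prediction table (no structure
computation):

```r
library(fieldQSAR)
rep <- statsOnlyReport()
with(rep$comfa$internal,
  cat(sprintf("CoMFA  : r2 = %.3f  SEE = %.3f  F = %.1f (6 components)\n",
              r2, see, f)))
with(rep$comfa$external,
  cat(sprintf("CoMFA  test set: r2pred = %.3f  k = %.3f  rm2 = %.3f\n",
              r2pred, k, rm2)))
cat(sprintf("rm2 from the published constants: CoMFA %.3f, CoMSIA %.3f\n",
            rep$comfa$reference$rm2, rep$comsia$reference$rm2))
```

prints (CoMSIA lines analogous):

```
CoMFA  : r2 = 0.986  SEE = 0.154  F = 160.6 (6 components)
CoMSIA : r2 = 0.981  SEE = 0.180  F = 117.6 (6 components)
CoMFA  test set: r2pred = 0.972  k = 0.985  rm2 = 0.746
CoMSIA test set: r2pred = 0.983  k = 0.992  rm2 = 0.883
rm2 from the published constants: CoMFA 0.942, CoMSIA 0.899
overall acceptability: TRUE TRUE
```

r² is the training determination coefficient, SEE its standard error at 6
latent components, r²pred the external predictive r² over the five held-out
compounds about the training mean, and k the slope of the regression of
actual on predicted through the origin; both models pass every
acceptability criterion.

The full structure-to-contours pipeline (≈10 s on one CPU):

```r
run <- runPipeline(defaultConfig(outputDir = "artifacts"))
run$tables$table3   # r2cv, ONC, r2, SEE, F, field contributions
run$tables$table4   # r2pred, k, r0^2, rm^2, gap ratio
```

`artifacts/` then holds the per-compound prediction table, both statistics
tables as JSON, per-channel STDEV*COEFF contour grids (`.dx`), the
alignment sidecar and a run log. Because the open force-field/charge stack
differs from the proprietary one used for the reference numbers, the
field-derived statistics are close to, but not identical with, the
reference analysis; the statistics layer above reproduces it exactly.

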