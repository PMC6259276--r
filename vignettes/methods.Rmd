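---
title: "Molecular-field QSAR with fieldQSAR: models, choices, limitations"
author: "fieldQSAR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular-field QSAR with fieldQSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fieldQSAR implements a classical 3D-QSAR workflow — comparative molecular
field analysis (CoMFA) and comparative molecular similarity indices analysis
(CoMSIA) with partial least squares — around a packaged series of 26
tricyclic TRPA1 agonists. This vignette is the package's account of the
science: the models and their assumptions, the parameters that matter and
why their defaults are what they are, the numerical choices, and what the
tests do and do not demonstrate.

## The dataset and its encoding

The series shares a dibenz-fused seven-membered ring closed by an azomethine
(CH=N); the bridge position 11 ("A") carries O, CH2 or S, and a single
substituent occupies one numbered benzo position (1–4 on the N-side ring,
7–10 on the azomethine-side ring). Activities are pEC50 = log10(1/EC50)
values spanning 6.030–10.301; 21 compounds train the models and compounds
7, 13, 15, 16 and 25 form the external test set. Because the original assay
concentrations are not recoverable, the pipeline starts from pEC50.

Structures are *constructed*, not looked up: a scaffold SMILES template with
a fixed position-label-to-atom map plus a token-to-fragment dictionary
(COOMe = methyl ester, CONEt2 = diethylamide, ...) yields each compound's
SMILES. The source structure table contains two internal inconsistencies
between its table and its running text (compound 13 listed as 8-CN vs 10-Br,
compound 24 as 9-OMe vs 8-COOMe, and a stray "COOMe2" for compound 8); the
packaged CSV follows the structure table and documents this in its header
comments.

## Structure preparation

Single conformers are generated per compound (the reference workflow used
one sketched, minimized pose): rule-based 3D generation, MMFF94 minimization
(energy tolerance 1e-6 kcal/mol or 2000 iterations) and Gasteiger partial
charges, all through Open Babel. The proprietary Tripos force field and
Gasteiger–Hückel charges used in the reference analysis are not available;
MMFF94 + Gasteiger is the standard open substitute, and the consequence —
field matrices and model statistics close to, but not identical with, the
reference — is flagged wherever numbers are compared. One empirical note:
under Gasteiger charges (both the Open Babel and RDKit implementations) the
sp3 ester oxygens of the template are *more* negative than the carbonyl
oxygen; intuition borrowed from lone-pair chemistry or other charge schemes
can point the other way.

Alignment fits the 14 heavy atoms of the common
(Z)-N-benzylidenebenzenamine fragment onto the template (compound 10, the
most active analogue) by Kabsch least squares. Hydrogens are excluded from
the fit (the reference text does not state its convention; heavy-atom
fitting is the common default). The fragment is topologically symmetric
across each phenyl ring, so several substructure matches exist; the match
with the lowest post-superposition RMSD wins, ties resolved to the lowest
atom-index order, which makes alignment deterministic and idempotent
(re-aligning changes coordinates by < 1e-6 Å).

## Fields

All fields are evaluated on one world-axis-aligned lattice: the union
bounding box of the aligned set extended by a 4 Å margin at 1 Å spacing,
points enumerated x-fastest. The probe is an sp³ carbon with +1e charge
(CoMSIA radius 1 Å, unit property weights).

* CoMFA steric: Lennard-Jones 6–12 with Tripos 5.2 element parameters
  (shipped as `vdw_params.csv`, radii combined additively, well depths
  geometrically), truncated at +30 kcal/mol.
* CoMFA electrostatic: Coulomb with the classic distance-dependent
  dielectric D(r) = r (a constant dielectric is switchable), clamped to
  ±30 kcal/mol. At points where the steric field is truncated the
  electrostatic value is physically meaningless (inside atoms), so it is
  replaced by the column mean over the remaining compounds — the classic
  CoMFA convention, switchable off.
* CoMSIA: Gaussian similarity indices with attenuation factor 0.3 Å⁻²; no
  truncation is needed (the kernel is bounded). Property weights: steric
  r³_vdw, electrostatic partial charge, hydrophobic coarse Crippen-type
  atomic log P increments (element/aromaticity/context typed), donor and
  acceptor 0/1 flags from simple typing rules (N–H and O–H donate through
  their heavy atom; N and O accept). These weights are deliberately simple;
  they reproduce the *structure* of CoMSIA, not any particular
  implementation's absolute values.

## PLS, column filtering, cross-validation

The descriptor block is column-filtered by the "minimum sigma" rule: drop
columns whose standard deviation across training compounds falls below the
threshold (default 2.0). Where the sd is measured needed a decision: applied
to raw values, the 2.0 threshold eliminates *every* column of four of the
five CoMSIA channels, because similarity indices are dimensionless and small
(max column sd 0.12–0.59 versus 6.5 for steric), which would contradict the
reference analysis in which all five channels contribute. fieldQSAR
therefore applies the filter after block scaling by default
(`filterOn = "scaled"`; `"raw"` is available). Block scaling ("comfa_std")
weights every channel block to the mean block variance — blocks contribute
equally, the data keep their energy-like magnitude, and since a uniform
rescaling leaves PLS predictions unchanged, the choice only matters to the
filter. Post-scaling, the default threshold retains columns in every
channel of both models.

The regression engine is NIPALS PLS1. Coefficients are mapped back to
original column units, so prediction is a plain inner product; at full rank
PLS reproduces ordinary least squares (tested to 1e-8). Leave-one-out
cross-validation refits centring and scaling inside every fold (the column
mask stays fixed, as in the reference workflow where filtering is set
before the CV), computes PRESS per component count, and selects the optimal
number of components (ONC) as the smallest count maximizing
q² = 1 − PRESS/SStot. SStot uses the full-training mean in both the q² and
r² denominators — whether the reference used the fold mean is not stated;
the full mean is the common convention and is logged here as the choice.
LOO equals brute-force refitting exactly (tested to 1e-10).

Internal statistics follow the standard definitions: r² = 1 − SSres/SStot,
SEE = sqrt(SSres/(n − c − 1)), F = (r²/c)/((1 − r²)/(n − c − 1)), and field
contributions Σ|coefⱼ|·σⱼ per channel, normalized — the conventional
definition; it is invariant to the internal scaling, since coefficients and
column sds transform inversely.

## External validation

r²pred = (SD − PRESS)/SD with SD taken about the *training* mean; slopes of
the regressions through the origin k = Σyŷ/Σŷ² (headline, matching the
reference table) and k′ = Σyŷ/Σy²; r0² and its primed variant; Roy's
rm² = r²(1 − √|r² − r0²|), with the absolute value because the reference
CoMSIA gap is negative; and the acceptability battery (q² > 0.5, r² > 0.6,
(r² − r0²)/r² < 0.1, 0.85 ≤ k ≤ 1.15, rm² > 0.5).

Two conventions deserve a note. First, rm² combines the *training* r² with
the *test-set* r0², which reproduces the reference arithmetic exactly
(0.986/0.984 → 0.942; 0.981/0.988 → 0.899); the test-set Pearson r² does
not. Second, the reference r0² values coincide numerically with k for both
models and do not match the Golbraikh–Tropsha r0² recomputed from the
printed per-compound predictions (0.927/0.971); whether that is coincidence
or a transcription artifact cannot be resolved from the text, so the
package computes the standard definition and, where reference-exact
reproduction is wanted (the `reference` block of `statsOnlyReport()`, the
acceptance script), derives rm² from the published constants themselves.
The reconstructed r²pred for CoMFA is 0.972 versus the published 0.967 — a
~0.005 gap attributable to three-decimal table rounding and the unstated
mean convention; CoMSIA reconstructs to 0.983 versus 0.981.

## Contour maps

STDEV*COEFF fields (column sd × coefficient, zero at filtered columns) are
contoured by the cumulative-contribution convention: the "80 % contribution"
favored level is the value above which the top 20 % of the positive mass
lies, and symmetrically for the disfavored side — the reference figures
never define the convention, so the standard one is implemented, with
absolute levels available through `contourLevels` directly. Fields export
as OpenDX text grids (z-fastest on disk, round-tripping to 1e-6).

## The synthetic-data generator

`genLinearDataset` emulates what the analysis assumes the fields to be:
locally correlated columns (moving average of window 5 over independent
normals — the smoothness that makes column filtering and PLS nontrivial),
a sparse true coefficient vector, and Gaussian activity noise. Defaults
(21 samples, 500 columns, 10 active, noise sd 0.3 log units) mirror a small
congeneric training set. It does not emulate truncation plateaus, block
structure across channels, or non-Gaussian activity error, so passing tests
show the *engine* is correct, not that real fields satisfy the model.
`genPerturbedSeries` produces rigid-motion-plus-jitter copies of a
conformer for exercising alignment; at larger jitter the copies are not
chemically plausible, which is intentional (the bonded-distance sanity
window is enforced after minimization, not on synthetic objects).

Coefficient recovery is assessed in the identifiable regime (40 samples,
30 columns, noise 0.1, 50 seeds; median cosine ≈ 0.90): when columns far
outnumber samples, the coefficient vector of *any* linear fit is confined
to the row space of X, capping the attainable cosine near sqrt(n/p)
(≈ 0.28 at 40×500) regardless of method — in that regime what survives is
predictive performance, which the q² tests cover.

## Problem sizes and determinism

The packaged analysis is small by design: 26 compounds, a ~26×24×16 grid
(≈10 000 points, 7 channels), 21-sample LOO over ≤ 10 components — the
full pipeline runs in about ten seconds on one CPU, and the test suite in
well under a minute. Every stochastic step (synthetic data, perturbation
series) flows from an explicit integer seed; the chemistry stack is
deterministic, so pipeline reruns are byte-identical.

## Known limitations

* Absolute field values, q²/r² of the field models, and contour shapes
  depend on the open force-field/charge substitutes and will not equal
  numbers produced with the proprietary stack; only the statistics layer is
  expected to agree at table precision.
* Single-conformer, single-template alignment: no conformational search,
  docking, tautomers or stereochemistry beyond the fixed (Z) azomethine.
* The hydrophobic/donor/acceptor typing is coarse; it orders chemistry
  sensibly but is not a calibrated log P model.
* No y-scrambling or applicability-domain analysis is included.
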