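---
title: "Quantitative characterization of cone CNG channels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative characterization of cone CNG channels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cngchan)
```

## Scope

Cone photoreceptor cyclic nucleotide-gated (CNG) channels are ligand-gated,
essentially voltage-independent cation channels assembled from A3 subunits
alone (homomeric) or together with B3 subunits (heteromeric). `cngchan`
implements the quantitative analyses used to characterize such channels from
inside-out patch recordings and from structural model ensembles:

1. **Dose–response analysis** — baseline subtraction, steady-state current
   extraction, Hill fits, cAMP efficacy and L-*cis*-diltiazem block, and a
   homomeric/heteromeric patch classification heuristic.
2. **Relative Ca²⁺ permeability** — reversal potentials from averaged voltage
   ramps, inverted through the divalent-extended Goldman–Hodgkin–Katz (GHK)
   reversal relation with single-ion activities to P~Ca~/P~Na~.
3. **Structural charge mapping** — time-averaged distances between acidic and
   basic charge atoms across multi-frame coordinate ensembles, salt-bridge
   calling, charge-cluster partitioning, and scanning for the Tri-Asp motif.
4. **Synthetic data** — a generator producing recordings and coordinate
   ensembles with known ground truth, so every stage is testable end to end.

## Gating model and dose–response analysis

Open probability follows the Hill form
$p(c) = \varepsilon\, c^{N} / (c^{N} + K_{0.5}^{N})$, where $K_{0.5}$ (µM)
is the half-activating ligand concentration, $N$ the Hill coefficient, and
$\varepsilon$ the agonist efficacy ($\varepsilon = 1$ for cGMP; for cAMP it is
the saturating-cAMP/saturating-cGMP current ratio). Net currents are obtained
by subtracting the zero-nucleotide bath sweep pointwise from each activated
sweep under an identical protocol; repeated traces are averaged pointwise
before steady-state extraction. The steady state of a step is defined as the
mean over the trailing 20 % of the step — activation of these channels is
fast relative to a 300-ms step and no kinetics are modeled, so the window
choice only trades noise averaging against drift sensitivity.

`fitHill()` fits $I(c) = I_{max} c^N/(c^N + K_{0.5}^N)$ by
Levenberg–Marquardt least squares. Starting values are taken from the data
(largest observed current; concentration nearest half-max; a logit–log slope
for $N$), and a grid-search oracle in the test suite confirms the optimizer
reaches the global optimum on randomized instances. Because published fits of
this kind do not always state whether $I_{max}$ was constrained to the
saturating current or fitted freely, both modes are provided
(`fixImax = NULL` or a value); defaults fit freely. Currents are analyzed at
−60 mV by default, matching the convention under which the reference
population parameters were tabulated.

Patch classification uses the rapid-evaluation heuristic: homomeric channels
show *low* cAMP efficacy and *little* diltiazem block (high remaining
current), heteromeric channels the opposite. No numeric cuts accompany the
published heuristic, so the defaults are the midpoints of the two population
means — efficacy 0.26 (between 0.19 and 0.33) and remaining-current ratio
0.60 (between 0.79 and 0.40); both are arguments. A patch on the wrong side
of only one cut, or exactly at a cut, is called ambiguous rather than forced
into a class.

## Reversal potentials and the extended GHK inversion

For Ca²⁺-permeability measurements, a voltage ramp (−20 → +20 → −20 mV) is
applied with and without 1 mM Ca²⁺ on the intracellular face in symmetric
120 mM NaCl. The ascending and descending limbs are interpolated onto a
common voltage grid and averaged, which cancels limb-antisymmetric offsets
(e.g. capacitive currents). The reversal potential is the zero of a
least-squares line fitted within ±5 mV of the sign change ("linearization");
the window is a parameter since the published procedure states linearization
without a width.

The permeability inference solves the constant-field (GHK) current equation
extended to divalents. Writing $u = EF/RT$ and single-ion activities $a$,
the net current carried by Na⁺ and Ca²⁺ at relative permeability
$r = P_{Ca}/P_{Na}$ is

$$ i(E) \;=\; kT\,q(u)\,\big(a^{Na}_i - a^{Na}_o e^{-u}\big) \;+\;
   2\,r\,kT\,q(2u)\,\big(a^{Ca}_i - a^{Ca}_o e^{-2u}\big),
   \qquad q(u) = \frac{u}{1 - e^{-u}}, $$

in normalized units. `ghkReversal()` returns the unique zero of $i(E)$ on
[−150, 150] mV to 10⁻⁶ mV. This zero satisfies the implicit relation

$$ E \;=\; \frac{RT}{F}\,
   \ln\!\frac{a^{Na}_o + 4P_o(E)\,r\,a^{Ca}_o}
             {a^{Na}_i + 4P_i(E)\,r\,a^{Ca}_i},
   \qquad P_o(E) = \frac{1}{1+e^{u}},\quad P_i(E) = \frac{1}{1+e^{-u}}. $$

A widely quoted variant of this relation applies a single divalent factor
$P'(E)$ to both sides; that variant agrees with the exact constant-field zero
only to first order in the divalent term. `cngchan` uses the exact zero
throughout, which guarantees three internal consistencies: the returned
potential nulls the net GHK current to below 10⁻¹⁰, it coincides with the
zero crossing of the forward recording simulator, and the forward/inverse
round trip (shift → ratio → shift) is exact to 10⁻⁶ relative.

`permeabilityRatioFromShift()` inverts a measured shift
$\Delta E_{rev} = E_{rev}^{test} - E_{rev}^{control}$ to the $r \ge 0$ whose
model shift equals it, by monotone bracket expansion ($r$ up to 10⁴) and
bisection. The divalent factors use the absolute reversal potential of each
condition, not the shift. A shift of the wrong sign for the declared side of
Ca²⁺ addition raises an error rather than silently clamping $r$ to zero.
RT/F is always derived from the declared solution temperature (default
295 K, room temperature), never hard-coded.

### Ionic activities and calibration

Activities enter as $\gamma c$. The default model computes single-ion
$\gamma$ from the Davies equation,
$\log_{10}\gamma = -A z^2\!\left(\sqrt{I}/(1+\sqrt{I}) - 0.3I\right)$, at the
solution's own ionic strength, with the Debye–Hückel coefficient $A$
evaluated at the declared temperature. Cl⁻, buffers and chelators are treated
as impermeant (the channel is modeled as cation-selective), configurable at
the solution level.

The inferred $r$ for a given shift is roughly proportional to
$1/\gamma_{Ca}$, and published inversions of this kind typically rely on an
activity table from earlier work rather than a printed formula. `cngchan`
therefore also provides a *fixed-table* mode and a calibration routine,
`calibrateGammaCa()`, which keeps $\gamma_{Na}$ at its Davies value and
solves (least squares in $\log r$) for the single $\gamma_{Ca}$ under which
the package's inversion best reproduces a set of reference (shift, ratio)
pairs. Calibrating on the two canonical worked examples of the cone-channel
literature — shifts of −0.47 mV (homomeric) and −4.02 mV (heteromeric)
against reference ratios 1.5 and 17.2 — yields $\gamma_{Ca} \approx 0.54$
(close to tabulated CaCl₂ values near this ionic strength, whereas Davies
gives 0.35), and reproduces both reference ratios within ±8 %:

```{r calibration}
ctrl <- standardSolutions(0)
test <- standardSolutions(1)
cal <- calibrateGammaCa(c(-0.47, -4.02), c(1.5, 17.2), ctrl, test)
cal
permeabilityRatioFromShift(-0.47, ctrl, test, cal)
permeabilityRatioFromShift(-4.02, ctrl, test, cal)
```

Exact joint reproduction is impossible for *any* single activity table: with
symmetric Na⁺ the exact inversion gives
$r = a^{Na}(e^{-2u}-1)/(4a^{Ca}_i)$, fixing the ratio of the two inferred
$r$ values at ≈ 9.9 for shifts of −4.02 and −0.47 mV, while the reference
ratios stand in proportion 17.2/1.5 ≈ 11.5. This is expected: the reference
ratios are population means over different patch sets, while the shifts are
single representative traces. The calibration spreads the residual
discrepancy evenly on the log scale. Under the default Davies model the same
two shifts invert to ≈ 2.7 and ≈ 24.7 — the correct order of magnitude and
ranking, but 40–80 % above the population means, which is why the calibrated
table is the documented mode for quantitative comparison with reference
values.

## Structural charge mapping

Charged sites are one designated charge atom per residue: NZ for Lys, CZ for
Arg, CG for Asp, CD for Glu; histidine is not treated as charged. Residues
of a charged type lacking their atom are reported (with a warning), never
silently dropped. `meanDistanceMap()` averages Euclidean distances between
all (acidic, basic) pairs over a frame window. The "last 20 ns" convention of
trajectory analyses is generalized to a trailing-fraction window (default:
last 25 % of frames), since the frame↔time mapping is file metadata, not
geometry. Subunits are identified by chain ID and mapped separately —
four-fold symmetry is deliberately *not* assumed, because relaxed ensembles
of these bundles settle into different salt-bridge patterns per subunit.

Salt bridges are called at a mean charge-atom distance ≤ 4 Å by default (the
common structural-biology convention; no cutoff accompanies the published
maps), with the full distance map always available so the cutoff affects
calling only; the threshold is closed (a pair at exactly the cutoff is
reported) and ties order deterministically by chain and residue number.
Charge clusters are the connected components of the salt-bridge graph, each
labeled extracellular or intracellular by its mean z relative to the declared
membrane midplane — mirroring the two-cluster organization (an extracellular
cluster around the outer Tri-Asp aspartates and an intracellular cluster
around D3) seen in relaxed bundle models.

The Tri-Asp motif is the conserved 11-residue S2 span with aspartates at
spacing (i, i+4, i+10) — positions 252/256/262 in canine B3 numbering and
221/225/231 in canine A3. `scanTriAsp()` reports all, possibly overlapping,
hits in the sequence's own 1-based coordinates; strict mode requires Asp at
all three positions, and `allow-E-flanks` accepts Glu at the two flanking
positions (as in related Kv channels) while the central position must remain
Asp. The scanner is verified exhaustively against a brute-force oracle on all
two-letter sequences up to length 14.

## The synthetic-data generator

The generator exists so that every analysis stage has inputs with known
ground truth; its defaults emulate the recording conditions under which
cone-channel characterization is performed:

* **Voltage protocols**: 300-ms steps in 10-mV increments between −80 and
  +80 mV; ramps −20 → +20 → −20 mV. Sampling interval 1 ms.
* **Solutions**: symmetric 120 mM NaCl; Ca²⁺-permeability runs add 1 mM
  CaCl₂ to the intracellular (bath) face of the inside-out patch.
* **Gating**: Hill parameters from the homomeric and heteromeric population
  presets (`presetChannelParams()`): K₀.₅ = 10.3/16.0 µM and
  N~h~ = 2.40/1.87 for cGMP, 1665/1569 µM and 2.06/2.36 for cAMP, cAMP
  efficacy 0.19/0.33, diltiazem remaining-current 0.79/0.40, P~Ca~/P~Na~
  1.5/17.2, rectification 1.6/1.25.
* **Unitary current**: the Na⁺/Ca²⁺ GHK current sum, times a multiplicative
  asymmetry factor $e^{-\beta V}$ solved in closed form so that
  |I(−60)|/|I(+60)| equals the requested rectification ratio exactly
  (rectification is an empirical observation here; no mechanism is asserted,
  and the positive factor leaves the reversal potential untouched).
* **Scale**: 300 channels × 25 pS, chosen once so saturating macroscopic
  currents fall in the few-hundred-pA range typical of excised cone-channel
  patches (~450 pA at −60 mV).
* **Diltiazem**: a concentration-independent multiplicative block of
  open-channel current — the block is characterized at a single blocker
  concentration (25 µM), so no concentration dependence is modeled.
* **Noise and leak**: additive Gaussian noise plus an ohmic leak; real bath
  currents are only constrained through the subtraction step, so the leak is
  an explicit stand-in, not a measured model.
* **Structures**: charged-site ensembles either at explicit coordinates, at
  random positions, or arranged on a four-helix-bundle layout with charges
  facing the bundle lumen and per-frame Gaussian jitter. Coordinates are
  quantized to 0.001 Å at generation so PDB round trips are lossless.

What the generator does **not** emulate: single-channel gating kinetics and
activation time courses, capacitive transients, series-resistance artifacts,
Ca²⁺ block of Na⁺ current (the characterization solutions chelate divalents
precisely to remove it), voltage-dependent block, and real conformational
dynamics of helix bundles. Tests passing on synthetic data therefore
establish the correctness of the *analysis* — recovery of known gating,
permeability and geometric ground truth through the full pipeline — not the
biological fidelity of the generator itself.

## Numerical choices

* Root searches: reversal potentials by `uniroot` on [−150, 150] mV to
  10⁻⁶ mV; permeability ratios on [0, 10⁴] with log-spaced bracket
  expansion, relative tolerance 10⁻⁶; GHK flux evaluated with a series
  expansion of $q(u)$ for |u| < 10⁻⁶ to avoid 0/0 at the origin.
* Hill fits: Levenberg–Marquardt (`minpack.lm`), up to 500 iterations,
  ftol/ptol 10⁻¹²; $K_{0.5}$ and $N$ bounded positive.
* Degenerate inputs fail loudly: all-equal concentrations, empty
  concentration lists, non-overlapping ramp limbs, IV curves without a sign
  change, missing activity coefficients in fixed mode, positive shifts under
  internal Ca²⁺ addition, clashing residue numbers, zero-frame ensembles.
* Determinism: simulators reseed only when the noise model carries a seed;
  the pipeline derives per-stage sub-seeds from the run seed so adding a
  stage does not perturb another stage's stream.
* Problem sizes in the shipped test-suite: 200 simulated patches for the
  Hill-recovery and mixture-classification checks, ensembles up to 50 sites
  × 20 frames for the distance-map oracle, and the exhaustive motif check on
  all {D,A} sequences of length ≤ 14 — sizes chosen to exercise the
  estimators well past asymptotic regime while keeping a full run fast.

## Worked example

```{r example}
params <- presetChannelParams("cA3")
noise <- noiseModel(sd = 9, seed = 42)    # ~2% of the saturating current
rs <- simulateDoseResponse(params, stepProtocol(levels = -60),
                           "cGMP", c(1, 3, 10, 30, 100, 500), noise)
tab <- doseResponseTable(rs, voltage = -60)
fitHill(tab)
patchMetrics(simulatePatchSet(params, noise = noiseModel(sd = 9, seed = 43)))
```

## Known limitations

* The activity calibration absorbs, by construction, any residual difference
  between this implementation's exact constant-field zero and whichever
  variant of the extended reversal relation a reference analysis used; it
  cannot make two mutually inconsistent reference values exactly consistent.
* Surface-charge (Gouy–Chapman) corrections are deliberately out of scope —
  the inversion is defined as ignoring surface-charge effects — as are
  anomalous mole-fraction behavior and divalent block.
* The classification cuts are population-derived defaults; patches from
  channels with intermediate subunit stoichiometries will legitimately fall
  in the ambiguous class.
* Distance maps use single charge atoms per side chain; hydrogen-bond
  geometry criteria and solvent accessibility are not evaluated.
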