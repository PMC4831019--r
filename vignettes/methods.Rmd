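---
title: "From a sodium-channel splicing switch to conduction delay: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a sodium-channel splicing switch to conduction delay: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardiosplice)
```

# The problem

In myotonic dystrophy (DM), expanded CUG repeats titrate MBNL splicing
factors away from their targets. One consequence in heart is a switch of the
cardiac sodium-channel gene *SCN5A* from its adult exon 6B to the mutually
exclusive fetal exon 6A. The two exons encode part of the domain-I voltage
sensor, so the switch changes the channel's biophysics: the fetal isoform
(hNav1.5e) activates at potentials about 7 mV more depolarised and carries
about 45% less peak current than the adult isoform; an equimolar mix shifts
by 3.8 mV and loses about 30%. Steady-state inactivation and recovery from
inactivation are unchanged. Reduced and right-shifted INa means slower
upstrokes and slower conduction, which is the proposed link between the
splicing switch and the conduction delay (wide QRS, long PR/AH) seen in DM.

`cardiosplice` implements the full computational chain behind that argument
as testable code: synthetic generators for every input, the curve-fitting
layer that turns voltage-clamp and gel data into channel parameters, the
motif-enrichment statistics that implicate MBNL, PSI quantification from
restriction-digested RT--PCR gels, and tissue-scale simulations that
translate the fitted channel presets into QRS and atrium--His predictions.

# Channel presets and the forward clamp model

The three presets (`channel_preset("adult" | "fetal" | "mix")`) encode the
measured differences: activation mid-potential $V_m$ of $-40$, $-33$ and
$-36.2$ mV (slope $s = 7$ mV), peak-current scales 1, 0.55 and 0.70, a
common inactivation curve ($V_h = -85$ mV, slope $-6$ mV) and a common
recovery constant (20 ms). The adult $V_m$ and slope are representative
two-electrode-oocyte values; what matters downstream are the differences,
which are the measured ones.

`gen_clamp_family()` produces current families under the standard protocol
(holding $-120$ mV, steps $-80$ to $+20$ mV, 50 kHz sampling) from a
Hodgkin--Huxley forward model with closed-form gate relaxation:

$$I(t, V) = g\,m(t)^3 h(t)\,(V - E_{Na}), \qquad
m_\infty(V) = \frac{1}{1 + e^{-(V - V_m)/s}}.$$

Two deliberate conventions make the generate-and-fit chain exact:

* **Peak-current normalisation.** The conductance of each preset is scaled
  internally so that its noise-free peak current at the $-10$ mV reference
  potential is exactly `g_scale` times the adult peak. Amplitude reductions
  were *measured* as peak-current ratios, so the generator defines them the
  same way; fitting peaks at $-10$ mV therefore recovers 45% and 30%
  identically.
* **Voltage-axis translation.** The time-constant curves $\tau_m(V)$ and
  $\tau_h(V)$ are translated by each preset's activation shift (the data
  show the inactivation *time constant* shifting together with activation),
  while the steady-state inactivation curve is shared. Because the driving
  force $(V - E_{Na})$ is common, the normalised conductance of a shifted
  preset is an exact voltage translation of the adult curve, and any
  consistent fitting procedure recovers $\Delta V_{1/2}$ of $+7.0$ and
  $+3.8$ mV up to optimizer tolerance.

$E_{Na}$ is fixed at the Nernst potential of the oocyte bath, $\frac{RT}{F}
\ln(96/10) \approx 57.5$ mV at 22 °C. The fitting layer never assumes this
value: `iv_and_reversal()` interpolates the zero crossing of the peak I--V
relation (and refuses to extrapolate when the protocol does not bracket it,
as the standard $-80\ldots+20$ mV protocol does not --- use an extended
protocol for reversal estimation).

Oocyte practice is mirrored in QC: families whose peaks exceed 6 µA are
excluded from kinetics by `qc_families()`, and the default conductance keeps
adult peaks near 4.6 µA.

# Fitting

All nonlinear fits use Levenberg--Marquardt least squares
(`minpack.lm::nlsLM`) with deterministic, data-driven starts: the
mid-potential starts at the linearly interpolated half-maximum crossing, the
slope at ±7 mV, the IC50 at the geometric mean of the concentrations. Tests
verify each fit against a brute-force grid oracle. The conductance point at
$V = E_{rev}$ is dropped, not regularised. The EMSA binding equation is
implemented as

$$y = \min + \frac{\max - \min}{1 + (x/\mathrm{IC}_{50})^{-n_H}},$$

the sigmoidal reading of the published expression; a flat (mutated-probe)
dataset is flagged degenerate rather than fitted. Group comparisons use
two-sided Student *t* with pooled variance (Welch by flag), no
multiple-testing correction, matching the original analyses; significance
stars sit at 0.05/0.01/0.001.

# Motif enrichment

`gen_exon_cohort()` builds misregulated and control exons (default 2,000
controls, mirroring the published control-set size) on independent contigs
with i.i.d. nucleotides of configurable composition (uniform by default ---
the simplest null consistent with the binomial test). Planting raises a
4-mer's frequency in the *upstream* flank of exons included in DM and the
*downstream* flank of exons excluded in DM, the MBNL splicing-map geometry.
Roughly half the records are placed on the minus strand so that strand-aware
window extraction is exercised end to end.

`build_enrichment_map()` extracts transcript-oriented windows (default
flank 250 nt; the original work does not state its window length, so it is a
recorded parameter), counts all $4^4$ motifs with overlaps allowed
(`Biostrings::oligonucleotideFrequency`; windows containing N contribute
nothing), computes the background per-motif frequency from control windows
of the same region, and tests each motif × region × direction cell with the
exact upper-tail binomial probability. The default significance threshold is
the published $10^{-7}$. Motifs unseen in the background receive a
half-count frequency floor so they remain testable; observed frequencies are
never altered, which preserves the identity `foreground == background
implies p >= 0.5`.

One property of planted designs is worth knowing: planting `UGCU` also
enriches its junction 4-mers (for example `GCUx`), some of which do not
contain a YGC element. On planted cohorts the significant cells are confined
to the planted region × direction pattern and the planted motif ranks first,
but a minority of significant motifs are junction artefacts --- exactly as
real enrichment maps show *mostly*, not exclusively, YGC motifs.

# PSI from digested gels

Exon 6A and 6B amplicons have identical lengths, so quantification uses the
BstBI site (TT^CGAA) present only in 6A. `digest_amplicon()` simulates the
digest (cut after 2 bases in each occurrence, left to right);
`gen_amplicons()` provides deterministic toy sequences reproducing the
printed fragment sizes (116+71 vs 187 bp for the minigene, 115+125 doublet
vs 240 bp endogenous). Band intensities follow mass staining
(intensity $\propto$ molar amount × fragment length, optional lognormal
noise); `psi_from_bands()` inverts this, averaging the 6A doublet as one
molar species, and reports $PSI = 100 \cdot 6A/(6A + 6B)$. With zero noise
the round trip through `gen_psi_tables()` is exact. Relative expression uses
the $2^{-\Delta Ct}$ rule against an RPLP0-style reference.

# The ventricular wedge

The tissue model is a 1D monodomain cable of Endo/M/Epi layers (0.12, 0.65,
0.24 cm; node spacing 0.01 cm, 101 nodes), forward-Euler in voltage and
Rush--Larsen in the gates from a 0.05-mV lookup table, time step 0.005 ms.
Both are halvable, and the convergence test re-runs the *calibrated*
procedure at the halved discretisation, holding QRS changes under 5%. The
distinction matters: at a fixed coupling coefficient, a deliberately slow
transmural front spans only a few grid nodes and its raw lattice velocity
keeps drifting until impractically fine grids; the reported QRS, however,
is defined at calibrated conduction velocity, and that end-to-end quantity
is insensitive to the discretisation.

The membrane is a reduced human ventricular model built for this purpose:
the fast sodium current uses the ten Tusscher--Panfilov human ventricular
formulation ($m^3 h j$), and repolarisation is carried by a sharply
rectifying IK1, an IKr-like delayed rectifier (layer-scaled, Epi > Endo > M,
giving the M layer the longest action potential) and an ICaL-like current.
The choice of the ten Tusscher--Panfilov INa over alternatives is
deliberate: its subthreshold inactivation is slow ($\tau_h \sim 40$ ms near
$-60$ mV), so slow transmural fronts do not accommodate. Formulations with
millisecond-scale subthreshold $\tau_h$ lose the propagation safety factor
at exactly the operating point this study needs --- a depolarising
activation shift on a slow front --- and block. Sodium conductance is
doubled (14.838 × 2 mS/µF at baseline), reproducing physiological
excitability and upstroke velocity.

A splice variant enters the tissue exactly as fitted from the oocyte stage
(`make_ina_variant()`): the activation gate's steady state and time constant
are translated by the fitted shift and the conductance is scaled;
inactivation gates are untouched (an `inactivation_shift` flag exposes the
alternative reading).

Propagation across a wedge is cross-fibre. The along-fibre velocity cited
for such preparations is ~60 cm/s, and transmural anisotropy ratios near 4
are standard, so the default calibration target is a transmural conduction
velocity of 15 cm/s, fixed a priori; `calibrate_conduction()` bisects the
coupling coefficient until the mid-cable velocity (measured between the 25%
and 75% positions) is within 5%. Pacing is 2-ms pulses at twice the measured
diastolic threshold (`measure_diastolic_threshold()`, bisection on a
propagated-response criterion) at 1 Hz. Five beats approximate steady state;
the final beat is analysed --- QRS is insensitive past a few beats, and the
number of conditioning beats is a recorded parameter.

The pseudo-ECG is the unipolar infinite-volume-conductor lead field
evaluated 2.6 cm beyond the epicardial border,
$\phi(t) \propto \sum_x (-\partial V_m/\partial x)\,\partial_x(1/r)\,\Delta x$,
in arbitrary units. QRS is measured at a 5% amplitude threshold. In this
reduced model, repolarisation deflections follow the R wave without a quiet
gap, so the wedge wrapper closes the depolarisation window 2 ms after the
last node's upstroke crossing; `measure_qrs()` on a bare trace falls back to
gap-based clustering.

With the shipped calibration the adult wedge gives a QRS near 66 ms
(printed control: 72 ms) and the fetal variant near 97 ms (printed: 88 ms),
with strict adult < mix < fetal ordering. The *relative* widening is larger
than the printed 22%: in a continuum cable the conduction velocity scales
roughly with $\sqrt{g_{Na}}$, so a 45% current reduction alone forces a
widening of at least ~35% before the activation shift adds its part.
Reproducing a 22% widening would require a sub-square-root velocity
dependence whose provenance (the original modified-ORd implementation and
its QRS annotation) is not printed; the package reports what its model
computes.

# The atrium--AV-node strand

The cited rabbit AV-node cell equations live outside this work, so the
strand is a documented simplified alternative: 156 cells --- atrium (25),
transitional ramp (8), nodal core (100), ramp (8), His (15) --- with every
heterogeneous property interpolated along a raised-cosine "nodalness"
profile (abrupt segment boundaries create source--sink mismatches that
produce artefactual block). Nodal cells rest near $-78$ mV through a linear
background leak replacing IK1, which partially inactivates their fast
sodium current; their coupling is weak (1e-4 vs 8e-4 cm²/ms); their action
potentials are kept short (smaller ICaL, larger IKr) so that the 350-ms
pacing interval leaves recovery time --- with long nodal plateaus the slow
j-gate recovery produces Wenckebach-like dropped beats, which the code
detects and reports rather than averaging over.

The splice variant is applied to the proximal Na-dependent cells (weighted
by nodalness); atrial and His cells keep adult kinetics, so stimulus capture
is variant-independent and the AH difference isolates nodal conduction. The
nodal conductance and coupling were calibrated once so that the adult strand
gives a control AH near the printed 81 ms (shipped defaults: 76.9 ms); the
mix and fetal intervals are then genuine outputs (102.8 and 148.6 ms against
printed 143 ms for fetal) and AH rises monotonically as the variant weakens
INa.

# What the synthetic data do and do not show

The generators reproduce the statistical structure the analyses assume ---
Boltzmann-shaped activation with additive recording noise, Hill-shaped
binding, i.i.d. background sequence with planted motifs, mass-staining band
intensities, Gaussian Ct values. They do not emulate oocyte batch effects
beyond noise, linkage or composition structure in real introns,
heteroduplex or stoichiometric gel artefacts, or sequencing reads (read
mapping and differential-splicing callers are out of scope; their
thresholds only define the synthetic misregulated cohort). Green tests
therefore certify the *chain* --- that the statistics and simulations
recover what the generators encode --- not the biology of any particular
dataset.

Problem sizes used by the shipped tests and the acceptance script: clamp
fits on 21-potential families; motif maps on 200+200 misregulated vs 2,000
control exons with 250-nt flanks; the wedge at 101 nodes × 5 beats; the AV
strand at 156 cells × 5 beats at 350 ms.

# Numerical choices and limitations

* Explicit monodomain integration bounds the coupling coefficient by
  $D\,\Delta t/\Delta x^2 < 0.45$; the calibration bracket respects it.
* Gate lookup tables are linear in 0.05-mV bins over $-150\ldots100$ mV;
  Rush--Larsen factors are precomputed per time step.
* Ties in threshold crossings resolve to the earlier sample at QRS onset
  and the later at offset; upstroke times interpolate linearly within a
  time step.
* The strand is phenomenological: it reproduces slow, decremental,
  Na-sensitive nodal conduction and the control AH, not rabbit AV-node
  electrophysiology in detail. Dual-pathway physiology, autonomic
  modulation, and 2D/3D geometry are out of scope.
* The printed simulation bath concentrations duplicate the oocyte solution;
  the tissue models use standard ventricular reversal potentials
  ($E_{Na} = 70$, $E_K = -91$, effective $E_{Ca} = 50$ mV), treating the
  printed set as a transcription ambiguity.
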