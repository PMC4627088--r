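---
title: "Models and methods behind cgsearch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cgsearch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cgsearch` simulates and analyses facilitated diffusion: a DNA-binding
protein searching for its target site on a DNA duplex by a mixture of 3D
diffusion, hopping, and sliding. The package contains

* a three-bead-per-nucleotide DNA model (phosphate / sugar / base) with
  Debye–Hückel phosphate electrostatics,
* a one-bead-per-residue native-topology (Gō) protein model,
* a cylindrical caging potential that restricts DNA base-pair centers to a
  radius *R* about the fixed end-to-end axis, mimicking macromolecular
  crowding,
* a BAOAB Langevin engine with periodic boundaries, end constraints, a
  rigid-DNA mode and deterministic seeding,
* the observable suite: search-mode classification
  (sliding/hopping/3D), groove geometry and occupancy, rotation–translation
  coupling, sliding-event statistics, 1D diffusion coefficients, and
  specific-binding kinetics via the fraction of specific contacts
  Q~sp~.

# The DNA model

Each nucleotide carries three beads at fiber-model cylindrical positions.
Strand 1 places site *s* of base pair *i* at azimuth
$(i-1)\,\Omega + \phi_s$ and height $(i-1)\,h + z_s$ (twist
$\Omega = 36^\circ$/bp, rise $h = 3.38$ Å); strand 2 uses the dyad-mirrored
placement. Base beads sit at $\phi = 90^\circ$ so base-pair centers fall
exactly on the helix axis, which makes the cage distance $d_i$ and the
end-constraint geometry exact at build time.

**Groove calibration.** Groove widths are defined as raw cross-strand
phosphate–phosphate distances at fixed registers: $W_{MJ}(i) = |P_1(i) -
P_2(i-3)|$ and $W_{MN}(i) = |P_1(i) - P_2(i+4)|$. The phosphate azimuth and
axial offset are solved (2×2 Newton iteration, `calibrate_helix_params()`)
so the rigid duplex reproduces 17.25 Å (major) and 11.58 Å (minor) exactly;
both registers remain genuine local minima of the cross-strand distance,
i.e. the registers are not an arbitrary choice. The sugar radius is then
re-derived so both backbone P–S bonds keep a 3.9 Å design length.

**Energy terms.** Bond ($k_2 d^2 + k_4 d^4$), angle ($k(\theta-\theta_0)^2$)
and backbone torsion ($k_1[1-\cos\Delta\phi] + k_3[1-\cos 3\Delta\phi]$)
terms take their equilibrium values from the build geometry (a Gō-style
parameterisation of B-DNA). Non-bonded terms: intra-strand stacking and
Watson–Crick pairing as 12-10 wells at native distances (pairing depth 2.0
kcal/mol for A·T, 3.0 for G·C, the 2:3 hydrogen-bond ratio), cross-strand
*cross-stacking* 12-10 wells between diagonal bases, a purely repulsive WCA
excluded volume, a solvent-induced cohesion term (attractive branch of a
Morse well between base beads, flat below its minimum — the repulsive branch
is delegated to excluded volume), and Debye–Hückel electrostatics between
the $-1e$ phosphates,
$$U_{ij} = \frac{332.06\,q_iq_j}{\varepsilon_r r}\,e^{-r/\lambda_D},\qquad
\lambda_D = (8\pi l_B N_A I)^{-1/2},$$
with $\varepsilon_r = 78$, truncated and shifted at $5\lambda_D$.

**Why cross-stacking.** With only intra-strand stacking and WC pairing the
duplex has a soft inter-strand shear/twist mode: at 300 K it untwists from
36° to ≈33.8°/bp and the groove widths drift several Å from B-form. The
diagonal cross-strand wells pin the helical register. The backbone torsion
constants were then fixed at the stiffness plateau where groove statistics
stop responding to further stiffening — a structural-integrity criterion
(the duplex should fluctuate *about* B-form), not a fit to any published
groove statistic. With these choices the free 200 bp duplex at 300 K / 20 mM
fluctuates with interior time-averaged widths of roughly 16.7–17.2 Å (major)
and 13.3–14.4 Å (minor), both wider than rigid B-form with the larger shift
in the minor groove; the acceptance script recomputes these numbers from
scratch at every run.

**Parameter provenance.** The published three-site model's exact parameter
tables are not available in this offline build; the package keeps that
model family's functional forms and documents every constant in
`inst/extdata/ff_params.json`. The constants are versioned and fixed — tests
read them from the file rather than hard-coding values.

# The protein model

One bead per residue at the Cα position; +1e on Arg/Lys, −1e on Asp/Glu
(His neutral). Bonds/angles/dihedrals at native values, native contacts as
12-10 wells (depth ε_native = 2.0 kcal/mol, the reduced energy unit of the
protein model), non-native WCA repulsion, and intra-protein Debye–Hückel
among charged residues. Native contacts come from a 4.5 Å heavy-atom
cutoff (|i−j| ≥ 3) on an all-atom structure, or a 6.5 Å Cα cutoff for
synthetic proteins. At 300 K the foldedness monitor (fraction of native
contacts Q with a 20 % distance tolerance) stays at mean Q ≈ 0.99 — the
model protein is "completely folded at the simulation temperature", which is
the calibration contract for ε_native.

**Protein–DNA coupling.** The protein interacts with DNA non-specifically
through cross excluded volume and Debye–Hückel terms (charged residues ×
phosphates). The absolute protein–DNA electrostatic scale is not derivable
from the study text; it is the single calibration constant
`cross$elec_scale` (default 2.5), set so that on rigid DNA the protein is
predominantly DNA-associated at 20 mM and fully dissociated by 100–200 mM —
the salt behavior the study states. The steric energy bookkeeping E~ev~
(intra-DNA + protein–DNA excluded volume, never the cage term, never
intra-protein repulsion) is exposed per frame.

# Confinement

The caging potential is implemented literally as printed:
$$V_{cage} = \sum_i K\left[x_i^4 - 2x_i^2 - 1\right]
  H\!\left(\tfrac{C}{2} - (R - d_i)\right),\qquad
x_i = \frac{C}{2(R - d_i)},$$
with $K = 100$, $C = 4$ Å, $H(0) = 0$, and $d_i$ the distance of base-pair
center *i* from the line through the two constrained end centers. The
bracket has zero slope at $x = 1$, so the force is continuous at the
Heaviside onset even though the literal energy jumps by $-2K$; a
`continuity_shift` flag adds $+2K$ inside the active region for continuous
bookkeeping (forces identical). `R = 0` is the rigid sentinel (frozen
ideal B-DNA), `R = Inf` disables the cage. If an integration step would put
a center within 0.01 Å of the wall the step is rejected and retaken with a
halved time step (the potential diverges at the wall).

# Dynamics

BAOAB Langevin splitting, bead mass 1, γ = 0.25 (inverse reduced time),
kT = 0.59616 kcal/mol at 300 K. dt = 0.01 reduced time by default — chosen
by a stability scan: it keeps the γ = 0 secular energy drift below 1e-4 of
the mean kinetic energy over 1e4 steps while configurational averages are
unchanged on halving dt (at dt = 0.02 a small discretisation bias in groove
statistics becomes visible, so acceptance runs use 0.01). Randomness comes
from one xoshiro256++ stream seeded per run; trajectories are bitwise
reproducible. Verlet neighbour lists with a 3–4 Å skin rebuild on a
max-displacement trigger. For production-style runs an optional
multiple-timestep split refreshes Debye–Hückel pairs beyond `mts_r` (40 Å)
every `mts_every` (4) steps; the far-field force varies slowly there
(λ_D ≈ 21 Å at 20 mM) and the default is OFF so all correctness tests use
exact per-step evaluation.

Periodic box 220 × 220 × 820 Å, DNA along Z; coordinates are stored
unwrapped (minimum-image displacements are used in all non-bonded terms and
analysis distances), so axial diffusion can be measured without unwrapping
artifacts. The two terminal base-pair centers are restrained harmonically to
their initial positions; only DNA is confined, never the protein.

# Search-mode classification

Per frame: 3D diffusion if the recognition-region center is more than 30 Å
from the closest base-pair center; sliding if (all three) the center is
within 18 Å, at least 70 % of recognition beads are in contact with the
major groove, and the orientation angle Ψ is below 25°; hopping otherwise
within 30 Å. A recognition bead is "in major-groove contact" when it is
within 10 Å of any sugar/base bead *and* nearer the major-groove midline
than the minor-groove midline at its closest base pair (midlines =
midpoints of the register phosphate pairs).

**Ψ.** The exact construction is deliberately kept behind one switch.
Default (`psi_mode = "surface"`): the angle between the recognition-helix
principal axis (leading right-singular vector of the centered recognition
Cα coordinates) and the local DNA surface plane — 0 when the helix lies
flat along the groove, 90° when it points radially away. The alternative
(`"tangent"`) measures against the major-groove midline tangent. Both are 0
for ideal groove tracking; the surface form is fold-agnostic (a straight
recognition helix seated across the spiralling groove channel scores
Ψ ≈ 50–70° under the tangent form even when fully engaged, which
under-counts sliding for helical-insertion folds).

θ is the azimuth of the recognition center about the cage axis (or a ±5 bp
local line fit for unconfined DNA), unwrapped; Z the axial coordinate.
Rotation-coupled sliding shows up as θ–Z correlation ≈ 1 with slope ≈
34 Å/360° (the helical pitch).

Derived observables follow the definitions in the analysis module: maximal
SLIDING runs are sliding events (length = |ΔZ|); search efficiency is the
mean number of unique base pairs visited during sliding per DNA-association
episode (episodes are delimited by 3D excursions; the per-event variant is
also exported); D1 is half the slope of the MSD of Z over lags 10 frames to
10 % of each contiguous sliding+hopping stretch (stretches < 100 frames are
skipped, no bridging across 3D excursions). The slope fit goes through the
origin (MSD(0) = 0 identically) and is weighted by count/lag⁵: the variance
of a single-trajectory MSD estimate grows steeply with the lag, and an
unweighted fit over the full window scatters by tens of percent even on a
10⁵-frame ideal random walk, while this weighting recovers a known D to a
few percent.

# Binding kinetics

The target sequence is inserted at the center of the duplex
(start = ⌊(L−t)/2⌋+1). Specific contacts are *soft attractive* wells at
native distances: a 12-6 tail above r₀ and a flat −ε core below it (zero
force; sterics stay with the separate excluded-volume term, which is why
these pairs are *not* excluded from it). A hard 12-6 core here would be both
unphysical ("soft" is the stated character of the interaction) and
numerically brittle when a replica starts overlapped. Native distances come
from a reference bound pose (either an experimental co-crystal via
`extract_specific_contacts()`, or the package's synthetic docking
convention: recognition center on the major-groove midline, helix axis
along the groove tangent). Non-specific sequence interactions are
short-ranged 12-6 wells between recognition residues and non-target bases
with per-pair depths drawn from N(0.6, 0.1²) kcal/mol, truncated positive,
frozen per replica (fresh draw per replica by default; `shared_map`
switches to one map for the ensemble). Replicas start with the recognition
center 20 bp before the target and 30 Å off the DNA surface. Success =
Q~sp~ ≥ 0.8 sustained for 10 output frames; the ensemble curve ⟨Q~sp~⟩(t)
averages successful replicas only.

# What the synthetic data emulate — and what they do not

The synthetic-data module replaces all external inputs: the ideal B-DNA
builder replaces a structure-server output (pinned by the printed rigid
groove widths); random sequences replace the study's random 200-mer; the
synthetic mini-protein replaces the downloaded DNA-binding domain. The
`winged` fold exists because a bare cationic helix parks in the *minor*
groove (the electrostatic potential is deeper between the closer phosphate
rows); two neutral wing helices at ±8 Å give the steric major-groove
selectivity of real DNA-binding domains. A green trend test with this
stand-in establishes that the *model physics* (screened electrostatics vs.
salt, steric selection of the wide groove, mode classification) behaves as
described — it does not establish quantitative mode propensities for the
real protein, which require the experimental structure (see the
acceptance-3 note in the decisions ledger: the structure cannot be
downloaded in this environment, so that criterion is deliberately red).
Scripted trajectories with known mode labels test the classifier end to end
against ground truth, independently of any dynamics.

# Numerical choices and degenerate inputs

* 12-10/12-6 wells and WCA cores are evaluated at `max(r, 0.4 r0)` /
  `max(r, 0.5 σ)` to keep the integrator finite through pathological
  overlaps; energies above 1e9 kcal/mol abort with a diagnostic.
* exp(−x) in the Debye–Hückel and solvent kernels uses an 8192-node table
  with a third-order Taylor remainder (relative error < 1e-12), so force =
  −∇E checks hold to 1e-5 through the fast path.
* Coincident bonded beads raise an error (undefined angles/torsions); angle
  forces are skipped within 1e-8 of sin θ = 0.
* Single-bp duplexes have no phosphates, bends or torsions and are valid
  inputs throughout the builder and energy paths.
* Classification ties (equidistant base pairs) break to the lower index;
  θ unwrapping forbids jumps above 180°/frame.
* Zero-variance series return NA with a reason (θ–Z and dynamics
  correlations) rather than NaN.

# Known limitations

* The DNA force-field constants are package-defined (see the provenance
  note in `ff_params.json`), not the published table of the original
  three-site model; sequence dependence enters only through AT/GC pairing
  depths.
* No intersegmental transfer detection, no base-pair-step helical parameter
  decomposition, no explicit crowders, no absolute time calibration of MD
  steps to seconds.
* The synthetic mini-protein is a stand-in: quantitative mode propensities
  and kinetics for Sap-1 require the experimental 1BC8 structure as input.
* Desk-scale runs are 1–2 orders of magnitude shorter than the study-scale
  10⁸-step productions; stochastic observables carry corresponding
  uncertainty.
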