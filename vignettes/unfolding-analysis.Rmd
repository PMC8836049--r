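---
title: "Analysing early protein unfolding in MD trajectories with mdunfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing early protein unfolding in MD trajectories with mdunfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdunfold)
```

## The scientific problem

Human gammaD-crystallin (HGDC) is a 173-residue, two-domain eye-lens protein
whose aggregation underlies cataract. Each domain is built from two Greek-key
motifs of intercalated antiparallel beta-strands, and the two domains are held
together by a hydrophobic interdomain interface. When partially destabilised
conformers of such a protein are simulated by molecular dynamics, the
questions of interest are *which* structural elements detach first, *in what
order*, which aromatic "clasp" interactions are lost or newly formed, and how
the two domains move relative to each other. `mdunfold` implements that
analysis battery for multi-model PDB trajectories and couples it to a
synthetic-trajectory generator with scripted ground truth, so every stage can
be validated quantitatively without running an MD engine.

## Native contact fraction Q

A contact between residues $i$ and $j$ is counted when any heavy atom of $i$
lies within 6.5 Å of any heavy atom of $j$. "Within" is read as a closed
bound ($\le 6.5$ Å). The contact fraction

$$Q(t) = \frac{\#\,\text{contacts at time } t}{\#\,\text{contacts in the
reference structure at } t=0}$$

is 1 at the reference frame by construction. Two conventions are implemented
because the definition's numerator ("the total number of contacts counted in
each time frame") counts *all* current contacts, so non-native contacts can
push $Q$ above 1. The default follows that literal counting; `mode = "native"`
restricts the numerator to reference pairs, guaranteeing $Q \le 1$. The
minimum sequence separation defaults to $|i-j| \ge 1$ (every pair counts);
a higher separation (e.g. 3) yields tertiary-contact-focused maps.

Contact detection uses a cell-list spatial grid with cells of one cutoff
length; the grid only prunes candidate pairs and is set-identical to the
all-pairs computation (this equivalence is asserted in the test suite against
an independent distance-matrix oracle on hundreds of random frames).

Regional $Q$ restricts both numerator and denominator to pairs with at least
one member inside the region, i.e. the region's contacts with its
neighbouring residues. A sustained-drop detector (`detect_q_drop`) calls a
detachment when the series stays below `drop_factor` (default 0.8) times the
early-trajectory baseline for a persistence of 3 sampled frames.

## Ensemble and subtractive contact maps

The ensemble contact map holds, for each residue pair, the fraction of
sampled frames in which it is in contact. Two ensembles are compared by a
signed subtractive map. Because the two denaturant ensembles of interest
start from *different* reference structures, the raw difference of
frequencies and the difference of per-ensemble change maps answer subtly
different questions; which one the original figure used is ambiguous, so both
are provided (`mode = "raw"`, the default and literal reading, and
`mode = "loss"`, which first subtracts each ensemble's own frame-0 indicator
map). In either mode the result negates under operand swap and negative
entries mark contacts whose loss is greater in the first ensemble.

## Secondary structure and unfolding events

Backbone hydrogen bonds use the Kabsch–Sander electrostatic model

$$E = 0.084 \cdot 332 \cdot \left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}}
- \frac{1}{r_{OH}} - \frac{1}{r_{CN}}\right)\ \text{kcal/mol},$$

with a bond called below $-0.5$ kcal/mol. Amide hydrogens are reconstructed
1.0 Å from N, anti-parallel to the preceding residue's C=O vector, when the
input has no hydrogens. The assignment implements the DSSP core: 3/4/5-turns
give G/H/I (two consecutive n-turns), parallel/antiparallel bridge patterns
give B and, when bridges chain into ladders, E; remaining turn residues are
T, default C, with priority H > E > G > I > B > T > C. Donor–acceptor pairs
are pre-filtered at 9 Å CA–CA (the four 1/r terms cannot reach −0.5 kcal/mol
beyond that). A CA–CA step over 4.5 Å is treated as a chain break that
terminates every n-turn and bridge neighbour relation; clashing (nonphysical)
geometry is treated as "no bond". Solvent accessibility, bend flags and
polyproline detection are out of scope, as is anything the unfolding-event
logic does not consume.

Unfolding events are called per named region from the per-frame percentage of
E/B labels among the region's residues. The series is smoothed with a centred
5-frame rolling mean; an event fires at the first raw crossing below the
threshold (default 50%) within half a window of a rolling-mean run that stays
below threshold for at least 5 sampled frames, provided the region had been
at or above threshold before. The threshold and persistence are free
parameters (no numeric rule exists to inherit, only an observed sequence of
events); both are exposed and tunable. A region ending below 10% beta content
while other regions also lost strands is flagged `melt`. Events sorted by
onset give the temporal detachment sequence — the pipeline's headline output.

## Aromatic interactions

Rings are the 6-membered Phe/Tyr ring, the full 9-atom Trp bicycle and
(optionally, off by default) the His imidazole. An interaction is present
when the ring-centroid distance falls inside the closed band 4.5–7.0 Å, the
range within which most aromatic–aromatic interactions in proteins fall.
"Minimal distance" traces in the literature may mean either centroid or
nearest-ring-atom distance; both metrics are implemented
(`metric = "centroid"` is the default because the band criterion is defined
on centroids) and neither is asserted to be the original figures' choice.
Persistence is the percentage of sampled frames in band. Clusters are
connected components (size ≥ 3 by default) of the in-band graph —
membership is transitive by design. A cluster-formation event is a member
set absent at the reference frame that is detected intact for at least 5
consecutive sampled frames.

## Essential dynamics

Frames are superposed to frame 1 on the selection (main-chain heavy atoms by
default) before the coordinate covariance is formed; whether the original
pipeline aligned first is not stated, but aligning is standard
essential-dynamics practice and removes the six rigid-body modes, so it is
the package's choice. Eigenpairs come from the SVD of the centred frame
matrix (numerically equivalent to diagonalising the covariance matrix and
exact for the identities $\sum_k \lambda_k = \mathrm{tr}(C)$ and
$\mathrm{var}(\text{projection}_k) = \lambda_k$, both asserted at 1e-6
relative tolerance). Eigenvector signs are fixed by making the first
component above 1e-10 positive, for reproducibility.

## Interdomain closure/twist decomposition

The published domain-motion tool's decomposition is not restated in the
source literature, so a simplified, fully specified stand-in is used: the
frame is superposed on the *fixed* domain's mainchain, the Kabsch rotation of
the *moving* domain gives an axis and angle, and with $\hat d$ the unit
vector between the two domains' mainchain centroids in the reference,

$$\%\,\text{twist} = 100\,(\hat a \cdot \hat d)^2, \qquad
\%\,\text{closure} = 100 - \%\,\text{twist}.$$

The squared projection makes the split independent of axis sign and exactly
complementary. A frame is labelled closure when closure ≥ 50%. Frames
rotating less than `angle_floor = 1.0`° carry no meaningful axis and are
excluded from motion fractions (reported separately); the floor guards
against noise-dominated axes. The hinge point is the moving-domain centroid
projected onto the screw axis — the reference figures place the axis only
visually, so this definition is the package's own. Acceptance of this module
is by recovery of scripted rigid-body rotations (0.1° tolerance), never by
parity with the original tool. Domains are user-specified regions;
window-based dynamic-domain discovery is out of scope.

## Potential-energy bookkeeping

The energetics module mirrors the term structure
$E_{pot} = E_{valence} + E_{nonbond}$,
$E_{valence} = E_{str} + E_{bend} + E_{tor} + E_{inv}$,
$E_{nonbond} = E_{van} + E_{elec} + E_{hbond}$, with
$\Delta E = E(t_{end}) - E(t_0)$ an exact subtraction. Scorers are pluggable;
the built-in toy scorer implements harmonic bonds ($E = k\,\Delta r^2$ — the
convention is declared, not the $\tfrac12 k$ form), Lennard–Jones dispersion
with Lorentz–Berthelot combination and Coulomb electrostatics at uniform
dielectric, and records the remaining terms as zero with a flag. A full
protein force-field parameterisation is intentionally not reproduced — the
original work used a commercial implementation and prints no parameters — so
the module's contract is the bookkeeping identities and endpoint
subtraction, which the toy scorer exercises end to end. Endpoints default to
single frames; window averaging is available behind a parameter because the
original convention is unstated.

## The synthetic-trajectory generator

`build_toy_two_domain()` constructs an idealised two-domain antiparallel
sheet: strands along x at 3.5 Å per residue, 4.85 Å CA–CA ladder spacing,
carbonyls alternating in the sheet plane so that partnered rungs have exactly
linear N–H···O=C geometry with $r_{ON}$ = 2.9 Å (Kabsch–Sander energy ≈ −2.9
kcal/mol, comfortably below the −0.5 threshold). Strands follow one another
in sequence without loop residues; the inter-strand jump acts as a chain
break. Strand length defaults to 7 — an odd length puts both strand termini
on non-hydrogen-bonded rungs, so every interior residue is strand-assigned,
whereas even lengths lose the terminal rung to the partner strand's
chain-start residue (which has no amide H). Designated residues carry
idealised aromatic rings 2.8 Å above the sheet plane. The geometry is an
idealisation, not a structural mimic: the acceptance surface is parameter
recovery, not realism.

`simulate_trajectory()` executes an `unfolding_script`: per-frame coordinates
are base + scripted rigid interdomain rotation (ramped linearly over the
trajectory, axis constructed from a chosen twist fraction) + ramped rigid
detachments of named regions (linear displacement over `ramp` frames; the
ground-truth onset is the first ramp frame) + aromatic cluster placements
(members moved to regular-simplex vertices with the scripted edge length,
placed absolutely so they compose predictably with rotations) + isotropic
Gaussian noise. Everything is deterministic given the seed.

The noise model is independent per atom per frame. That differs from real
thermal motion, which is largely collective: at equal amplitude, independent
noise exaggerates *relative* (internal) geometry fluctuations by roughly
$\sqrt 2$ per axis. The presets therefore use σ = 0.1 Å, which produces
realistic internal jitter (~0.15 Å in hydrogen-bond donor–acceptor
distances) even though the per-atom displacement is smaller than a typical
crystallographic B-factor would suggest. The RMSF calibration check uses
σ = 0.5 Å deliberately — RMSF measures absolute, not relative, displacement,
and its analytic expectation under isotropic noise is $\sigma\sqrt3$.

What the generator does *not* emulate: solvent and denaturant molecules,
force-field physics, temperature coupling, realistic Greek-key topology
(loops, strand pairing across motifs), or side chains beyond aromatic rings.
Consequently, passing the recovery tests shows that the analysis stack
measures what it claims on geometrically well-posed inputs with known truth;
it does not validate force fields or sampling, and real trajectories will
show gradual, partially reversible transitions rather than the generator's
crisp ramps.

### Study-scale choices

The packaged presets run 100 frames at 1 ns/frame over a 56-residue
two-domain system (8 strands of 7), with detachments scripted at 15, 35 and
50 ns — a desk-scale analogue of the sequential motif-2-first detachment
order, exercised across 10 seeds in the acceptance checks. The RMSF
calibration uses 2000 frames; the grid-vs-oracle equivalence uses 200 random
300-residue frames at protein-like density. These sizes were chosen so the
entire validation battery runs in minutes on one CPU while keeping every
statistical tolerance comfortable (e.g. the RMSF ratio concentrates within
~1% at 2000 frames against a 5% acceptance band).

## Residue numbering and the HGDC region map

PDB author numbering is preserved alongside a 1-based sequential index, and
all region configs address author numbers, because the HGDC literature's
residue labels (G61~A64, C33~V38, Q55~L58, Y46/Y51/Y56/Y63, W69, ...) are
author numbers under Met-inclusive numbering in which the mature chain
occupies positions 2–174. The built-in region map ships those regions:
the motif 2 beta3-strand (61–64) that detaches first, its antiparallel
partner motif 1 beta3-strand (33–38), the motif 2 beta2-strand (55–58)
carrying interface residues, the motif 3 loop (109–118), the de novo
strand-forming stretch (116–119), the aggregation-prone stretch (54–58), the
motif 4 beta2/beta3 block (138–162), and the two domains (N-td 2–83,
C-td 88–174, the standard split about the linker). Insertion codes are
rejected and the first altloc is kept — sufficient for this study's inputs.
The packaged `hgdc_ca_synthetic.pdb` is a CA-only *synthetic stand-in*
carrying the mature 173-residue sequence on an arbitrary smooth curve; it
exists so sequence-composition and region-lookup behaviour can be exercised
offline, and its coordinates carry no structural information.

## Numerical choices and degenerate inputs

* Kabsch superposition requires ≥ 3 non-collinear points and rejects
  rank-deficient selections; the proper-rotation branch (det = +1) is always
  taken.
* RMSF uses a two-pass reference (align to frame 1, average, re-align to the
  average) since tooling defaults differ on this point.
* Rotation angles near 0 return a conventional axis and angle 0; near 180°
  the axis comes from the +1 eigenvector.
* Q is undefined (an error) when the reference contact set is empty, rather
  than silently 0/0.
* Static trajectories: PCA returns all-zero eigenvalues; motion fractions
  over an all-below-floor trajectory are `NA` with a warning rather than a
  fabricated 100/0 split.
* All event detectors report sampled-frame indices alongside times, so
  stride interacts transparently with tolerances expressed in frames.

## A worked run

```{r example, eval = FALSE}
pre <- preset_unfolding("gdnhcl_like", seed = 1)
sim <- simulate_trajectory(pre$structure, pre$script, pre$regions)
an <- unfolding_analysis(sim$trajectory, pre$regions,
                         fixed_domain = "C_td", moving_domain = "N_td")
summary(an)
plot(an)

out <- run_pipeline(list(analysis_input = sim$trajectory,
                         regions_map = pre$regions, out_dir = tempdir()))
out$manifest
```

The README shows the exact console output of this run; the event table lists
the three scripted detachments in scripted order with onsets at the scripted
times.

## Known limitations

* The DSSP subset omits solvent accessibility, bends and polyproline; the
  event logic consumes only E/B content, so the omissions do not affect it.
* The closure/twist split is a deliberately simplified decomposition, not a
  reimplementation of the published domain-motion tool; numbers from the two
  will differ even on identical inputs.
* The literal-Q convention can exceed 1 on compaction; use the native mode
  when a bounded order parameter is required.
* The toy energy scorer is for bookkeeping validation, not for ranking
  conformers of real proteins.
* Only PDB input is supported; converting compressed trajectory formats
  (XTC/DCD) is the user's job.
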