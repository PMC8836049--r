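# mdunfold

Conformational analysis of early protein-unfolding MD trajectories, built
around the two-domain Greek-key beta-sandwich fold of human gammaD-crystallin
(HGDC) — the 173-residue eye-lens protein (14 Tyr, 4 Trp, 6 Phe) whose
aggregation underlies cataract. Given a trajectory (multi-model PDB), the
package answers the questions that drive early-unfolding studies: which
beta-strands detach, in what temporal order, which aromatic "clasp"
interactions are lost or newly formed, how the native contact network decays,
and how the two domains rotate relative to each other.

It is written for structural bioinformaticians who have trajectories from any
MD engine and want the analysis layer: no force field, no simulation engine,
plain R with base-R matrix numerics.

## What it computes

* **Native contact fraction** Q(t) = contacts at time t / contacts at t = 0,
  with a contact defined as any heavy-atom pair of two residues within
  6.5 Å (closed bound). Whole-protein, per-domain and per-region series;
  sustained-drop detection.
* **Ensemble contact maps** (per-pair frame fractions) and **signed
  subtractive maps** between two ensembles, in raw-difference and
  change-map ("loss") modes.
* **Secondary structure**: Kabsch–Sander hydrogen-bond energies
  `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol (bond below
  -0.5), minimal DSSP assignment (H/G/I/E/B/T/C), per-region beta content,
  and **ordered unfolding events** (threshold + persistence on smoothed beta
  content).
* **Aromatic interactions**: ring-centroid distances, presence in the
  4.5–7.0 Å band, per-pair persistence percentages, cluster detection
  (connected components) and cluster-formation events.
* **Essential dynamics**: PCA of the aligned coordinate covariance, with
  exact spectral identities, and per-frame projections on the top modes.
* **Interdomain motion**: Kabsch rotation of one domain after superposition
  on the other, decomposed into percent closure / percent twist via the
  squared projection of the rotation axis on the interdomain vector;
  per-frame labels and motion fractions.
* **Potential-energy bookkeeping** with a pluggable scorer
  (E_pot = E_valence + E_nonbond term structure) and exact endpoint deltas.
* **Synthetic trajectories with ground truth**: an idealized two-domain
  antiparallel sheet builder plus scripted detachments, rigid rotations with
  a chosen twist/closure mix, aromatic cluster formation and Gaussian noise —
  so every analysis above is testable against known answers.

## Worked example

A scripted "strong denaturant"-like preset detaches three strands at 15, 35
and 50 ns (100 frames, 1 ns/frame, 56-residue toy beta-sandwich, coordinate
noise 0.1 Å):

```r
library(mdunfold)
pre <- preset_unfolding("gdnhcl_like", seed = 1)
sim <- simulate_trajectory(pre$structure, pre$script, pre$regions)
an  <- unfolding_analysis(sim$trajectory, pre$regions,
                          fixed_domain = "C_td", moving_domain = "N_td")
summary(an)
```

```
Early-unfolding trajectory analysis
  56 residues, 100 frames (0..99 ns)
  final backbone RMSD: 8.91 A; final whole-protein Q: 0.700
  7 beta-loss event(s), first: d1_s1 at 15 ns
  interdomain motion: 0.0% closure / 100.0% twist
  essential dynamics: lambda1 2.8e+03 A^2 (79.6%), lambda2 544 A^2 (15.4%)
  event sequence:
    1. d1_s1                   15 ns  melt (beta 71% -> 0%)
    2. motif2_beta3            15 ns  melt (beta 71% -> 0%)
    3. d1_s4                   35 ns  melt (beta 71% -> 0%)
    4. N_td                    35 ns  beta_loss (beta 59% -> 29%)
    5. motif1_beta3            35 ns  melt (beta 71% -> 0%)
    6. d2_s1                   50 ns  melt (beta 71% -> 0%)
    7. motif2_beta2            50 ns  melt (beta 71% -> 0%)
  most persistent aromatic pairs (%):
    32-39: 50.0
    18-25: 35.0
    4-18: 0.0
    4-25: 0.0
    4-32: 0.0
```

Reading it: the three scripted strands are recovered at exactly the scripted
times and in the scripted order (the `motif*` names are aliases of the
detached strand regions, so each detachment appears under both names; `N_td`
registers the partial beta loss of the whole domain). The native aromatic
pairs 32–39 and 18–25 stay in the 4.5–7.0 Å band until their host strands
detach at 50 and 35 ns — hence persistences of 50% and 35% of the 100 ns —
while pairs involving residue 4 sit outside the band from the start. The
whole-protein contact fraction decays to 0.70, and the apparent interdomain
motion is classified twist-dominant.

Real trajectories enter the same way: `read_trajectory("traj.pdb", dt = 0.25)`
for a multi-model PDB, `load_regions("regions.cfg")` (or the built-in HGDC
map, `default_regions()`, in author numbering: motif2_beta3 = 61–64,
motif1_beta3 = 33–38, ...), then `unfolding_analysis()` or
`run_pipeline()` for TSV reports with a checksummed manifest.

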