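---
title: "Methods: solute tempering and trajectory analysis in rest2tools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: solute tempering and trajectory analysis in rest2tools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rest2tools)
```

## The sampling problem

Intrinsically disordered peptides bound to large globular proteins are
hard to sample: the peptide needs aggressive enhanced sampling while the
receptor, which barely changes conformation, does not. Replica exchange
with solute tempering (REST2) solves this by running every replica at a
single bath temperature $T_0$ and instead deforming the potential. The
total energy is decomposed into a solute internal term $E_{pp}$, a
solute–solvent term $E_{pw}$ and a solvent–solvent term $E_{ww}$, and
replica $i$ runs on

$$E_i = \lambda_i E_{pp} + \lambda_i E_{pw} + E_{ww},
\qquad \lambda_i = T_0 / T_i^{\mathrm{eff}},$$

so only the solute is effectively heated, to $T^{\mathrm{eff}} =
T_0/\lambda$. `rest2tools` implements this machinery — ladder
construction, the deformed potential, Metropolis exchange and a
round-robin driver — together with the complete analysis pipeline for
the resulting trajectories, and a synthetic-trajectory generator with
planted ground truth against which every analysis stage is validated.

Two deliberate scope boundaries: there is no all-atom force field and no
MD integrator here. Propagation is Metropolis Monte Carlo on decomposable
toy Hamiltonians that honour the same energy-decomposition contract an MD
engine would provide, which is exactly what the exchange machinery needs
and nothing more.

## The replica-exchange engine

**Ladder.** Effective temperatures are spaced geometrically,
$T_i = T_0\,(T_{\max}/T_0)^{i/(n-1)}$, the standard choice that keeps
neighbouring overlap roughly constant. With $T_0 = 300$, $T_{\max} =
600$ K and $n = 16$, rungs 8 and 10 (0-based) fall at 434.2 K and
476.2 K after rounding.

**Exchange.** A swap between rungs $i$ and $j$ holding configurations
$x_i$, $x_j$ is accepted with probability
$\min\{1, e^{-\beta_0 \Delta}\}$, where
$\Delta = [E_i(x_j) + E_j(x_i)] - [E_i(x_i) + E_j(x_j)]$ and
$\beta_0 = 1/(k_B T_0)$. Because every replica shares the same $E_{ww}$
term, the solvent contributions cancel algebraically; the implementation
computes acceptance from the solute terms only, and a property test
checks the cancellation against the full deformed potentials with
randomised $E_{ww}$ to $10^{-12}$.

**Scaling convention.** Two couplings for the solute–solvent term
coexist in the literature: linear $\lambda E_{pw}$ and geometric
$\sqrt{\lambda}\,E_{pw}$. The `pw_exponent` argument exposes both
(default 1, i.e. linear). Nothing else in the package depends on the
choice; the cancellation property holds for either.

**Driver details.** Exchange attempts alternate between even pairs
(0–1, 2–3, …) and odd pairs (1–2, 3–4, …), the usual scheme when the
source of the ladder is silent on ordering. An accepted swap exchanges
the rung assignment (the $\lambda$), never the coordinates — equivalent
and cheaper. Occupancy is recorded every step; because each rung holds
exactly one replica at all times, the *column means* of the
replica-by-rung dwell-fraction matrix equal $1/n$ identically (6.25%
for 16 replicas). That conservation is the sanity anchor; the
*per-replica* spread around it is the informative mixing diagnostic,
along with the mean exchange acceptance and the round-trip count.

**Units.** Physical systems use $k_B = 0.0083144621$ kJ/mol/K
(`kB_kJ_mol_K`); the toy systems use reduced units with $k_B = 1$,
which removes unit bookkeeping from every test.

## The toy Hamiltonians

The bundled system is a bead-chain solute (harmonic bonds $k/2\,(r -
r_0)^2$ between consecutive beads, truncated unshifted Lennard-Jones
between non-bonded pairs) in a Lennard-Jones solvent bath, in a cubic
periodic box under the minimum-image convention. Defaults: 10 solute
beads, 100 solvent beads, box $10\sigma$, $k = 100\,\epsilon/\sigma^2$,
$r_0 = \sigma$, LJ cutoff $2.5\sigma$, displacement moves of up to
$0.1\sigma$. The LJ potential is truncated rather than shifted because
Monte Carlo only ever uses energy differences of a fixed Hamiltonian;
the discontinuity at the cutoff is irrelevant there. Moves are
single-bead displacements only — correctness over speed at desk scale.
Solute moves are accepted on the $\lambda$-scaled $E_{pp}$ and $E_{pw}$
changes; solvent moves see the scaled $E_{pw}$ plus unscaled $E_{ww}$.
The energy decomposition is cached and updated incrementally in compiled
code; a test drives many sweeps and checks the cache against a
from-scratch recomputation to $10^{-9}$.

The headline physical check uses a 1-dimensional two-bead chain
(`dim = 1`, no solvent): equipartition gives
$\mathrm{var}(r) = k_B (T_0/\lambda)/k$, so the sampled bond-length
variance must grow linearly in $1/\lambda$ — the operational meaning of
"heating the solute". The suite samples $10^5$ sweeps per rung (after a
2000-sweep burn-in, recording every 5th sweep, move size $0.35\sigma$
to keep autocorrelation short) and requires agreement within 5% at
$\lambda \in \{1, 0.75, 0.5\}$. The one-dimensional chain is used
because in 3D the bond-length Jacobian biases $\mathrm{var}(r)$ at the
percent level, which would blur an otherwise exact closed form.

## Secondary structure

Assignment follows the Kabsch–Sander scheme. The backbone amide
hydrogen is reconstructed as $H = N + \widehat{C_{i-1} - O_{i-1}}$
(1.0 Å bond; the first residue is never a donor), and the hydrogen-bond
energy is

$$E = 0.084 \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}}
 - \frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right) \cdot 332
 \ \mathrm{kcal/mol},$$

with a bond when $E < -0.5$. Bridges between residues at least 3 apart
follow the antiparallel/parallel patterns; adjacent bridges of one type
form ladders (label E), isolated bridges B, two consecutive
$i \to i+4$ turns give helix H, isolated 3/4/5-turns give T, and a
C$^\alpha$ bend over 70° gives S, with priority
E > B > H > T > S > C. Residues with incomplete backbone geometry are
assigned C rather than erroring. The 3₁₀/α/π distinction is collapsed
into the single helix class because every consumer in this package
reports one helix content.

Reported β-sheet content counts label E only; B is reported separately.
Whether a published "β-sheet" fraction included isolated bridges is
often unknowable, so `include_bridge = TRUE` is available on the
profile and histogram functions.

## Clustering

**Superposition** is the Kabsch SVD solution with the determinant
correction enforcing a proper rotation; degenerate (collinear)
selections error. A test pits it against a brute-force rotation-grid
search (coarse 40³ grid plus local refinement) on 4-point toys at
$10^{-3}$ Å.

**Conformational clustering** is the iterative neighbour-count
algorithm: the frame with the most neighbours within the RMSD cutoff
(default 2 Å = 0.2 nm, pairwise superposed on the backbone selection)
becomes a centre, its neighbourhood is removed, repeat. Ties in
neighbour count go to the lowest frame index, which makes the result
deterministic and matches the stable behaviour of common
implementations.

**Pose clustering.** Each frame is superposed onto a reference
structure on the receptor backbone, the transform is applied to the
whole frame, and the ligand centre of mass becomes the pose point
(mass-weighted by default; whether a published centre of mass was
mass-weighted or geometric is usually unstated, so `weighted = FALSE`
is a flag). Points are partitioned by DBSCAN with `eps = 3` Å and
`min_samples = 20` — declared defaults, not inferred ones, exposed in
the interface. DBSCAN's documented border-point ambiguity is fixed
deterministically: a border point belongs to the first cluster whose
core reaches it in scan order. Tests compare partitions against a naive
density-reachability oracle up to label permutation, on core and noise
points where the algorithm is unambiguous.

## Contacts, salt bridges, hydrogen bonds, regions

* **Contact**: two residues are in contact when any two heavy atoms lie
  within 5.4 Å. Contact maps keep sequence neighbours (consumers may
  mask them); the diagonal is 1 by convention. Probabilities are
  fractions over *all* frames — "percentage of snapshots" — not over
  bound frames only.
* **Binding propensity**: per residue, the fraction of frames with at
  least one heavy-atom contact to the partner chain, reported for both
  molecules with the molecule-wide mean alongside.
* **Salt bridge**: side-chain oxygen of an acidic residue (D/E) within
  4 Å of a side-chain nitrogen of a basic residue (K/R). Histidine is
  treated as neutral at pH 7 and never participates. Chain termini can
  be admitted as charged groups behind `include_termini` (default off):
  a reported terminal bridge is ambiguous between side chain and
  terminus, so the conservative reading is the default.
* **Hydrogen bond**: donor–acceptor heavy-atom distance ≤ 3.5 Å and
  H–donor–acceptor angle ≤ 30°, the defaults of the major MD analysis
  tools; on reduced topologies the backbone amide H is reconstructed as
  in the secondary-structure module and H-less side-chain tips are
  skipped.
* **Conserved β-regions**: a residue qualifies when it forms a β-strand
  in at least `region_min_clusters` (default 3, "more than 2") cluster
  representatives, pooling several systems when a list of flag matrices
  is given. Maximal runs of qualifying residues become regions β1, β2,
  … N→C. Single-residue gaps are bridged *only when the gap residue is
  a strand residue in at least one cluster*; a residue never seen in a
  strand always splits. The conditional rule is the design decision
  that reconciles two facts: long regions (e.g. spanning residues
  15–24) must survive single-residue breaks in individual cluster
  profiles, while the one-residue gaps at positions like 14 and 37 of
  the 42-mer separate genuinely distinct regions and must not be
  bridged. An unconditional merge cannot satisfy both.
* **Sheet associations**: two regions are associated in a frame when at
  least two Kabsch–Sander backbone H-bonds connect E-labelled residues
  of one to E-labelled residues of the other. The two-bond threshold is
  this package's quantitative reading of qualitative "connected by
  hydrogen bonding" descriptions; one bond is too easily a geometric
  accident.
* **RMSF**: per-residue C$^\alpha$ fluctuation about the mean structure
  after superposing every frame on a reference selection.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. It emulates
the study conditions the analyses are meant for: a 42-residue disordered
peptide (default sequence = the amyloid-β 42-mer, whose N-terminal 16
residues carry 6 charged residues and 3 histidines) interacting with a
rigid multi-domain receptor, represented as three spherical lobes of
reduced residues — rigid because a large globular receptor moves little
on the timescale of peptide conformational exchange. Topologies are
reduced to N, CA, C, O plus one side-chain tip per residue (oxygen-like
for acidic, nitrogen-like for basic), which supports every analysis in
the package without rotamer machinery.

Per frame, independently:

* **Hairpins.** With configured probability, strand ranges (default
  residues 17–23 paired antiparallel with 30–36, probability 0.5) are
  realised from an ideal antiparallel template: 3.4 Å rise, 4.75 Å
  strand separation, alternating carbonyl orientation, giving
  cross-strand O···N distances near 2.9 Å and Kabsch–Sander energies
  around −2.8 kcal/mol — far below the −0.5 threshold, so assignment
  survives the default 0.05 Å coordinate noise with margin. Loop and
  tail residues are laid along circular arcs with ~3.4 Å spacing and
  carbonyls pointing out of the sheet plane, so they cannot form bridge
  ladders; frames without any hairpin are genuine random coils built
  from backbone dihedrals sampled outside the β basin. Every frame is
  audited by running the assignment on the emitted coordinates; a coil
  that accidentally forms a bridge is resampled, and a frame that
  cannot realise its planted labels aborts generation loudly.
* **Poses.** The peptide is randomly oriented and its centre of mass
  placed at one of the configured sites (default three sites ≥ 50 Å
  apart, weights 0.40/0.35/0.25, positional σ = 1 Å) or, with
  probability 0.1, unbound — at least 20 Å from every receptor atom,
  which is unambiguous against the 5.4 Å contact cutoff.
* **Salt bridges.** Listed pairs (default ligand residue 28 to an
  acidic receptor residue, probability 0.8 in bound frames) are forced
  by placing the ligand side-chain tip 3.2 Å from the receptor tip,
  then audited against the 4 Å predicate.
* **Rigid motion.** The whole complex receives a random rotation and
  translation, so every analysis that claims superposition invariance
  actually has to earn it.

Ground truth records the per-frame per-residue β labels, pose-site id
(NA for unbound), the planted salt-bridge list, and the full
ligand–receptor residue contact set computed by an independent
block-matrix route over the atom distance matrix. Generation is bitwise
reproducible from the seed.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: no excluded volume or physical loop
closure (connector residues may be stretched), no side-chain rotamers,
no solvent, no force-field energetics, a receptor with synthetic fold
and sequence, and conformational diversity far below a real disordered
ensemble. Recovery results on these ensembles validate the *statistics*
(the estimators and their calibration), not force-field realism.

## Numerical choices and degenerate inputs

* Internal residue indexing is 0-based; user-facing tables are 1-based
  with one-letter labels (D1…A42).
* Masses come from a fixed element table; an unknown element errors
  rather than silently weighing 0.
* Empty atom selections error ("never silent empty analytics").
* PDB I/O is fixed-column with MODEL/ENDMDL; coordinates round-trip at
  the format's 0.001 Å precision, and inconsistent model sizes or
  unparseable records fail with the offending model/line.
* Pipeline stages draw from RNG streams derived from the global seed by
  a stable string hash of the stage name, so inserting a stage never
  perturbs the others; all derived seeds stay below $2^{31}$.
* Problem sizes in the shipped validation: $10^4$ driver steps for the
  dwell check, $10^5$ sweeps per rung for equipartition, 1000 synthetic
  frames for recovery statistics, ≤ 200-point instances for the
  clustering oracles — sizes at which the binomial error bars used in
  the assertions are tight enough to be meaningful.

## Known limitations

The replica-exchange driver is single-process and round-robin; it is a
reference implementation for testing exchange statistics, not an HPC
engine. The secondary-structure module implements the sheet/helix/turn
/bend core of the Kabsch–Sander algorithm, not the full ladder/sheet
bookkeeping of the original program (no PP-II, no π-helix distinction in
reports, bends only via the 70° rule). Force-field interaction energies
between molecules are out of scope; the toy Hamiltonians provide
decomposable energies for the exchange machinery instead.
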