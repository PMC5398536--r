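---
title: "Methods: coevolution-guided docking of protein heterocomplexes"
author: "coevodock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coevolution-guided docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`coevodock` models a two-chain protein complex from the residue coevolution
of a single domain family. It chains together four stages:

1. **Mean-field direct coupling analysis (DCA)** of the family alignment —
   identity-based sequence reweighting, pseudocounted frequency estimation,
   coupling inference by inversion of the column-pair covariance matrix, and
   direct-information (DI) scoring of every column pair.
2. **Exclusion filtering** — coupled pairs explained by the monomeric fold,
   by solvent burial, or by a known homodimer interface are removed; the
   top-K survivors are the predicted heterocomplex contacts.
3. **Restrained docking** — the two protomers, each held near its crystal
   geometry by a C-alpha structure-based (Go-type) model, are assembled by
   simulated-annealing Langevin dynamics under coupling-derived distance
   restraints plus one metal-cluster proximity restraint; a replica ensemble
   is run and the model with fewest steric clashes is kept.
4. **Evaluation** — per-pair minimum distances, restraint satisfaction, the
   inter-cluster distance, clash audit, and an interface-connectivity score.

A synthetic-data layer generates every input with known ground truth: Potts
alignments with planted couplings, and toy two-chain bead complexes with a
designed interface and ligand sites. The flagship integration run
(`run_pipeline()` on a synthetic config) exercises all four stages and checks
that the designed geometry is recovered.

# The statistical model

Alignment columns are modeled by a q-state Potts distribution
$P(\sigma) \propto \exp\big(\sum_i h_i(\sigma_i) + \sum_{i<j}
e_{ij}(\sigma_i,\sigma_j)\big)$. DCA inverts this model to separate direct
couplings from transitive correlation.

**Reweighting.** Sequence $m$ receives weight $1/n_m$ with $n_m$ the number
of sequences at identity $\ge x$ to it (itself included); $M_\mathrm{eff} =
\sum_m w_m$. Default $x = 0.8$, the customary choice; identity is counted
over all columns, gaps comparing like ordinary states.

**Frequencies.** With pseudocount $\lambda$,
$f_i(A) = \big(\lambda/q + \sum_m w_m\,\delta_{A^m_i,A}\big) /
(\lambda + M_\mathrm{eff})$, pair frequencies analogously with
$\lambda/q^2$. Default $\lambda = M_\mathrm{eff}$, the canonical mean-field
setting; both $x$ and $\lambda$ are arguments. The identities
$\sum_A f_i(A) = 1$, $\sum_{AB} f_{ij}(A,B) = 1$, and
$\sum_B f_{ij}(A,B) = f_i(A)$ hold to $10^{-12}$ and are asserted in tests.

**Couplings.** The covariance matrix $C_{ij}(A,B) = f_{ij}(A,B) -
f_i(A)f_j(B)$, restricted to the first $q-1$ states of each column (the last
state — the gap for family alignments — is the gauge reference), is inverted:
$e_{ij}(A,B) = -(C^{-1})_{ij}(A,B)$. A positive pseudocount guarantees
invertibility; at $\lambda = 0$ a degenerate alignment raises a conditioning
error advising $\lambda > 0$. Coupling norms for ranking diagnostics are
reported in the zero-sum gauge.

**Direct information.** For a pair $(i,j)$ the two-site direct distribution
is $P^{dir}(A,B) \propto e^{e_{ij}(A,B)}\,\mu_i(A)\,\mu_j(B)$, with the
single-site factors fixed by requiring the marginals of $P^{dir}$ to equal
$f_i, f_j$. The fixed point is found by damped iteration (damping 0.5,
tolerance $10^{-6}$, at most 500 sweeps; non-convergence is an error carrying
the residual). $DI_{ij}$ is the mutual information of $P^{dir}$ against
$f_i \otimes f_j$; it is non-negative and vanishes when the pair factorizes.
The test suite checks DI against an independent oracle — iterative
proportional fitting of $\exp(e_{ij})$ to the marginals — on every
enumerable two-column alignment with $q \le 3$ and $M = 6$ (about 3000
systems), agreeing to $<10^{-6}$.

**Ranking.** Pairs with $|i-j|$ below a separation floor (default 5) are
dropped as trivially sequence-local; survivors are sorted by DI descending,
ties broken lexicographically. No average-product correction is applied: the
protocol ranks raw DI.

# Exclusion filtering

Because both interaction partners belong to the same domain family, a
coupling between columns $(i,j)$ is evidence for *some* residue contact, not
specifically an inter-protein one. Three exclusion tests remove pairs already
explained:

* **monomeric fold** — $(i,j)$ maps onto an intrachain contact of either
  monomer (heavy-atom minimum distance $\le 5$ Å, sequence separation
  $\ge 5$; cutoffs are arguments, chosen tight so only genuinely
  fold-explained couplings are removed);
* **burial** — relative solvent accessibility (Shrake–Rupley sphere sampling,
  probe 1.4 Å, 240 points/atom, normalized by Tien-style Gly-X-Gly maxima)
  below 0.05 on every available orientation — a deliberately permissive
  exposure threshold;
* **homodimer interface** — $(i,j)$ maps onto a cross-chain contact of a
  user-declared crystal homodimer assembly of either protein.

Orientation ambiguity is retained: a surviving column pair is carried in both
orientations (column $i$ on chain 1 with $j$ on chain 2, and vice versa)
whenever both ends map. The family alignment cannot distinguish the two, so
both enter the restraint set. Every excluded pair is recorded in an audit
table with its reasons; filtering is order-preserving and idempotent, and
raising the exposure threshold can only shrink the survivor set (tested).

The default K is 20 candidate pairs for family-scale runs. In the synthetic
flagship configuration K equals the number of planted interface couplings
(4 unique column pairs for the default 8 designed contacts), since the ground
truth is known by construction.

# Restrained docking

**Structure-based model.** One bead per C-alpha. Harmonic virtual bonds
($k_b = 200\,\varepsilon/\mathrm{Å}^2$) and angles ($k_a =
40\,\varepsilon/\mathrm{rad}^2$) at native values; native dihedrals with the
usual one- and three-fold terms ($k_d = 3\,\varepsilon$); native contacts
(heavy-atom distance $\le 4.5$ Å when all-atom coordinates exist, C-alpha
$\le 8$ Å otherwise, separation $\ge 3$) as 12-10 wells of depth
$\varepsilon = 1$ at the native C-alpha distance; all remaining pairs repel
as $(4\,\mathrm{Å}/r)^{12}$. Energies are in units of the contact depth. The
dihedral stiffness is higher than the classic all-helix parameterization on
purpose: with a single bead per residue the torsions are the only terms that
encode chirality, and $k_d = 3$ keeps a 30-bead model folded ($Q \approx
0.96$) at the hottest point of the annealing schedule, where $k_d = 1$ lets
it melt and occasionally refold through near-mirror intermediates. A
consecutive C-alpha gap over 4.5 Å is rejected as a chain break. The native
structure is verified (by test) to sit at the model's minimum: local FIRE
minimization from the native coordinates ends with maximum force below
$10^{-6}$.

**Restraints.** Each candidate orientation becomes one inter-chain restraint
between C-alpha beads with three pieces:

* a *flat bottom* below $r_{couple} = 10$ Å — the satisfaction criterion,
  motivated by the observation that most true coupling distances fall within
  10 Å;
* a harmonic wall above it ($k = 1\,\varepsilon/\mathrm{Å}^2$) that switches
  to *linear* beyond 2 Å of violation, capping the pulling force at
  $2\,\varepsilon/$Å. Uncapped harmonic walls at the 75 Å starting
  separation exert forces of order $60\,\varepsilon/$Å and mechanically
  unfold the monomers during the approach; the capped form reels the chains
  in gently (this is the standard harmonic-then-linear distance-restraint
  shape used by MD engines);
* a shallow Gaussian well (depth 1, minimum 8 Å, width 2 Å) that localizes
  the pair at a typical residue-contact distance once the chains are close.
  A pure flat bottom leaves no force inside 10 Å, and we measured the
  consequence: every replica satisfied all restraints yet interface RMSD
  ranged 5–14 Å across the ensemble, because the satisfied set is a wide
  rigid-body manifold. Treating each coupling as an attractive predicted
  contact — as coevolution-guided docking protocols do — removes that
  degeneracy.

One additional harmonic restraint (same capped shape, $k_c = 1$) holds the
distance between the two *ligand sites* — each the centroid of the C-alpha
positions of the cluster-coordinating residues (3 Cys + 1 His for a 2Fe-2S
site) — at $r_{cluster} = 12$ Å, the distance range reported to permit
iron–sulfur cluster transfer between proteins.

**Protocol.** Chain B is placed 75 Å from chain A (center of mass, exact) in
a seed-determined random orientation with no inter-chain contacts. BAOAB
Langevin dynamics (timestep $5\times10^{-4}$, friction 1, in reduced units)
runs for $2\times10^5$ steps while the temperature ramps linearly from
$T^* = 1.2$ to $0.2$ and the restraint coupling ramps linearly from 0 to 1.
The slow-growth ramp is deliberate: with full-strength restraints from step
one, the chains dock while still hot and partially unfolded and then trap;
ramping ties the encounter to the cold half of the schedule. After the ramp,
FIRE minimization polishes the structure. Ten independent replicas
(consecutive seeds) are run; the model with fewest inter-chain C-alpha pairs
closer than 3.8 Å (one virtual bond — the clash criterion) is selected, ties
broken by lower restraint-violation energy, then lower seed. All randomness
passes through R's RNG, so a seed fixes the trajectory bit-for-bit.

# Evaluation

The evaluation report contains: the inter-cluster (ligand-site centroid)
distance; the fraction of candidate pairs whose model distance is within
10 Å (the "minimum distance" convention of the candidate table); the clash
count; the restraint-satisfaction fraction (distance at most the flat-bottom
bound plus a 2 Å tolerance band); and a single-interface score — the
fraction of satisfied pairs inside the largest connected component when
pairs are linked whenever their chain-A residues are within 15 Å. The 15 Å
connectivity radius operationalizes the qualitative notion of "a single
interface". Interface RMSD against a reference complex superposes the model
on the chain-A C-alphas (Kabsch) and measures RMSD over the residues named
in the reference contact list. Reports are recomputable from the written
two-chain PDB file to within its 3-decimal coordinate precision.

# Synthetic ground truth

**Potts alignments.** `sample_potts_msa()` Gibbs-samples
$P(s)\propto\exp(\sum h + \sum J\,\delta_{s_i s_j})$ with matching-state
couplings planted on chosen site pairs; burn-in $100L$ sweeps, thinning 10
sweeps per emitted sequence. The sampler is validated against exact
enumeration (27-state system, total variation $< 0.01$ at $M = 10^5$) and,
for disjoint planted pairs, against exact i.i.d. sampling (the joint then
factorizes). The default recovery benchmark — $L=30$, $q=8$, $M=2000$, 15
disjoint pairs at strength 1.0 — is recovered by the DCA stage with top-15
PPV of 1.0 across seeds. The corresponding null alignments put the largest
DI at roughly 13–16% of the planted-pair median: a noise floor of the
mean-field estimator at this depth (insensitive to the pseudocount and
identical under exact sampling), worth knowing when interpreting weak
couplings on real families.

**Toy complexes.** `make_toy_complex()` builds one compact self-avoiding
bead chain (3.8 Å bonds, protein-like pseudo-angles, anisotropic collapse
into a prolate globule so the dimer interface is an extended seam rather
than a single patch) and poses a second copy as its 180°-rotation about an
axis perpendicular to the packing direction. The two-fold symmetry makes the
designed contact set orientation-symmetric — $d(A_i,B_j) = d(A_j,B_i)$
exactly — mirroring the orientation ambiguity of couplings within one
family. Designed contacts are chosen from cross-chain pairs at 6–8 Å with
column separation $\ge 5$, by greedy max–min dispersion so they span the
seam (clustered anchors act as a hinge and leave the pose underdetermined).
The ligand sites are a four-residue window whose centroids realize the
design distance (default 12 Å) exactly after a small refinement of the
packing separation; infeasible designs error out after bounded attempts.
The alignment for the flagship run plants couplings exactly at the designed
contact columns, with the toy chains' sequences set to the alignment
consensus so that column-to-residue mapping is exercised end to end.

What the toy ground truth does *not* emulate: phylogenetic correlation
between sequences (samples are i.i.d.; reweighting is still exercised via
the identity threshold), gaps, side-chain packing, and any conformational
change on binding. Passing the synthetic benchmarks therefore demonstrates
the machinery is correct and internally consistent, not that a particular
real family will yield a correct complex.

# Study sizes and numerical choices

The synthetic flagship uses $M = 1130$ sequences — the depth of the
zf-CDGSH (PF09360) family alignment that motivates the pipeline — with
$q = 8$ and $L = 30$ to keep the covariance inversion small; planted
coupling strength is 1.0, matching the recovery benchmark. Docking runs 10
replicas of $2\times10^5$ steps. The full test suite runs in ~6 minutes on
one CPU; the acceptance script in ~4 minutes.

Degenerate inputs are handled explicitly: empty alignments, ragged records,
all-gap columns (consensus 'X', effectively unmappable), chains lacking
C-alphas, singular covariance at $\lambda = 0$, non-convergent DI fixed
points, restraints referencing unmapped residues (skipped with a warning),
failed replicas (recorded; the ensemble errors only if all fail), and
infeasible toy designs. Determinism is part of the contract: identical
configs and seeds give byte-identical artifacts, which the tests assert by
hashing.

# Known limitations

* The docking stage keeps the monomers flexible under their structure-based
  models; a rigid-body mode is not provided. With the restraint force caps
  and the coupling ramp, flexibility did not harm pose recovery, and a
  rigid mode would have duplicated the integrator.
* Model selection follows the fewest-clashes rule; with zero clashes across
  most replicas the restraint-violation tie-break decides, which favors
  well-satisfied but occasionally imperfectly folded poses (observed as
  ~1 in 5 selected toy models landing above the 3 Å interface-RMSD mark).
* All-atom refinement of the selected C-alpha model is out of scope; the
  evaluation stage reports the C-alpha geometry only.
* The mean-field null DI floor at moderate alignment depth is ~13% of a
  strength-1.0 planted signal (see above); raw-DI ranking inherits it.
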