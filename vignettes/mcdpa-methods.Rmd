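---
title: "Dynamics-perturbation prediction of ligand-binding regions in protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics-perturbation prediction of ligand-binding regions in protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdpa)
```

## The model

mcdpa scores candidate binding regions by how strongly a fixed surface
test point ("probe") perturbs a protein's equilibrium conformational
ensemble. The ensemble comes from a coarse-grained anisotropic elastic
network: one node per residue at the Cα position, Hookean springs of
force constant $\gamma$ between all node pairs within a contact cutoff,
rest lengths equal to the build-time distances. The energy is quadratic,
so near the native state the conformational distribution is a zero-mean
Gaussian over the $3N$ Cartesian displacements with precision matrix
$H$, the Hessian of the spring energy. Six eigenvalues of $H$ vanish for
a connected network (rigid-body translations and rotations); all
statistics live on the $r = 3N - 6$ dimensional internal subspace.

A protein–protein complex is modeled by the same network plus an
interface term

$$V_{AB} = \tfrac12 \sum_{i \in A,\ j \in B} \gamma_{AB}
  \,(r_{ij} - r^0_{ij})^2$$

over cross-chain node pairs within the cutoff. Setting
$\gamma_{AB}=\gamma$ makes interface contacts as stiff as intra-protein
ones and is exactly equivalent to building one network over the union of
chains (`couple_chains()` reproduces the merged Hessian bit for bit);
$\gamma_{AB}$ can be lowered to model weaker interactions, and
$\gamma_{AB}=0$ decouples the chains: the Hessian becomes block
diagonal, the rigid-mode count rises to 6 per chain, and every probe
score is provably the *sum* of the scores the probe would receive on
each monomer network alone. That additivity is what "the complex behaves
like its monomers" means operationally, and it is asserted numerically
in the test suite.

## Probe scoring

Probes are laid out in layers (defaults 4 and 6 Å) around the nodes: for
each layer offset $d$, candidates are sampled on spheres of radius $d$
from a seeded generator, kept only if their *nearest-node* distance is
within 0.5 Å of $d$ (a candidate inside the body always has a closer
node, so this rejects buried points without any molecular-surface
machinery), and thinned greedily to a minimum spacing of 2 Å in
candidate order. Generation is a pure function of (nodes, seed).

A probe at position $s$ attaches a spring of constant $\gamma_s$ to
every node within the interaction radius $r_\mathrm{int}$ (default 6 Å,
chosen so that probes in the 4–6 Å layers engage first-shell nodes).
The probe is held fixed and its springs are at equilibrium at build
time, so the perturbation adds no degrees of freedom and shifts no mean;
it only stiffens the Hessian by
$\Delta H = \gamma_s \sum_k \hat d_k \hat d_k^{\mathsf T}$ on the
attached nodes' diagonal blocks ($\hat d_k$ the unit vector from probe
to node $k$). The score is the Kullback–Leibler divergence of the
perturbed from the unperturbed Gaussian, both projected on the
unperturbed internal subspace:

$$D_x = \tfrac12\left[\operatorname{tr}(\tilde H \tilde H'^{-1}) - r
 + \ln\frac{\det \tilde H'}{\det \tilde H}\right], \qquad
 \tilde H' = \tilde H + P^{\mathsf T}\Delta H P .$$

Three choices here were genuinely open and are fixed as follows:

* **KL direction.** $D_x$ = KL(perturbed ‖ unperturbed): the score
  measures the change the probe induces *relative to the native
  ensemble*. The direction is recorded in every run's configuration
  (`kl_direction`).
* **Fixed probe.** A mobile probe would add 3 degrees of freedom and a
  mean-shift term; the fixed-probe model is the simplest one in which
  $D_x$ is a pure function of the stiffness change, and it keeps the
  convenient identity $D_x = \tfrac12\sum_i [\ln(1+g_i) - g_i/(1+g_i)]$
  over the eigenvalues $g_i \ge 0$ of the $m \times m$ core
  $G = W^{\mathsf T}\Lambda^{-1}W$ ($W$ the projected low-rank factor,
  $m$ = number of attached nodes). This low-rank path is what
  `score_all()` uses; a dense evaluation of the projected formula is
  kept as a cross-check and the two agree to $10^{-8}$ relative on all
  test systems.
* **Zero modes.** Both matrices are projected on the *unperturbed*
  non-rigid subspace even though $\Delta H$ breaks translational
  invariance; this keeps all scores finite and mutually comparable.

Because $D_x$ depends only on force-constant ratios, jointly rescaling
$(\gamma, \gamma_{AB}, \gamma_s)$ leaves every score unchanged —
temperature and energy units drop out, so scores are reported in nats
with no unit ambiguity. The quantile-based selection rule inherits this
scale freedom.

## From scores to predictions

Probes at or above the top-10% $D_x$ quantile (ties included, so the
rule is deterministic) are grouped by single-linkage connected
components at 3.5 Å — the same cutoff used for overlap evaluation, so
one spatial scale governs both. Components smaller than 5 probes are
discarded as noise. Clusters are ranked by mean $\bar D_x$ (ties: larger
first, then lexicographic centroid) and labeled O, P, Q, … — primed
when the prediction came from a complex. The selection fraction,
linkage cutoff and minimum size are configuration with logged defaults;
none of them is stated by the underlying method description, and the
quantile rule was preferred to an absolute threshold precisely because
of the rescaling invariance above.

## Evaluation and change taxonomies

Precision and recall use strict inequalities,
$c=\{s_i \in C: d(s_i,L) < r_\mathrm{cutoff}\}$,
$l=\{l_i \in L: d(l_i,C) < r_\mathrm{cutoff}\}$, $P=|c|/|C|$,
$R=|l|/|L|$, with $r_\mathrm{cutoff}=3.5$ Å by default. Per ligand, the
reported prediction is the cluster maximizing recall (ties: precision,
then label order), plus a hit flag (at least one covered ligand atom).

Comparing monomer-based and complex-based cluster sets requires the
shared protein to be superposed first (Kabsch, correspondence by
chain-agnostic residue number). Overlap fractions are computed both ways
for every cluster pair; a link exists when either fraction reaches 0.2,
and a 1–1 link counts as *unchanged* when both fractions reach 0.5
(*shifted* otherwise); 1–many is *split*, many–1 *merged*, isolated
clusters *vanished*/*created*. The two numeric thresholds are design
choices — the taxonomy itself has no published numeric rule — and
many–many components are decomposed greedily by descending link
strength into star components so that every cluster lands in exactly
one change record. Ligand inventories are matched by residue name and
centroid proximity (8 Å) after superposition; matched same-size pairs
are classified by ARMSD against the 1 Å convention (unchanged below,
shifted above), one-sided presence gives disappeared/new-ligand, and a
change in the number of covalently linked residue units (oligomer
merging as in poly-NAG glycans, threshold 1.9 Å between hetero
residues) gives fused/split.

ARMSD itself pairs ligand atoms by PDB atom name within residue units
matched in order; unmatched atoms are excluded and listed, and
chemically different ligands fall back to the distance between centers
of mass.

## Synthetic fixtures and what they do (not) show

All tests run without downloads on two generated structure families
(CA-only pseudo-proteins, deterministic under seed, written as valid
PDB):

* **Pocket cage** — a solid quasi-uniform ball (concentric Fibonacci
  shells 4 Å apart, surface spacing ≈ 4 Å at the default 200 surface
  nodes and 16 Å radius, 5% angular jitter) with a cylindrical channel
  pocket of depth 7 Å and mouth radius 5.5 Å carved into the +z
  surface. The mouth radius is chosen so that both probe layers fit
  inside the channel; with a much narrower mouth the pocket holds too
  few probes to clear the minimum cluster size, which tests sampling
  density rather than discrimination. The ground truth `pocket_center`
  is the midpoint of the channel axis. Optionally a 5-atom rigid ligand
  is planted there (`with_ligand`).
* **Two-chain complex** — two shells labeled A and B with a 4 Å
  interface gap (≥ 10 cross pairs within the cutoff) and an optional
  planted ligand at the interface midpoint or at a distal site. The
  interface gap is deliberately too narrow to host probes, so this
  fixture exercises coupling semantics, superposition, ARMSD and the
  evaluation plumbing — not interface-pocket discovery.

These fixtures establish that the machinery is correct (KL values match
closed forms and Monte-Carlo sampling; coupling and decoupling behave
exactly; metrics match brute-force counting) and that the core
discriminative claim holds at toy scale: pocket-adjacent probes out-
score convex-face probes (pooled one-sided Wilcoxon rank test across ten
seeded fixtures), and the top-ranked cluster lands within 5 Å of the
planted pocket center in at least 8 of 10 seeds. They do *not* show
performance on real proteins: pseudo-residue lattices have none of the
packing heterogeneity, secondary-structure anisotropy, shallow grooves
or chemical specificity of crystal structures, and no claim about
benchmark precision/recall on PDB entries follows from green tests here.
Runs on real structures require user-supplied PDB files (the package
never downloads).

## Numerical choices

* Rigid modes are identified by magnitude (below $10^{-8}$ of the
  largest eigenvalue) and *verified*: the detected count must equal 6
  per rigid body (connected component of the spring graph), and the
  near-zero eigenvectors must span the analytic translation/rotation
  generators (minimum principal overlap 0.99). A mismatch is a hard
  error, because silently miscounted zero modes corrupt every
  pseudo-determinant downstream.
* Alternate locations: highest occupancy wins, ties to first in file.
  Residues without a Cα are dropped with a warning.
* Dense eigendecomposition is used throughout; fixture sizes were chosen
  at a few hundred nodes ($3N \lesssim 1200$), where one
  decomposition takes a second or two and each probe afterwards costs
  only an $m \times m$ eigenproblem ($m \le$ a dozen attached nodes).
  The Monte-Carlo oracle uses $2\times10^5$ samples per network on 5–15
  node networks.
* Degenerate inputs fail loudly with classed errors: disconnected
  networks (component sizes named), fewer than 3 or collinear
  superposition pairs, empty clusters in precision, no ligands on
  either side of a comparison.

## Known limitations

* Cα resolution and a single cutoff ignore side-chain packing;
  shallow, wide sites perturb the ensemble weakly and are the method's
  known blind spot (carbohydrate sites especially).
* The probe model is purely elastic — no chemistry, no desolvation — so
  scores rank geometry-dynamics coupling, not affinity.
* Superposition correspondence is by residue number, not sequence
  alignment; renumbered chains need an explicit correspondence.
* `gamma_AB` is a single scalar per interface; heterogeneous interface
  stiffness is out of scope.
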