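---
title: "From sequence covariation to coarse-grained folds: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sequence covariation to coarse-grained folds: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dcafold)
```

This vignette is the package's account of its science: the statistical
model, the geometry, the tunable parameters, and the choices made where
the design was genuinely open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## 1. The inverse Potts model and its mean-field solution

A multiple sequence alignment of a protein family is treated as a sample
from a maximum-entropy distribution over sequences constrained to match
the observed single-column frequencies $f_i(A)$ and pair frequencies
$f_{ij}(A,B)$, with each position in one of $q = 21$ states (20 amino
acids and gap):

$$P(A_1 \dots A_L) \;=\; \frac{1}{Z}\,
\exp\Big(\sum_{i<j} e_{ij}(A_i,A_j) + \sum_i h_i(A_i)\Big).$$

The partition function $Z$ is never evaluated — it is intractable, and the
mean-field route does not need it. To first order in the couplings, the
solution is

$$e_{ij}(A,B) = -\big(C^{-1}\big)_{ij}(A,B), \qquad
C_{ij}(A,B) = f_{ij}(A,B) - f_i(A)\,f_j(B),$$

with all quantities restricted to the first $q-1$ states. Dropping the gap
state both fixes the gauge (all stored couplings involving state $q$ are
exactly zero, the "zero-gap" gauge) and makes $C$ invertible for any
positive pseudocount. The diagonal blocks of $C$ are set to the
single-site covariances $f_i(A)[A{=}B] - f_i(A)f_i(B)$, the convention
under which the inversion is well posed.

**Why a global model.** Plain mutual information scores every pair in
isolation, so a position B in contact with both A and C induces an
apparent A–C signal (transitive correlation) that MI cannot distinguish
from a real contact. Inverting the full covariance matrix redistributes
that shared signal onto the direct pairs. The test suite checks this on a
chain-topology model small enough to enumerate exactly ($q^L = 243$
states): planted pairs dominate the DI ranking while the transitive pair
A–C scores orders of magnitude lower, yet its MI remains clearly above the
null median.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `theta` | 0.7 | identity fraction | neighbourhood radius for sequence down-weighting; "≥ 70 % identical" is counted inclusively, over all columns, gap–gap counting as a match (both switchable) |
| `lambda` | `meff` | pseudocount mass | uniform prior mass entering as $\lambda/q$ and $\lambda/q^2$; the equal-weight default is the standard mean-field choice and guarantees invertibility |
| `mi_lambda` | 0 | pseudocount mass | the MI baseline uses raw weighted frequencies by default |
| `tol`, `max_iter` | 1e-4, 500 | — | pair-field fixed point (below) |

Sequence weighting is $w_s = 1/\#\{t : \mathrm{id}(s,t) \ge \theta\}$ and
$M_\mathrm{eff} = \sum_s w_s$; whether identity should be computed over
gapped columns is not settled usage, so it is a documented option
(`include_gaps`), on by default.

### Direct information

For each pair, a two-site distribution
$P^{Dir}(A,B) \propto \exp(e_{ij}(A,B) + \tilde h_i(A) + \tilde h_j(B))$
is built whose fields are iterated — alternating multiplicative
marginal-matching updates, a fixed point reached in a few dozen iterations
— until both marginals match $f_i, f_j$ to `tol` (1e-4 on the max
deviation; every converged pair's residual is checked in the tests). DI is
the Kullback–Leibler divergence of $P^{Dir}$ from the product of its
marginals, in nats, clipped at zero below $-10^{-10}$.

A consequence of the pseudocount worth knowing: a *fully conserved*
alignment does not give DI = 0 — the 50/50 data/prior mixture makes pair
frequencies differ from products of singles, producing a uniform nonzero
DI at every pair. The landscape is featureless (no pair distinguished),
and the conservation filter removes such columns before contact selection,
but users comparing raw DI values across families should be aware of it.

### Memory contract

The pair-excess matrix is dense of order $(L(q-1))^2$; at $q=21$ this is
6000² doubles for $L = 300$, the supported ceiling. Longer alignments
fail with an explicit resource error rather than degrading silently.

## 2. The synthetic-data generator

`plant_from_structure()` plants i.i.d. Gaussian, block-symmetrized
couplings (scale `coupling_strength`, default 1) on the contact graph of a
toy structure — pairs within 8 Å Cα and $|i-j| > 5$ — and
`sample_alignment()` draws sequences by heat-bath Gibbs sampling (default
500 burn-in sweeps, thinning 10, chains capped at 200, all seeded). The
toy targets (`ideal_helix()`, `helix_hairpin()`) use canonical helix
geometry (2.3 Å radius, 1.5 Å rise, 100°/residue, virtual bond 3.8 Å).

What the generator emulates: covariation from direct contacts, redundancy
(duplicate and near-duplicate sequences exercising the reweighting), and
known ground truth for precision measurements. What it does **not**
emulate: phylogenetic correlation (tree-structured sampling), alignment
errors, gaps from variable-length homologs, and functional (non-contact)
constraints. Passing tests therefore certify the inference machinery, not
performance on real families — on real data the effective sequence number
is far below the raw count and false-positive rates are substantially
higher.

Generator defaults are study conditions, not dials: the recovery
benchmark is fixed at $L=30$, $q=8$, 20 planted pairs, $m=2000$ sampled
sequences; the end-to-end fold at a 60-residue hairpin with top-$L/2$
contacts, mirroring the observation that roughly $L/2$ constraints
suffice for a correct approximate fold.

## 3. Contact selection

Four rules turn the DI ranking into EICs, each behind its own function:

- **minimum separation** — keep $j - i > 5$;
- **secondary-structure consistency** — drop pairs internal to one
  predicted helix or strand segment. The finer conflict taxonomy used in
  the original protocol is not publicly specified, so this conservative
  reading was chosen and isolated in `filter_ss_conflict()` for easy
  revision; pairs bridging distinct segments always pass;
- **conservation** — drop pairs touching a column whose raw, unweighted
  modal frequency exceeds 0.9 (conservation is a property of the observed
  family, not the reweighted one; switchable);
- **cysteine exclusivity** — among Cys–Cys pairs, one partner per
  cysteine, greedily by rank. This rule is rank-greedy and therefore
  applied last; the other three commute (verified by permutation tests).

Equal DI values tie-break lexicographically on $(i,j)$ for determinism.
The default $N_C$ grid runs from 30 in steps of 10 up to $L$.

## 4. Restraints and distance geometry

Restraint bounds (Å), all configurable in `restraint_config()`:

| origin | pair | bounds | applied to |
|---|---|---|---|
| chain | $(i,i{+}1)$ | 3.8 (exact, weight 10) | Cα |
| helix | $(i,i{+}2)$ / $(i,i{+}3)$ / $(i,i{+}4)$ | [5.1,5.9] / [4.8,5.6] / [5.8,6.6] | Cα |
| strand | $(i,i{+}2)$ | [6.2,7.0] | Cα |
| EIC | selected $(i,j)$ | [3.5,7.0] | pseudo-Cβ |

Two deliberate choices here. First, the helix $(i,i{+}2)$ restraint is
included although only $(i,i{+}3)$/$(i,i{+}4)$ are strictly canonical:
without it the distance set underdetermines local helix geometry and
zig-zag artifacts satisfy all bounds. Second, Cβ-level EIC bounds are
converted to effective Cα bounds by widening with **one** Cβ offset
(1.53 Å), not two — contacting side chains point broadly toward each
other, and the two-offset conversion proved nearly non-binding. Pseudo-Cβ
atoms are placed 1.53 Å from Cα along the local tetrahedral direction from
three consecutive Cα positions (glycine keeps Cα), and are used for
model-side contact definitions (Cβ–Cβ < 8 Å, labelled `cb_proxy`;
reference structures use the 5 Å minimum-heavy-atom rule).

Embedding: triangle-inequality smoothing over the full bounds matrix
(upper bounds by all-pairs shortest paths, lower bounds by the standard
rule $l_{ij} \ge l_{ik} - u_{kj}$; contradictions raise an error naming
the worst pair), one-shot random metrization within the smoothed bounds,
double-centered Gram matrix, spectral embedding on the top three
components. Distances carry no chirality, so both the embedding and its
mirror are refined and the better-handed image kept.

Refinement is a coarse-grained surrogate for molecular-dynamics simulated
annealing: flat-bottom harmonic restraint energy plus soft-sphere Cα
repulsion (onset 4 Å) and the chain-bond term, minimized by L-BFGS-B in
five outer stages that ramp the repulsion weight 0.1 → 1.0 (300 iterations
each). The best coordinates by full-weight energy are carried across
stages, so the reported energy trace is non-increasing by construction; a
final SHAKE-like projection restores the 3.8 ± 0.2 Å virtual bond. This
surrogate tests the information content of the restraints; it does not
produce all-atom physics, hydrogen bonding, or β-sheet register.

## 5. Ranking: handedness and knots

Natural helices and strand pairings are right-handed, and distance-only
embeddings cannot know that. The handedness score is the fraction of
in-helix virtual Cα dihedrals (i..i+3) inside +30°..+70° — a tolerant
window around the canonical +50°, since coarse models are distorted —
plus, for strands, the fraction of inter-strand dihedrals (pairings
detected by Cα proximity < 5.5 Å between distinct predicted strands) with
right-handed sign; components are combined by a weighted mean over the
number of H and E residues. The exact combination rule in the original
protocol is unspecified ("scores normalized to the secondary structure
content"); the weighted mean is one defensible reading. With no H/E
residues the score is undefined and reported neutral (0.5) with a flag. A
model and its mirror have combined scores summing to 1 whenever all
dihedrals are defined.

Knot detection closes the chain radially through a sphere at 3× the
structure's extent, reduces the closed polygon by KMT triangle
elimination (reduction must happen *after* closure — an open chain is
always trivially untiable), projects along a deterministic sequence of
directions until the projection is generic, and evaluates the Alexander
polynomial at $t = -1$ from the crossing diagram. $|\Delta(-1)| \ne 1$
flags a knot; the trefoil gives 3. The invariant is chirality-blind and
cannot certify *unknottedness* (standard limitation), and genuinely
knotted native folds would be wrongly discarded — an accepted trade-off.
An independent Fox three-coloring count backs the determinant in the
tests.

Ranking sorts unknotted models by combined handedness, ties broken by
lower restraint energy, then provenance.

## 6. Evaluation metrics

Contact side: true-positive rate of the top $N_C$ predictions, plus two
index-space distances — false-positive severity (mean distance of each
prediction to the nearest observed contact) and spread (mean distance of
each observed contact to the nearest prediction, the coverage dual). All
restricted to $|i-j| > 5$ on both sides.

Structure side: Kabsch superposition (proper rotations only), trimmed
Cα-RMSD (sigma cut 2.0, at most 5 cycles, never below half the residues —
values declared, not inferred from any particular alignment tool),
TM-score with $d_0 = 1.24(L_{ref}-15)^{1/3} - 1.8$ floored at 0.5, and
GDT-TS as the mean over 1/2/4/8 Å of the maximal superposable fraction.
TM and GDT use the same fragment-seeded iterative superposition search;
it is approximate (documented), and the tests bound it against exhaustive
window enumeration on small fixtures.

## 7. Problem sizes and determinism

Every stochastic step takes an explicit seed and restores the global RNG
state; pipelines re-run byte-identically from config + seed. The bundled
benchmarks use $q^L = 243$ for exact enumeration, $m = 2000$ sequences
for sampled recovery, 20-residue helices for embedding fidelity, and
6–8 models per arm for the end-to-end comparison — sizes chosen so the
full suite runs on a single desktop CPU in about a minute while leaving
the measured effects (DI/MI precision gap, EIC-vs-control RMSD gap) far
from their decision thresholds.

## 8. Known limitations

- Mean-field inversion is a first-order approximation; pseudolikelihood
  and Gaussian variants are out of scope.
- No phylogenetic correction beyond identity reweighting.
- The coarse-grained refinement cannot reach the ~2 Å regime that
  all-atom annealing achieves with ideal constraints; on the toy family
  the floor is a few Å.
- The SS-conflict filter is a conservative single rule, not the full
  (unpublished) conflict taxonomy.
- Alexander-determinant knot detection misses knots with
  $|\Delta(-1)| = 1$ (e.g. some composite/pretzel knots) — irrelevant at
  these chain lengths in practice.
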