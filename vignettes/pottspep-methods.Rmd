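---
title: "Designing plastic-binding peptides with a Potts model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing plastic-binding peptides with a Potts model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pottspep)
```

## The design problem

Microplastic remediation strategies that use peptides as capture agents need
short sequences with high adsorption affinity for a given plastic surface.
`pottspep` treats this as fixed-conformation sequence design: given one frozen
conformation of a 12-residue peptide backbone adsorbed on a plastic slab, find
the amino-acid sequences that minimize a physics-based score.

The score is a Potts model over per-residue amino-acid states. Writing
$s_{i\alpha} \in \{0,1\}$ for "residue $i$ carries amino acid $\alpha$",

$$\mathrm{Score} = \sum_i E_{i,s_i} \;+\; \lambda \sum_{i<j} E_{i,s_i,j,s_j} \;+\; p,$$

where the one-body energy $E_{i\alpha}$ collects the interactions of the side
chain at $i$ with the plastic surface, with itself and with the whole peptide
backbone, and the two-body energy $E_{i\alpha,j\beta}$ is the side-chain to
side-chain interaction. The weighting $\lambda$ (default 0.01) down-weights
intrapeptide stability relative to surface affinity, and $p$ is a constant
reporting offset. Lower scores mean higher predicted affinity. Proline is
excluded from the 20 natural amino acids because its backbone constraint is
incompatible with a fixed backbone, leaving a 19-letter design alphabet.

Because the tables are precomputed, scoring any sequence is a table lookup;
the combinatorial problem is choosing the best of $19^{12}$ sequences.

### On the constant penalty $p$

A constant offset cannot change the minimizer (the test suite verifies this
exhaustively on small instances). We keep it because scores harvested from a
grid of $(\lambda, p)$ cells are compared and deduplicated together, and the
offset is part of each cell's provenance; it is recorded in solver metadata
rather than given any mechanistic role.

## Energy tables from atoms

`build_tables()` derives the tables from a conformation with a simplified
molecular-mechanics energy: Coulomb electrostatics
($k\,q_iq_j/\varepsilon_{\mathrm{in}} r$, $k = 332.0636$ kcal·Å/mol·e²,
no cutoff), Lennard-Jones with Lorentz–Berthelot combination, and a
generalized-Born (GB) solvation cross-term using the Still smoothing function
$f_{\mathrm{GB}} = \sqrt{r^2 + R_iR_j\,e^{-r^2/4R_iR_j}}$ with
$\varepsilon_{\mathrm{in}} = 1$, $\varepsilon_{\mathrm{out}} = 78.5$.

Three modelling devices make the many-body physics separable into one- and
two-body terms:

* **Side-chain coarse-graining for Born radii.** Born radii depend on every
  atom in the system, which does not fit a pairwise decomposition. Whenever a
  residue is not one of the "active" residues of the term being computed, its
  side chain is replaced by a single neutral, LJ-inert sphere of radius 3 Å
  at the ideal C$\beta$ position. The sphere participates only in the
  pairwise-descreening sum (an analytic $1/r^4$ volume integral, clipped
  against the self sphere and capped at an effective radius of 30 Å for
  deeply buried atoms).
* **Rotamer reduction.** Side-chain conformations come from a packaged
  minimal rotamer library (three $\chi_1$ wells per rotatable side chain).
  For each (residue, amino acid) pair, every library rotamer is built with
  ideal internal coordinates (NeRF placement), refined by a deterministic
  coordinate-wise $\pm10^\circ$ scan (two sweeps), and only the rotamer with
  the lowest one-body energy is retained. Two-body energies reuse exactly
  that retained rotamer, so the tables stay sequence-independent.
* **Term assignment.** Backbone–backbone and backbone–plastic energies are
  sequence-invariant and omitted; side-chain–backbone cross terms go into
  the one-body energy, keeping the two-body term purely side chain to side
  chain. Intra-residue Coulomb/LJ pairs use bonded exclusions (1-2 and 1-3
  excluded, 1-4 scaled by 0.5 over the united-atom bond graph); the GB term
  carries no exclusions, as is conventional.

The packaged force field is deliberately small: a united-atom topology with
one to five pseudo-atoms per side chain, about fifteen atom types carrying the
residue's net charge, polarity and bulk. It is a self-contained toy parameter
set, not a transferable biomolecular force field; the whole pipeline is
parameter-file driven (`read_forcefield()`, `read_rotamer_library()`) so
richer parameters can be dropped in without code changes. One known residual
inconsistency is inherent to the coarse-graining: the Born radii used inside
a one-body term (only residue $i$ atomistic) differ slightly from those used
inside a two-body term (residues $i$ and $j$ atomistic). The acceptance
checks therefore compare table scores against a *direct* recomputation in the
same coarse-graining context, which agrees to machine precision; agreement
with a full atomistic many-body energy is approximate by construction.

Glycine has no C$\beta$ in this topology, so its side chain is empty, its
one- and two-body energies are zero, and it is excluded (and flagged) from
the geometric environment analysis.

## Solvers

The design problem is solved classically through three interchangeable
routes, all of which emit only feasible sequences and break ties
lexicographically by alphabet order:

* `solve_exhaustive()` — the ground-truth oracle, guarded to
  $|A|^n \le 10^7$.
* `solve_simulated_annealing()` — a Metropolis walk in the feasible space
  (moves change one residue's letter, so the one-hot constraint can never be
  violated), geometric cooling. The default schedule starts at ten times the
  standard deviation of 1000 random-sequence scores, ends at 0.01, and uses
  $5\times10^4$ steps; the seed is mandatory, never taken from the clock.
  An incrementally maintained conditional one-body field makes each proposal
  O(1) and each accepted move O($nA$).
* `solve_hybrid()` — a large-neighborhood decomposition refiner: small
  residue blocks (default pairs) are solved exactly with the rest frozen,
  improvements only are accepted, so the score trace is monotone
  non-increasing. With block size $n$ it degenerates to the exhaustive
  solver. It mirrors the structure of hybrid quantum/classical decomposition
  solvers, with the subproblem solver replaced by exact enumeration.

`encode_one_hot_qubo()` exposes the equivalent QUBO: one binary variable per
(residue, letter), the per-residue penalty $A_w(\sum_\alpha s_{i\alpha}-1)^2$
with $A_w = 2(\sum_i \max_\alpha|E_{i\alpha}| + \lambda\sum_{i<j}
\max_{\alpha\beta}|E_{i\alpha,j\beta}|) + 1$, which strictly dominates any
energetic gain from violating a constraint (verified exhaustively on small
instances). Hardware-specific annealer parameters (chain strength, anneal
time, minor embedding) are intentionally out of scope.

`hyperparameter_scan()` solves one model per $(\lambda, p)$ grid cell and
returns the per-cell best plus the deduplicated sequence set, which is how
multiple designs are harvested from a single conformation.

## PPO exploration of near-optimal sequences

Degenerate, near-optimal sequences matter because they diversify
physicochemical properties at almost no cost in predicted affinity. The
`ppo_explorer` module trains a proximal-policy-optimization agent on the
Potts landscape:

* **Network.** An embedding table maps each residue's letter to a 16-d
  vector; a gated recurrent unit (hidden size 64) consumes the embedded
  sequence; a softmax output layer over the $n \times |A|$ substitution
  actions gives the policy, and a linear value head shares the recurrent
  trunk (PPO needs a critic even though only the policy is of interest).
  The network is implemented in plain R matrix code with hand-derived
  backpropagation through time; the gradients are verified against numerical
  differentiation in the test suite.
* **Environment.** The state is the current sequence; an action substitutes
  one letter at one position. The reward is the score *decrease*
  $\mathrm{score}(s_t) - \mathrm{score}(s_{t+1})$. Written as a raw score
  difference the reward would favour score increases; we flip the sign so
  that the stated goal — a policy that moves toward lower scores — holds.
  Episode rewards then telescope to the net score drop, which the tests
  assert. The sign is a documented convention, not a tunable.
* **Training.** Episodes start from the solver optimum (seeding exploration
  from the optimum measurably accelerates alternate discovery — this is a
  tested property). Updates use the clipped surrogate objective
  (clip 0.2), GAE advantages (discount 0.99, $\lambda_{\mathrm{GAE}}$ 0.95),
  an entropy bonus, Adam (lr $3\times10^{-4}$), and an approximate-KL guard
  that rolls back any update epoch that moves the policy beyond the limit.
  Everything is deterministic given the config seed.
* **Harvesting.** `collect_alternates()` rolls the stochastic trained policy
  from the seed sequence and keeps every distinct visited sequence whose
  score lies within a window (default 5 score units) of the best known
  score, excluding the seed itself. Every member is re-scored on output, so
  the window rule holds by construction and by test.

## Geometry and property analyses

For adsorbed designs the package characterizes each residue's side-chain
environment by three descriptors: the signed height of C$\beta$ above the
slab top, the angle between the C$\alpha\to$C$\beta$ vector and the surface
normal, and the solvent accessibility of a *bare* C$\beta$ (all other atoms
of that side chain deleted) from an own Shrake–Rupley implementation
(960 deterministic golden-spiral points, probe 1.4 Å). Structures are first
rigidly aligned so the best-fit slab plane is normal to $+z$ with the peptide
above; the slab top $z_0$ is the maximum plastic heavy-atom $z$. Descriptors
are rigid-motion invariant (SASA to within the point-set discretization,
about 2%).

Bin edges are not prescribed by any convention we could adopt, so the
defaults are explicit, configurable choices: distance
$(-\infty,0,2,4,6,8,\infty)$ Å, angle $(0,60,120,180)^\circ$, SASA
$(0,40,80,\infty)$ Å², all half-open $[lo, hi)$ with the top angle bin
closed. `environment_preference()` reports a bin's modal amino acid only when
it occurs in more than one third of the observations in that bin; modal ties
are conservatively suppressed.

Sequence-level properties: net charge by Henderson–Hasselbalch with an
EMBOSS-style pKa set (swappable, since pKa conventions differ between
servers), pI by bisection (unique because the termini guarantee both signs
and charge is strictly monotone in pH), average or monoisotopic mass, Welch's
unequal-variance $t$ test for composition comparisons, and a *solubility
proxy* — minus the mean Kyte–Doolittle hydropathy plus half the absolute
per-residue net charge. The proxy is clearly labelled: it is a
composition-only stand-in, not the CamSol intrinsic solubility method, and
its values are not comparable to CamSol scores.

## Synthetic fixtures and what passing tests show

All test inputs are generated by code, each a pure function of its
specification and seed:

* `make_planted_tables()` hides a known unique optimum with margin at least
  half the requested gap (enumeration-verified at build time for small
  instances; the guarantee assumes the default $\lambda = 0.01$ regime where
  the bounded two-body noise, under $\mathrm{gap}/8n$ per entry, cannot
  overturn a one-body gap).
* `make_degenerate_tables()` plants $k$ single-mutant alternates exactly at
  the window edge with every other sequence at least twice the window worse;
  two-body terms are zero so the construction is exact at any $\lambda$.
* `make_toy_system()` builds an ideal extended backbone (with one C$\beta$
  per non-glycine residue) parallel to a rectangular united-CH$_2$ slab
  lattice, mass-weighted center of mass 4 Å above the slab top, with a small
  seeded jitter.
* `make_env_dataset()` draws descriptor triples uniformly inside every bin
  and plants a chosen letter at a chosen frequency in chosen bins.

These fixtures emulate the *structure* of the real problem — a rugged
separable-plus-pairwise landscape, planted degeneracy, a slab geometry — but
not its physics: toy conformations are idealized (no MD-derived backbone
dihedrals, no realistic plastic surfaces, a minimal force field), so passing
tests demonstrate correctness of the machinery (table construction,
solver optimality, window rules, descriptor geometry), not the accuracy of
any specific affinity prediction for a real plastic.

## Numerical choices and problem sizes

* Tolerances: score/QUBO equivalence at $10^{-9}$ relative; strict-improvement
  thresholds $10^{-12}$ in solvers so ties never cycle; pI bisection to
  $10^{-4}$ charge units.
* Degenerate geometry (coincident atoms, zero distances with nonzero
  weights, non-positive Born radii) raises classed numerical errors rather
  than returning silently wrong values.
* Sequence-space checks run at $n = 4$, $|A| = 5$ where the exhaustive
  oracle enumerates 625 sequences; full-size stochastic checks (planted
  recovery, PPO harvesting) run at $n = 12$, $|A| = 19$, the design size.
  The oracle suite uses 50 seeded random instances; planted recovery uses
  20 seeded runs; PPO harvesting uses 3 training seeds with a total step
  budget of $10^5$.
* Default solver/PPO parameters live in one place (`anneal_schedule()`,
  `ppo_config()`) and every stochastic entry point requires an explicit
  seed.

## Known limitations

* The force field is a self-contained toy set; absolute energies are not
  comparable to Amber-class force fields, and no nonpolar (SASA-based)
  solvation term is included.
* The GB one-/two-body partition under coarse-graining is approximate with
  respect to a full many-body GB energy (see above); the package quantifies
  internal consistency, not that residual.
* No conformational degrees of freedom: one model per frozen conformation,
  by design. Ensembles are handled by building tables for many conformations
  and pooling designs.
* The PPO action space is a flat joint softmax over (position, letter);
  autoregressive generation is not implemented.
* No trajectory parsing, periodic-boundary imaging, quantum-hardware
  submission, or third-party solubility predictions.
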