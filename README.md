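# pottspep

Sequence design of short plastic-binding peptides (PBPs) on a fixed adsorbed
conformation, for researchers exploring peptide-based microplastic capture.

Given one frozen conformation of a peptide backbone above a plastic slab,
`pottspep` scores any candidate sequence with a Potts model over per-residue
amino-acid states,

```
Score = sum_i E[i, s_i]  +  lambda * sum_{i<j} E[i, s_i, j, s_j]  +  p
```

where the one-body energy `E[i, a]` is the interaction of amino acid `a` at
residue `i` with the plastic surface, itself and the peptide backbone, the
two-body energy `E[i, a, j, b]` is the side-chain/side-chain interaction,
`lambda` (default 0.01) weights peptide stability against surface affinity,
and `p` is a constant reporting offset. Lower scores mean higher predicted
affinity. The 19-letter design alphabet is the natural amino acids minus
proline.

The package provides, end to end:

* **Energy tables from atoms** — a simplified Coulomb + Lennard-Jones +
  generalized-Born energy with side-chain coarse-graining (3 Å spheres at
  Cβ) for Born radii and lowest-one-body-energy rotamer reduction
  (`build_tables()`), driven by swappable force-field / rotamer parameter
  files.
* **Classical solvers** for the one-hot QUBO encoding of the model —
  exhaustive enumeration (oracle), feasible-space simulated annealing, and a
  large-neighborhood decomposition refiner (`solve_exhaustive()`,
  `solve_simulated_annealing()`, `solve_hybrid()`), plus a
  `(lambda, p)` hyperparameter scan that harvests multiple designs per
  conformation.
* **A PPO explorer** (embedding + GRU policy network, written in base R with
  hand-derived backpropagation) that learns to navigate the score landscape
  and harvests *alternate* designs within 5 score units of the best known
  score (`ppo_train()`, `collect_alternates()`).
* **Analyses** — net charge, isoelectric point, mass, a clearly-labelled
  composition-based solubility proxy, amino-acid frequencies with Welch
  t-tests, and the side-chain geometric environment preference table
  (Cβ–surface distance, Cα→Cβ angle, bare-Cβ SASA).
* **Synthetic fixtures** — planted-optimum and planted-degeneracy energy
  tables, toy peptide+slab structures in PDB, and environment datasets; all
  generated by seeded code.

See `vignettes/pottspep-methods.Rmd` for the model, assumptions, parameter
choices and limitations.

## Worked example

```r
library(pottspep)

# a toy 4-residue peptide 4 Angstrom above a united-CH2 slab
conf <- make_toy_system(4, seed = 11, slab_margin = 4)
tables <- build_tables(conf, conformation_id = "toy-4mer")
model <- potts_model(tables, lambda = 0.01)

sa <- solve_simulated_annealing(model, anneal_schedule(n_steps = 2e4, seed = 1))
best <- solve_hybrid(model, init = sa$sequence, seed = 2)
best
#> [hybrid] YRNR  score = -339.411

# train PPO from the optimum and harvest near-optimal alternates
pol <- ppo_train(model, best$sequence,
                 ppo_config(updates = 8, horizon = 20,
                            episodes_per_update = 3, seed = 3))
alts <- collect_alternates(pol, model, window = 5, budget = 20000, seed = 4)
alts
#> alternate_set: 7 members within 5 of best -339.411
#>   YKNR  -335.555
#>   YKTR  -334.640
#>   YRNK  -338.641 ...

property_profile(paste(best$sequence, collapse = ""))
#>   sequence net_charge    pI  mass solubility_proxy
#> 1     YRNR      1.975 11.15 607.7            3.697
```

The best design `YRNR` scores −339.4 kcal/mol on this conformation (tables
are in kcal/mol; magnitudes reflect the packaged toy force field, not an
Amber-class energy). PPO finds 7 distinct sequences within 5 score units —
single substitutions such as `YRNK` (−338.6) that trade a little predicted
affinity for different physicochemistry. The profile says the design carries
about +2 e at pH 7 with an isoelectric point of 11.2.

A thin command-line dispatcher over the same functions is installed as
`exec/pottspep` with subcommands `tables`, `solve`, `explore`, `analyze` and
`simulate`, each driven by a YAML config (see `?cmd_tables` and friends).

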