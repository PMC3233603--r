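# dcafold

Protein residue–residue contacts leave a statistical footprint in the
evolutionary record: positions that touch in the folded structure co-vary
across a family of homologous sequences. `dcafold` turns that footprint
into coarse-grained 3D structure predictions. It is aimed at structural
bioinformaticians who have a deep multiple sequence alignment (MSA) of a
protein family, a per-residue secondary-structure prediction, and no
crystal structure — and at methods developers who want a fully synthetic,
seeded benchmark for coupling-inference and folding pipelines.

## The model

Sequences `A = (A_1 … A_L)` (each position one of q = 21 states: 20 amino
acids plus gap) are modelled by the maximum-entropy distribution consistent
with the observed single- and pair-column frequencies — an inverse Potts
model:

    P(A) ∝ exp( Σ_{i<j} e_ij(A_i, A_j) + Σ_i h_i(A_i) )

In mean-field approximation the couplings come from one matrix inversion,
`e_ij = −(C⁻¹)_ij`, where `C_ij(A,B) = f_ij(A,B) − f_i(A) f_j(B)` is the
pair-excess (covariance) matrix restricted to q−1 states. Sequences with
≥ 70 % identity to neighbours are down-weighted (effective count `Meff`),
and a uniform pseudocount λ regularises the frequencies.

Each pair is scored by **direct information**,

    DI_ij = Σ_{A,B} P_ij^Dir(A,B) ln [ P_ij^Dir(A,B) / (f_i(A) f_j(B)) ] ,

the mutual information of the two-site *direct* distribution
`P^Dir ∝ exp(e_ij + h̃_i + h̃_j)` whose fields are fitted to reproduce the
single-site marginals. Unlike plain mutual information (MI, also computed
as the local baseline), DI suppresses transitive correlations — if B
touches both A and C, then A and C co-vary without being in contact, and
only the global model can tell the difference.

Top-ranked DI pairs pass four filters (sequence separation |i−j| > 5,
consistency with predicted secondary structure, > 90 % conservation
removal, one disulfide partner per cysteine) to become **evolutionary
inferred contacts (EICs)**. EICs plus secondary-structure geometry become
distance bounds; candidate structures are generated by distance geometry
(triangle-inequality bound smoothing, random metrization, metric-matrix
embedding — both chiral images, since distances carry no handedness) and
refined against the restraints with an annealed soft-sphere repulsion.
Candidates are ranked blindly by the fraction of right-handed virtual
Cα dihedrals (helix and strand-pair twist, weighted by predicted secondary
structure content), and knotted chains — detected via the Alexander
polynomial at t = −1 after KMT chain reduction — are discarded. Against a
reference structure, the package reports contact true-positive rate,
false-positive severity and spread (index-space distances), and trimmed
Cα-RMSD, TM-score and GDT-TS.

## Worked example

A fully synthetic run on a 60-residue helix-hairpin toy family. The
generator plants Potts couplings on the hairpin's real contact pairs, so
the ground truth is known exactly:

```r
library(dcafold)

hh     <- helix_hairpin()                                  # toy target + SS track
model  <- plant_from_structure(hh$ca, coupling_strength = 1, seed = 1)
fam    <- sample_alignment(model, 2000, sampler_config(seed = 2))
walign <- compute_weights(fam$alignment)                   # 70% identity reweighting
scores <- score_all_pairs(walign)                          # mean-field DI + MI
head(tidy(scores), 5)
#>       i     j ref_i ref_j    di    mi
#> 1    15    49    15    49 0.287 0.403
#> 2     1    60     1    60 0.243 0.463
#> 3    12    49    12    49 0.226 0.378
#> 4    15    46    15    46 0.223 0.375
#> 5     5    57     5    57 0.209 0.376

eics <- select_eics(scores, n_c = 30, ss = hh$ss, aln = fam$alignment)
obs  <- contacts_from_model(hh$ca, threshold = 8, min_sep = 5)
true_positive_rate(eics, obs, 30)
#> [1] 0.8

models  <- generate_ensemble(list("30" = eics), hh$ss, hh$L,
                             n_per_bin = 6, seed = 3)
ranking <- rank_candidates(models, hh$ss)
best    <- models[[ranking$model[1]]]
trimmed_rmsd(best$ca, hh$ca)
```

The top DI pairs are genuine hairpin contacts (e.g. 15–49 bridges the two
helices), 24 of the top 30 EICs are true contacts (TP rate 0.8), and the
ensemble folds to 6.1–9.0 Å trimmed Cα-RMSD against the toy target —
versus about 10 Å at best for a shuffled-pair control with identical
settings. On
real families the same calls apply with `read_alignment()`,
`read_ss_track()` and `contacts_from_reference()`; alignments of at least
~1000 sequences are recommended (shallower ones produce a warning).

A thin command-line front end is installed as `exec/dcafold`
(`dcafold pipeline --config cfg.yml`, plus `simulate`, `couplings`,
`select`, `evaluate` subcommands) for shell use; every subcommand is a
thin wrapper over the functions above.

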