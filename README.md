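# flexrin

Confidence–flexibility concordance and residue interaction networks for
protein conformer ensembles.

## What this is for

Structure predictors in the AlphaFold family attach a per-residue
confidence (pLDDT, stored in the PDB B-factor column) to every model.
For well-folded globular proteins that confidence is informative about
*dynamics*: low-confidence regions tend to be the ones that move, and
binding-site segments predicted confidently behave as if their cofactors
were already in place.  flexrin is for structural bioinformaticians who
want to quantify that relationship on a conformer ensemble — a set of
molecular-dynamics snapshots or a population of predicted models — and to
characterise cofactor/substrate binding modes at contact level.

The core quantities:

* **RMSF**: per-residue root-mean-square fluctuation about the ensemble
  mean after Kabsch superposition of every frame onto the first,
  `RMSF_i = sqrt(mean_t |r_i(t) - r̄_i|²)`.
* **Reverse-normalised confidence score**:
  `s_i = (pLDDT_max − pLDDT_i) / (pLDDT_max − pLDDT_min)`,
  so high score = low confidence = predicted flexibility; compared with
  RMSF through the Pearson correlation with a two-sided t-based p-value.
* **Residue interaction networks (RIN)**: vertices are polymer residues
  plus whole ligand groups; an edge exists when the *minimum heavy-atom
  distance* between two vertices is strictly below 3.5 Å (the classic
  Cβ/8 Å dialect is also provided).  Built per frame over an ensemble,
  RINs yield per-ligand contact percentages and partner-count
  statistics.
* **Ligand transfer**: rigid-body grafting of cofactors from a holo
  template into an apo model via Needleman–Wunsch residue pairing and
  Kabsch superposition, with a clash check.
* **Structure trees**: pairwise Cα RMSD matrices converted to
  neighbor-joining trees with Newick output.

A deterministic synthetic-ensemble generator (helical base fold,
rigid-residue Gaussian jitter with a designed per-residue σ profile,
confidence anti-correlated with σ, ligand groups in contact in an exact
fraction of frames) provides ground truth for every analysis.

## Worked example

```r
library(flexrin)

## a 60-residue synthetic system: flexible termini, rigid core, a cofactor
## in contact with residue 25 in exactly 82% of frames and a substrate at
## residue 40 in 50%
base <- make_base_fold(60, seed = 11)
spec <- synth_spec(60, n_frames = 200, seed = 11,
                   ligand_schedules = list(ligand_schedule("BVQ", 25, 0.82),
                                           ligand_schedule("PFO", 40, 0.50)))
ens <- sample_ensemble(base, spec)
ens
#> <flexrin_ensemble (trajectory): 200 frames, 303 atoms, 60 polymer residues, 2 ligand group(s)>

## flexibility vs predicted confidence
fx <- rmsf(ens)
pl <- synth_plddt(spec$sigma, noise_sd = 5, seed = 11, base = base)
pearson_concordance(af2_score(pl), fx)
#> <concordance: PCC 0.591, p 6.47e-07, n 60>

## dynamic ligand contacts: the designed 82% is recovered exactly
rep <- ligand_report(ens, targets = c("BVQ", "PFO"))
rep$tables$BVQ
#> <freq_table 'BVQ': 1 interacting residue(s) over 200 frames; partners 0.82 +/- 0.38>
#>       key res_name class percent
#> A:25 A:25      ILE other      82

## equilibration summary
tm <- tail_mean(rmsd_series(ens), 0.1)
sprintf("tail RMSD: %.2f +/- %.2f A", tm$mean, tm$sd)
#> "tail RMSD: 1.58 +/- 0.10 A"
```

The concordance of 0.591 says the noisy synthetic confidence profile
(Gaussian noise, sd 5 pLDDT on a 12-pLDDT signal range) still tracks the
measured flexibility; with zero noise the correlation is exactly 1 by
construction.  The contact table reads like a dynamic binding-site
report: residue 25 touches the BVQ group in 164 of 200 frames (82%), and
the cofactor has 0.82 ± 0.38 polymer partners per frame.

Real data enter through `read_multimodel_pdb()` (multi-model PDB,
pLDDT-in-B-factor) and `read_confidence_json()` (per-residue pLDDT array,
optional PAE matrix); `transfer_ligands()` grafts cofactors from a holo
template into such models, and `neighbor_joining(pairwise_rmsd_matrix(ens))`
summarises a model population as a structure tree.

A thin command-line wrapper is installed as `inst/scripts/flexrin`
(subcommands `synth`, `rmsf`, `af2score`, `concordance`, `rmsdseries`,
`rin`, `dynrin`, `transfer`, `tree`, `run`).

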