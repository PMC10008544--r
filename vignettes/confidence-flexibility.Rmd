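---
title: "Confidence, flexibility and ligand contacts in conformer ensembles"
author: "flexrin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence, flexibility and ligand contacts in conformer ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexrin)
```

## The scientific question

AlphaFold-style structure predictors attach a per-residue confidence, the
pLDDT, to every model, conventionally stored in the PDB B-factor column.
For well-folded globular proteins this confidence tracks residue
flexibility: regions predicted with low confidence tend to be the regions
that move — flexible termini, loops, and binding-site segments that only
rigidify when a cofactor or substrate is present.  flexrin implements the
quantitative machinery for examining that relationship on conformer
ensembles (molecular-dynamics snapshots or populations of predicted
models), together with the contact-level analyses used to characterise
cofactor and substrate binding modes:

* per-residue RMSF and per-frame RMSD from an ensemble, after Kabsch
  superposition;
* the reverse min–max normalised confidence score
  $s_i = (\mathrm{pLDDT}_{\max} - \mathrm{pLDDT}_i) /
  (\mathrm{pLDDT}_{\max} - \mathrm{pLDDT}_{\min})$,
  so that high score means predicted flexibility, and its Pearson
  concordance with the RMSF profile;
* residue interaction networks (RINs) in which whole ligand groups are
  single vertices, built per frame, with contact-frequency statistics per
  ligand;
* rigid-body transfer of cofactors from a holo template into an apo model
  over a sequence-alignment-derived residue pairing;
* neighbor-joining trees from pairwise structural RMSD matrices.

Because real trajectories of the motivating systems are not distributable,
the package ships a synthetic-ensemble generator with exact ground truth;
every analysis can therefore be validated end-to-end against designed
values.

## The contact model

Two contact dialects are provided.  The classic dialect measures
C$\beta$–C$\beta$ distances (C$\alpha$ for Gly) with an 8 Å cutoff.  Its
known failure mode is geometric: two residues whose sidechains touch can
have C$\beta$ atoms far apart (and vice versa), producing false negatives
and false positives.  The default dialect therefore defines the distance
between two residues as the *minimum over all heavy-atom pairs* and calls
a contact when that distance is strictly below 3.5 Å — the upper end of
hydrogen-bond donor–acceptor separations (X–H…Y distances run ~2–3 Å for
conventional hydrogen bonds and ~3.5 Å for C–H…O).  A `rin_graph` is the
binary, symmetric, zero-diagonal adjacency over polymer residues plus one
vertex per ligand group; the distance to a multi-atom ligand group is the
minimum over all its heavy atoms.

Choices within this model:

* **Strict inequality at the cutoff.**  A pair at exactly 3.5 Å is not a
  contact.  The boundary convention is tested explicitly.
* **Sequence-adjacent polymer pairs are kept** as edges but carry a
  `bonded` flag; `exclude_bonded = TRUE` removes them.  Both behaviours
  are exposed because published RIN variants differ here.
* **Hydrogens never participate.**  Heavy atoms only, in both dialects.
* Ligand groups are excluded from the C$\beta$ dialect (they have no
  C$\beta$), with a warning.

Per-frame RINs over an ensemble yield, for each ligand vertex, the
percentage of frames in which each residue touches it, the ligand's
per-frame polymer degree summarised as mean ± sd, and a residue × ligand
matrix exposing shared binders.  The sd uses the population ($n$) divisor:
at the 100-frame scale typical here the difference from $n-1$ is
immaterial, and the population form makes the sum rule
$\overline{\mathrm{deg}} = \sum_i p_i / 100$ exact.  Ranking thresholds
are strict (`percent > threshold`), and ties in the ranking are broken by
residue position so output is deterministic.

## The synthetic-ensemble generator

The generator is a first-class module, not a test fixture: it defines the
study conditions under which every quantitative claim of the package is
checked.

**Base fold.**  An idealised $\alpha$-helical C$\alpha$ trace (rise 1.5 Å,
radius 2.3 Å, 100°/residue).  Backbone N and C atoms sit on the same
helical sweep a third of a residue before and after each C$\alpha$, the
carbonyl O points radially outward from C, and a C$\beta$ pseudo-atom sits
1.5 Å radially outward from C$\alpha$ (omitted for Gly).  This gives
consecutive C$\alpha$ spacing of 3.83 Å, plausible bond lengths, and no
non-bonded heavy-atom pair closer than 2.0 Å, so the unperturbed fold
contains no spurious contacts.  A helix was chosen over a self-avoiding
random walk because it is reproducible and clash-free by construction.

**Fluctuations.**  Frame $t$ displaces every atom of residue $i$ by one
shared draw from an isotropic Gaussian with per-coordinate sd $\sigma_i$
(*rigid-residue jitter*).  One draw per residue per frame — rather than
per atom — keeps inter-residue minimum distances fluctuating coherently,
closer to rigid sidechain motion, and makes the RMSF ground truth exact:
$\mathbb{E}\,\mathrm{RMSF}_i = \sqrt{3}\,\sigma_i$.  The default
$\sigma$ profile has a rigid core (0.3 Å) ramping to flexible termini
(1.5 Å over 10 residues), which reproduces the RMSF scale seen in
well-folded globular proteins (profile means around 0.8 ± 0.6 Å).

**Confidence.**  $\mathrm{pLDDT}_i = \mathrm{clamp}(95 - a\sigma_i +
\eta_i,\,0,\,100)$ with slope $a = 10$ pLDDT/Å and seeded Gaussian noise
(default sd 5).  With zero noise the profile is exactly affine in
$\sigma$, so the reverse-normalised score correlates perfectly with the
ground-truth flexibility — the cleanest possible test of the concordance
machinery; rising noise degrades the correlation monotonically.

**Ligand schedules.**  A rigid three-atom ligand group is placed, in
exactly `round(f * n_frames)` frames (drawn without replacement from a
seeded RNG), with its nearest atom at `d_on` (default 3.0 Å, i.e. in
contact) from the target residue's C$\beta$ along the outward radial
direction, and at `d_off` (default 6.0 Å, out of contact) otherwise.
Exact frame counts — not Bernoulli draws — make frequency recovery exact
rather than statistical.  The placement follows the jittered anchor, so
realised distances are exact in every frame.

**What the generator does not emulate:** torsional sampling, correlated
domain motions, anisotropic fluctuations, solvent, realistic ligand
chemistry.  Passing tests therefore demonstrate the *correctness of the
estimators and bookkeeping* on data whose ground truth is known — not
that any scientific conclusion transfers to a particular real protein.

## Flexibility and concordance machinery

* **Superposition** is closed-form Kabsch: SVD of the covariance of the
  centred paired coordinates, with the reflection branch corrected by a
  sign flip on the smallest singular vector, so mirror-image inputs yield
  a proper rotation (det = +1) and a non-zero residual.  Degenerate input
  (< 3 pairs, collinear points) is an error.
* **RMSF** defaults to C$\alpha$ atoms after superposing every frame onto
  the first over all C$\alpha$s; without superposition, global rigid
  drift inflates the profile.  On synthetic ensembles (which have no
  drift) parameter-recovery checks run with superposition off, where
  $\mathrm{RMSF}/\sqrt{3}$ estimates $\sigma$ without the small bias the
  fit would introduce.  `selection = "heavy"` averages per-atom RMSF over
  the residue's heavy atoms.
* **The confidence score** normalises over the profile's own extrema, so
  it is invariant under positive affine rescaling and spans [0, 1] for
  any non-constant input.  A constant profile maps to all zeros with a
  warning rather than an error, so pipelines on degenerate fragments do
  not abort.
* **Concordance** is the sample Pearson correlation with the two-sided
  $t$-based p-value ($t = r\sqrt{(n-2)/(1-r^2)}$, $n-2$ df), reported
  raw: one correlation per system, no multiple-testing correction.  All
  residues enter by default; a range mask can be applied upstream by
  subsetting profiles.
* **PAE comparison.**  A predicted-aligned-error matrix and a structural
  distance map live on different scales but encode the same pair
  constraints, so their agreement is quantified as the Spearman rank
  correlation over strict upper-triangle entries.

## Ligand transfer

Cofactors are grafted from a holo template into an apo model by (1)
pairing residues through Needleman–Wunsch global alignment (match 1,
mismatch 0, gap −1; traceback ties resolved diagonal > up > left for
determinism), (2) Kabsch superposition over the paired C$\alpha$ atoms —
unweighted, in contrast to distance-weighted iterative structure aligners;
for near-identical sequences, the regime this workflow targets, the two
coincide — and (3) applying the resulting rigid map to every template
ligand atom.  Internal ligand geometry is preserved exactly.  A clash
check (default 2.0 Å, the shortest plausible non-bonded heavy-atom
approach) gates the placement.

## Trees from RMSD matrices

The pairwise matrix holds C$\alpha$ RMSD after independent pairwise
superposition; this is not a metric (no triangle inequality), but
neighbor joining does not require one.  NJ follows Saitou–Nei with the
standard $Q$ criterion and branch-length formulas; it is exact on
additive matrices.  Ties in $Q$ are broken by the lexicographically
smallest label pair; negative branch lengths, which can arise on
non-additive input, are clamped to zero with a warning.  NJ (rather than
UPGMA) matches the default behaviour of the distance-tree tools this
workflow replaces.  Trees are `ape` `phylo` objects; Newick output writes
branch lengths at 6 significant digits and single-quotes labels
containing spaces or metacharacters.

## Numerical and interface choices

* pLDDT is read from the C$\alpha$ B-factor (per-residue-mean optional);
  values outside [0, 100] are clamped with a warning.
* Alternate locations resolve to the highest-occupancy copy, ties to the
  alphabetically first altloc.  Waters are always dropped.  Author
  residue numbering is preserved end to end.
* An ensemble's atom table (including B-factors) comes from its first
  model; multi-model files with per-model B-factors contribute only their
  first model's confidence track.
* Profile CSVs carry 8 significant digits so a write/read cycle is
  lossless beyond 1e-6 even for values near 100.
* All generation is a pure function of the seed; reruns of the full
  pipeline with one seed are byte-identical (manifests carry the only
  timestamp).

## Problem sizes used in the shipped checks

Parameter recovery uses 60 residues × 2000 frames with
$\sigma_i \in [0.5, 3]$ Å, where the RMSF estimator's relative sampling
error ($\approx 1/\sqrt{2T}$) sits near 1.6%, comfortably inside the 5%
recovery band being asserted.  Contact-frequency recovery uses 100 frames
and the designed fractions {0, 0.15, 0.40, 0.50, 0.82, 0.90, 1.0},
mirroring the percentage range a dynamic binding-site analysis reports.
Oracle equivalence for the RIN builder runs on 100 random frames of up to
60 residues and 2 ligand groups against a brute-force all-pairs scan.
Tree inversion uses 200 random additive binary trees of up to 12 leaves.

## Known limitations

* Single-chain polymer analyses; multi-chain structures parse, but
  sequence pairing for transfer assumes one chain per frame.
* No mmCIF, no binary trajectory formats; multi-model PDB is the sole
  structural dialect.
* Contact persistence (lifetimes, autocorrelation) is out of scope; an
  interaction is a per-frame binary event.
* The rigid-residue noise model cannot produce correlated motions, so
  concordance statistics on synthetic data are an upper bound on what
  structured real-world motion would give at equal noise.
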