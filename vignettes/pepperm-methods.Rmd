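---
title: "Multi-level modelling of cyclic peptide membrane permeability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level modelling of cyclic peptide membrane permeability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Head-to-tail cyclic peptides are attractive therapeutics but often permeate
membranes poorly, and passive permeability is hard to predict from
structure: it depends jointly on whole-molecule lipophilicity, on the local
residue composition (N-methylation famously shields backbone hydrogen-bond
donors), and on the conformations the macrocycle can adopt in a membrane
environment. `pepperm` models the common log10 of passive permeability
(cm/s, as measured by PAMPA-style assays) from three coordinated views of
the same molecule:

* **atom level** — the molecular graph and a 3D conformer, consumed by a
  structure-enhanced transformer;
* **monomer level** — the cyclic sequence of residues, each residue
  summarized by 16 physicochemical descriptors, consumed by a 1D
  convolutional network that may treat the sequence as a closed loop;
* **peptide level** — 16 whole-molecule descriptors plus a 2048-bit Morgan
  fingerprint, consumed by a pair of multilayer perceptrons.

The three branch latents are concatenated and passed through a shared
layer that emits the prediction. Only that fused output is used at
inference time; during training each branch additionally carries two
auxiliary losses (below).

## Monomer division and capping

Peptides are decomposed into residue-level monomers by cleaving only the
backbone amide `C(=O)–N` and ester `C(=O)–O` single bonds that lie inside
the macrocycle (the largest ring of at least 9 atoms); bonds outside the
macrocycle — in particular side-chain amides — are never divided. A bare
hydrolysis would create new hydrogen-bond donors and misrepresent the
fragment's physicochemistry, so each cut is capped: the amine nitrogen (or
ester oxygen) receives a methyl group and the acyl carbon becomes an
aldehyde. Units are ordered by walking the macrocycle N→C from the unit
containing the atom of lowest canonical rank, which makes the cyclic order
deterministic without any database annotation. `divide_monomers()` accepts
an explicit monomer annotation instead (e.g. from a HELM-style sequence
plus a monomer library) and passes it through unchanged.

## Atom-level features

Heavy atoms are nodes (hydrogens stay implicit everywhere: features,
coordinates, surface areas). Each atom is a 30-wide one-hot row — atom
type (C/N/O/S/F/Cl/Br/other), heavy-atom degree (1–4/other), bonded
hydrogens (0–4), formal charge (−1/0/+1/other), hybridization
(sp/sp2/sp3-or-other), tetrahedral chirality (none/CW/CCW) — plus in-ring
and aromatic flags. Out-of-vocabulary values land in each block's final
slot, so every block always contains exactly one 1.

Three pairwise matrices describe relative structure:

* `Bond`: 0 for non-bonded pairs, otherwise 1.0 (single), 1.4 (conjugated
  single), 1.5 (aromatic), 2.0 (double), 3.0 (triple). Conjugation
  upgrades only single bonds; aromatic/double/triple bonds keep their
  order weight. This resolves the one ambiguity in the weight vocabulary
  (a conjugated double bond reads 2.0, not 1.4).
* `Graph`: all-pairs shortest path lengths on the bond graph.
* `Conf`: Euclidean distances (Å) from one embedded conformer.

`Graph` and `Conf` are passed through the inverse-distance attenuation
`Strength[i,j] = 1` on the diagonal and `1/d[i,j]` off it. 3D distances
can fall below 1 Å only in pathological embeddings; strengths are clipped
at 1 so the matrix stays in `[0, 1]`. A zero off-diagonal distance between
distinct real atoms is treated as a degeneracy error rather than silently
producing an infinite weight.

## The atom model

Node and bond features are embedded jointly,
`x = (Node W_node + Bond W_bond) / sqrt(d_model)`, so the bond matrix acts
as a learnt *relative* positional encoding. Two parallel encoder blocks —
one attenuated by `Strength(graph)`, one by `Strength(conf)` — each apply
`layers_per_block` encoder layers: multi-head attention whose per-head
probability matrix is multiplied element-wise by the Strength matrix
(without renormalization, so distant pairs genuinely lose influence),
residual + layer norm, a ReLU feed-forward sublayer, residual + layer
norm. Scores are scaled by `sqrt(d_model)` (note: not the per-head
width `sqrt(d_head)` that many transformer implementations use). The two block
outputs are mean-pooled over real atoms, blended as
`(lambda_g * graph, (1 - lambda_g) * conf)` and mapped linearly to the
branch latent. `lambda_g` defaults to 0.5, an untuned midpoint between the purely
topological and purely conformational views; it is worth tuning per
dataset.

Applying Strength element-wise to the probability matrix is the only
composition whose shapes are consistent for every head width, and it
attenuates attention between distant pairs literally; a matrix-product
composition (`Strength %*% multihead`) was considered and rejected.

## The monomer model

Each residue's capped fragment is described by the same 16 descriptors as
the whole peptide; the L×16 matrix (rows in cyclic order, Z-scored) is
placed in a fixed `max_len`-row frame. Convolutions run along the residue
axis with `kernel = 3` by default; `conv_kind = "cyclic"` wraps the
receptive field circularly over the occupied span, treating the peptide as
a closed loop, while `"plain"` sees the zero frame. Pooling is the masked
mean over occupied rows only. Two consequences are worth stating
explicitly:

* appending padded rows never changes the branch output (mask invariance),
  for both convolution kinds;
* at full frame length the cyclic convolution is exactly equivariant to
  sequence rotation, so the pooled output is rotation-invariant.

Because pooling is masked, the *translation* component of the sequence
arrangement augmentation is feature-neutral by construction; rotation is
the component that changes what the network sees. The translation offsets
are retained in the arrangement grid for interface fidelity.

## The peptide model

The 16 whole-molecule descriptors (Z-scored) and the 2048-bit fingerprint
(1024 bits at radius 2 followed by 1024 at radius 3) feed two separate
MLPs; their latents are concatenated and mapped linearly to the branch
latent.

## Fusion and auxiliary losses

With `y` the clipped label and MSE as the loss function, training
minimizes

```
Loss = L_fusion
     + gamma_sub   * (L_atom + L_monomer + L_peptide)
     + gamma_layer * (L_layer_a + L_layer_m + L_layer_p)
```

with `gamma_sub = 0.10` and `gamma_layer = 0.05`. The three sub-model
losses attach linear heads to each branch latent; the three layer losses
attach linear heads to the *mean* of the per-layer pooled representations
of each branch (encoder layers for the atom branch, conv layers for the
monomer branch, the two MLP branch outputs for the peptide branch). These
auxiliary paths inject gradient into every depth of the network; all
parameters demonstrably receive nonzero gradients on a generic batch (this
is a unit test, as is a full finite-difference check of the analytic
backward pass).

## Data augmentation and ensemble inference

Replica `k` of a peptide combines, jointly (not as a cross product):

1. a seeded random atom reordering of the SMILES (node/bond/graph view);
2. a fresh seeded conformer for the peptide (`Conf` matrix + 3D peptide
   descriptors) and for each monomer (monomer descriptor rows);
3. one cell of the rotation × translation arrangement grid, sampled
   without replacement until the grid is exhausted.

All replicas carry the parent's label and are shuffled as independent rows
during training. At inference the prediction is the arithmetic mean over
the replicas of the peptide. Per-replica seeds are hashed from
`(run seed, peptide id, k)`, so generation is reproducible and independent
of dataset order; monomer conformers are keyed by `(capped SMILES, k)` and
shared across peptides, which keeps large cohorts cheap.

The full augmentation scheme generates 60 replicas per peptide
(`build_replicas()` default); the studies in this package's tests use
1–5 replicas, which is where the replica-count curve
is steepest.

## Descriptors: open-source mapping

Several members of the 16-descriptor panel are defined in terms of
descriptors only available in commercial software (MOE); their meanings
are preserved here with open equivalents:

| panel name | here | computed as |
|---|---|---|
| Vsa:EState9 | `VSA_EState9` | RDKit EState/surface-area hybrid |
| density | `density` | MW ÷ additive vdW sphere volume (implicit H included) |
| MolLogP | `MolLogP` | Wildman–Crippen logP (RDKit) |
| fr_Al_OH | `fr_Al_OH` | aliphatic hydroxyl count (RDKit) |
| logP(o/w) | `logP_ow` | OpenBabel additive logP (distinct parameterization; falls back to Wildman–Crippen without `obabel`) |
| lip_violation | `lip_violation` | Lipinski violations from computed MW/logP/HBD/HBA |
| h_logD | `h_logD` | MolLogP − 2 × (carboxylic acids + basic amines), a neutral-fraction penalty at pH 7 |
| dens | `dens3D` | MW ÷ grid-based molecular volume of the conformer |
| FNSA4, FNSA2, FNSA5 | same | fractional charged partial negative surface areas (Stanton–Jurs variants 4/2/5) |
| RNCS | `RNCS` | SASA of the most negative atom × its share of negative charge |
| FASA− | `FASA_neg` | SASA fraction on negatively charged atoms |
| FCASA+ | `FCASA_pos` | positive-charge-weighted SASA fraction |
| FAsa:P | `FASA_P` | SASA fraction on polar (N/O) atoms |
| vsurf_Wp2 | `Wp2` | polar-atom vdW volume surrogate |

Partial charges are Gasteiger charges with hydrogen charges folded onto
their heavy atom; surface areas are a deterministic Shrake–Rupley
computation over heavy atoms (96 golden-spiral points, 1.4 Å probe).
Numerical parity with MOE is explicitly not a goal; what matters for the
model is that the panel spans lipophilicity, polarity and charged surface
chemistry consistently between training and prediction.

`select_descriptors()` reproduces the selection *procedure* on any tagged
descriptor pool: drop constants, prune pairs with `|r| ≥ 0.9` (processed
in descending pair `|r|`, keeping the member better correlated with the
labels; ties break by column order), then rank the survivors by
impurity-based random-forest importance fitted separately on the 2D and 3D
blocks (500 trees, fixed seed).

## Standardization

Z-scoring uses population standard deviations and is always fitted on the
training peptides only; validation and test rows reuse the training
statistics (a leakage unit test asserts that refitting on all data changes
held-out features). The exported `fit_standardizer()` rejects zero-spread
columns; the training pipeline passes `on_constant = "unit"` because some
panel members (e.g. Lipinski violations) are legitimately constant across
all monomer fragments — such columns pass through centred.

## Dataset preparation

Labels are clipped to `[-8, -4]`: −8 is the typical assay detection floor
and the single-compound ceiling is −4. The test set is chosen by the
Kennard–Stone algorithm on fingerprint Euclidean distances (seed with the
maximum-distance pair, then greedily add the sample with the largest
minimum distance to the selected set) so that it covers the structural
space; three mutually disjoint validation folds are drawn at random from
the remainder. Reported study metrics are per-fold; the acceptance studies
run one fold per seed.

## The synthetic study system

Because the package must be testable without any external download, it
ships a generator that emulates database-like records: head-to-tail
macrocycles of 5–12 monomers drawn uniformly from a 26-entry alphabet (14
natural amino acids, 7 N-methylated, 5 D-variants; molecular weights span
roughly 450–1550). The ground-truth label is

```
label = clip(-6.5 + 0.8 z(logP) - 0.5 z(TPSA) - 0.4 z(HBD) + eps, -8, -4),
eps ~ N(0, 0.3^2)
```

with z-scores over the generated cohort. The drivers and signs mirror what
is known about passive permeability (lipophilicity helps; polar surface
area and H-bond donors hurt), make the label learnable from the peptide
branch and meaningfully coupled to N-methylation through the monomer
composition, and leave an irreducible noise floor of 0.3 log units.
What passing the recovery study shows is that the pipeline can extract a
permeability-like structure–property relationship end to end; it does
*not* show real-assay accuracy — the generator has no assay
heterogeneity, no conformation-dependent label component, and no
activity cliffs.

Proline-like monomers (side chains closing onto the backbone nitrogen) are
excluded from the alphabet because the textual head-to-tail assembly
reserves the backbone ring closure; this is a generator limitation, not a
featurization one (records with such residues still featurize through
`divide_monomers()`).

## Numerical and runtime choices

* **Conformers.** Embeddings are seeded distance-geometry runs followed by
  UFF minimization capped at 200 iterations, with up to 5 attempts per
  conformer and a random-coordinate fallback from the third attempt. The
  default method is the plain experimental-torsion variant (`etdg`): on
  current RDKit builds the knowledge-enhanced variants take from several
  seconds to nearly a minute per 10–12-residue macrocycle on one CPU,
  which is incompatible with conformer-ensemble augmentation at cohort
  scale; the plain variant embeds the same macrocycles in well under a
  second and, after UFF minimization, yields geometries adequate for
  distance matrices and surface-area descriptors. `method =` selects the
  other variants where quality matters more than throughput.
* **Optimizer.** Adam (`lr 1e-3`, β 0.9/0.999), minibatch 32, early
  stopping on validation MAE with patience 10; the best-epoch parameters
  are restored. All randomness (initialisation, shuffling, dropout,
  conformers, arrangements) derives from explicit seeds via a 31-bit
  FNV-1a hash shared between R and the Python helper.
* **Study sizes.** The package defaults are `d_model 64, 4 heads, 2
  layers/block, ffn 128, channels (32, 32), latent 32`. The acceptance
  studies in `tests/testthat/test-acceptance.R` and
  `scripts/acceptance.R` use a documented lighter model (`d_model 32, 1
  layer/block, ffn 64`) and 1–5 replicas on cohorts of 32–500 peptides;
  these sizes are the package's chosen study conditions for a single-CPU
  run and are stated here once rather than repeated in the tests.
* **Degenerate inputs.** Disconnected molecules, empty SMILES, oversized
  molecules (> 128 heavy atoms), zero-spread standardizer columns,
  zero-distance atom pairs and unsatisfiable selections all raise typed
  conditions (`pepperm_input_error`, `pepperm_size_error`,
  `pepperm_chem_error`, `pepperm_degeneracy_error`, ...).

## Open design choices made here

* The attention–Strength product is applied element-wise per head without
  renormalization (shape-consistent and literal; see above).
* Layer losses use mean-pooled per-layer representations — the natural
  mask-safe readout.
* Monomer standardization is fitted jointly over all monomer rows rather
  than per sequence position.
* Arrangements are sampled without replacement until the rotation ×
  translation grid is exhausted, then with replacement.
* The cyclic order of divided monomers starts at the unit containing the
  atom of lowest canonical rank and proceeds N→C.
* SMILES enumeration is a seeded uniform atom permutation re-rendered
  non-canonically; for fully symmetric molecules (benzene) all renderings
  coincide — the enumeration invariants are therefore tested on molecules
  with distinguishable atoms.

## Known limitations

* Chemistry runs out of process through a bundled RDKit helper; each
  call spawns an interpreter, so the API batches whole cohorts per call
  and per-molecule calls cost ~0.2 s of overhead.
* The network is plain R; it is comfortably fast for desk-scale studies
  (tens of milliseconds per replica-epoch) but not for database-scale
  training.
* Only head-to-tail (and backbone-ester) macrocycles are divided;
  disulfide or side-chain-bridged topologies are out of scope.
* `h_logD` is a two-group ionization penalty, not a pKa model; `Wp2` is a
  composition-level surrogate for a volumetric polar-field descriptor.
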