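---
title: "Predicting reaction barriers from 3D structures: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting reaction barriers from 3D structures: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxn3d)
```

## The problem

Activation barriers (ΔE‡ or ΔG‡, kcal/mol) are the energy difference between
an optimized transition state and the optimized reactants.  Computing them
quantum-chemically is expensive; predicting them from quantities that are
cheap to obtain — the 3D structures of reactants and products, and possibly
an atom map linking their atoms — is the regression task this package
addresses.  The barrier is not a direct function of those inputs (the
transition state is absent by design: using it would defeat the purpose), so
the model learns an implicit interpolation between the reactant and product
geometries.

## Molecular channels

Each molecule is a radius graph: nodes are atoms, and directed edges connect
every atom to its neighbors within the cutoff `r_max`, capped at the
`n_neigh` nearest (ties broken by atom index) and then symmetrized so the
edge set is closed under reversal.  Initial features are

* **node descriptors** `x_a(0)`: 16 cheminformatics descriptors (atomic
  number, chirality class, bonded-neighbor count, ring counts and size-3..7
  flags, implicit valence, formal charge, attached hydrogens, unpaired
  electrons, hybridization class, aromaticity, and a generic in-ring flag in
  the reserved sixteenth slot).  They come from the SMILES-derived graph
  when one is matched, otherwise from covalent-radius bond perception on the
  coordinates alone.
* **radial edge features** `e_ab(0)`: `n_g` Gaussians with centers uniformly
  spaced on `[0, r_max]` and width equal to their spacing, multiplied by a
  smooth cosine cutoff envelope vanishing at `r_max` so messages switch off
  continuously as atoms cross the cutoff.  The envelope sits upstream of
  the learned radial filters on purpose: the filter network can then
  re-amplify attenuated near-cutoff shells during training, whereas an
  envelope applied to the filter output caps those shells untrainably
  (moving it there cost an order of magnitude of held-out accuracy on the
  synthetic benchmark, whose second coordination shell sits at 0.9 of the
  cutoff).  The expansion is symmetric in the edge direction, smooth in
  the distance, and isolated behind one function so another basis can be
  swapped in.
* **spherical-harmonic filters** `z_ab`: real spherical harmonics of the
  edge direction with unit mean-square components, up to degree 2 in the
  equivariant variant and degree 0 (a constant) in the invariant one.

`n_conv` convolution layers update the node features.  Each layer forms, for
every edge, the tensor product of the neighbor's features with the edge's
spherical-harmonic filter, contracted through real Clebsch–Gordan couplings
into the output degrees (scalars, plus degree-1 vectors in the equivariant
variant), channelwise, with a per-edge, per-path, per-channel weight
produced by a two-layer perceptron on the edge features.  Messages are
aggregated per receiving node, mixed across channels by a learned linear
map per degree, combined with a learned self-interaction, and passed
through a silu nonlinearity (scalars) or sigmoid gates driven by the scalar
channels (vectors; gating preserves equivariance).  The Clebsch–Gordan
tensors are computed once per degree triple as the one-dimensional
invariant subspace of the triple Kronecker product of real Wigner matrices
over a fixed rotation set, and cached.

Rotating the input coordinates leaves the invariant variant's features
numerically unchanged and transforms the equivariant variant's degree-1
blocks by the rotation matrix; the scalar output is rotation invariant in
both.  Translation invariance holds trivially (only relative vectors enter).

**Aggregation.**  Messages are summed and divided by a fixed constant
(sqrt(10), a typical neighbor count), not averaged per node.  A per-node
mean erases the number of neighbors from the representation, and additive
per-atom targets — including the package's synthetic ground truth, which is
a function of coordination counts — then become unlearnable in principle.
The constant keeps activations of one scale across `r_max` choices;
`aggregation = "mean"` remains available for comparison.

**Hydrogen exclusion.**  With `exclude_h` (the default), hydrogens are
removed as graph nodes; their information survives in the attached-hydrogen
count descriptor of the heavy atoms.  This matches common practice for
barrier datasets, where hydrogens are implicit in the SMILES, often
unmapped, and their explicit inclusion does not help consistently.

The per-atom output is the local representation `X` (dimension `n_s`, plus
the mean-pooled incident edge embeddings when `sum_mode = "both"`).

## Combining molecules into reactions

One encoder, one set of weights, processes every molecule of both sides;
sharing makes the difference-mode identities exact and halves parameters.
Three mapping variants connect the sides:

* **M** (atom-mapped): product rows are reordered so row *i* is the product
  atom mapped to reactant atom *i*; requires a balanced reaction and a
  complete map over retained atoms.
* **X** (cross-attention): single-head scaled dot-product attention with
  reactant queries over product keys/values replaces the map.  It is
  implemented for completeness and deliberately not tuned; the mapping-free
  variant is the recommended default when maps are absent.
* **S** (mapping-free): each side is pooled globally; no correspondence is
  used.

`combine_mode` merges the two sides (difference, sum, mean, or an MLP on
the concatenation).  Two readouts produce the scalar:

* **vector**: per-atom MLP, sum over atoms into a global reaction vector,
  final MLP.
* **energy**: a per-atom MLP predicts atomic contributions ("quasi-molecular
  energies" per side in variant S) that are summed and combined.  The
  energy MLP is *centered*: the contribution is `g(x) − g(0)`, so a zero
  reaction representation contributes exactly zero while the MLP keeps its
  hidden biases.  A fully bias-free MLP has the same exact-zero property
  but optimizes badly (sign-gradient stalls); centering keeps the identity
  `identity reaction → prediction exactly 0.0` for M/diff/energy and
  S/diff/energy without paying that cost.

Targets are standardized by the training set and the scaling is inverted
at prediction time.  For diff-combined energy readouts the standardization
is scale-only (divide by the standard deviation, no centering): the model
output E_p − E_r is structurally closed under no constant shift — a
constant per-atom energy cancels between balanced sides — so mean-centering
would ask the network to fabricate a constant out of incidental
reactant/product asymmetries, which measurably hurts generalization and
would also break the exact identity-reaction zero.  Heads with output
biases (vector mode, non-diff combines) use the full z-score.

## Dataset curation

Reaction records arrive as xyz files plus a reaction SMILES.  For every
molecule the covalent-radius graph of the structure (Cordero-style radii,
tolerance 0.4 Å, both configurable) is matched to the SMILES graph by
labelled VF2 isomorphism — on the heavy-atom skeletons with
attached-hydrogen counts as an extra color when the SMILES hydrogens are
implicit.  Hydrogens are assigned per heavy atom by count, not
individually, and the whole procedure is unaware of chirality and
double-bond stereochemistry, so enantiomeric assignments can be wrong; that
is a known limitation inherited from the matching approach.  Records whose
molecules all match are kept; failures are reported per record with a
reason and never abort the batch.  When several isomorphisms exist the
first under the deterministic VF2 ordering is used, so runs are
reproducible.  Atom maps are treated as opaque keys (they need not be
contiguous), and composing SMILES maps with the per-molecule permutations
yields the record-level atom map.

Reaction-type signatures compare the connectivity matrices over mapped
atoms, ignoring bond orders: bonds only in the products contribute formed
labels (`+C-H`), bonds only in the reactants broken labels (`-C-H`);
element pairs are ordered alphabetically, formed labels sort before broken,
and the comma-joined string is canonical (ASCII-internal, with an en-dash
display form).

## Splits

Ten folds of 80/10/10 train/validation/test splits, each seeded.  Besides
random splits there are three extrapolation splits: scaffold (records
grouped by the element-retaining ring-system framework of the designated
side's molecules — terminal atoms pruned iteratively, remainder
canonicalized; groups shuffled by seed and packed greedily into train, then
validation, then test, so no scaffold ever spans two partitions; acyclic
molecules share the empty scaffold), size (sorted by reactant-side
heavy-atom count; a seeded shuffle breaks ties, so constant sizes reduce to
the random split), and property (sorted by target, training on high
barriers and testing on low; reverse orderings available for both).

## Training protocol

Adam on z-scored targets; the learning rate is cut by 40% (factor 0.6)
after 60 epochs without validation-MAE improvement, training stops after
150 stagnant epochs or 512 epochs total, and the returned model is the one
from the best-validation epoch, not the last.  Any strict decrease counts
as improvement.  Minibatch composition is fixed by an initial seeded
shuffle and batch order is reshuffled every epoch, which keeps runs
bit-reproducible per seed.

The default objective is the Huber loss (quadratic within one standard
deviation of the standardized target, L1 beyond).  Pure L1 matches the MAE
selection criterion but its constant-magnitude gradients prevented Adam
from closing the last factor of ~2 on noise-free fits at the largest
admissible learning rate; Huber keeps L1's robustness to outliers with a
usable gradient near the minimum.  `loss = "l1"` and `"l2"` are available.

The hyperparameter search space is: learning rate {5e-5, 1e-4, 5e-4,
1e-3}; weight decay {1e-5, 1e-4, 1e-3, 0}; `n_s`, `n_v`, `n_g` each {16,
32, 48, 64}; `n_conv` {2, 3}; `r_max` {2.5, 5, 10} Å; `n_neigh` {10, 25,
50}; dropout {0, 0.05, 0.1}; `sum_mode` {node, both}; `combine_mode` {mlp,
diff, mean, sum}; `graph_mode` {energy, vector}.  `sweep_random()` samples
it uniformly and scores configurations by first-fold validation MAE under
a reduced epoch budget (the budget is a parameter), standing in for an
external Bayesian-search service.  The package defaults (`r_max` 2.5 Å,
`n_neigh` 25, `n_g` 16, `n_s` 32, `n_conv` 3, dropout 0, node mode, diff
combine, energy readout, lr 1e-3, weight decay 0, batch size 8) were fixed
once, by validation error on the first random split of the synthetic
benchmark — the same first-split rule the sweep tool applies — and are not
revisited per run.

## Synthetic fixtures

Tests and the acceptance script need inputs with known ground truth and no
downloads; the `synthetic_fixtures` functions provide three.

**Homometric pair.**  Two four-atom He arrangements sharing the full
multiset of six pairwise distances while not being related by any rotation,
translation or reflection (verified by optimal superposition over all 4!
correspondences).  The second structure re-assigns the distances of the
first to different atom pairs and re-embeds them from the Gram matrix.
Collinear constructions (such as 0,1,4,6 vs 0,2,5,6) fail this purpose:
x → 6−x shows they are mirror images, and a 1D mirror is a proper rotation
in 3D.  The pair defeats any featurization that depends on the global
distance multiset alone, while per-atom message passing distinguishes some
atoms — the mechanism behind the invariant model's partial
distinguishability.

**Angle probe.**  A central atom with three neighbors at distance r = 1.5 Å,
trigonal-planar versus pyramidal (apex angle 70°), with all
neighbor–neighbor distances above 1.9 Å.  With a radial cutoff below the
neighbor–neighbor distances, the central atoms' within-cutoff *distance*
environments coincide at every message-passing depth, so the invariant
channels cannot separate the two structures at any depth, while the
equivariant channels see the differing angular arrangement from the first
layer on (the planar arms' degree-1 harmonics sum to zero; the pyramid's
do not).  One subtlety is worth recording: for this maximally symmetric
probe the *scalar* block of the central atom is provably identical at
depth 2 in any channelwise tensor-product network — each isolated
neighbor's degree-1 feature is exactly parallel to its edge, so the
degree (1,1)→0 contraction at the center reduces to a
configuration-independent constant, and degree-2 filters cannot write
into scalars from scalar inputs.  The angular signal first reaches the
central scalars at depth 3 (center degree-1 → neighbor scalars at layer
2 → center scalars at layer 3), and at initialization that three-hop
signal is numerically minute.  The distinguishability checks therefore
compare the full degree-structured local representation per block: the
central atom's degree-1 block is exactly zero for the planar structure
and nonzero for the pyramidal one from the first layer on, so the
equivariant channels separate the pair at depth 2 with a per-block
relative difference of order one, deterministically, while the invariant
channels (whose representation has no higher-degree block to look at)
remain identical at every depth.  Richer environments (neighbors with
several neighbors of their own, as in the homometric pair) do not have
the scalar-block degeneracy.

**Additive reaction sets.**  Reactant molecules are connected random walks
on a cubic lattice (spacing 1.6 Å) with Gaussian positional jitter
(σ = 0.06 Å); the element alphabet is {C, N, O}; a side has one or two
molecules.  The product *is* the reactant structure with one localized,
lattice-preserving perturbation — an atom relocated to a free adjacent
site, or two different-element atoms exchanging positions — under an
identity atom map.  The target is the product-minus-reactant difference of
additive atomic energies f(element, coordination number within 2.5 Å),
drawn once per dataset from a seeded table and emitted alongside, plus
Gaussian noise σ.  The lattice constants put the occupied-site shells at
1.6, 2.26 and 2.77 Å, each ≥ 0.24 Å from the 2.5 Å counting radius, so
coordination numbers are a stable function of the lattice under jitter —
mirroring how bonded and non-bonded contacts are separated in relaxed
molecules.  (An early draft jittered more aggressively around a 1.5 Å
lattice, which put the cube diagonal within jitter range of the counting
radius; held-out targets then hinged on razor-thin threshold crossings and
no model could generalize.  Well-posedness of the ground truth, not model
convenience, dictated the lattice.)

What the generator does *not* emulate: chemically valid valences, bond
orders, conformational flexibility, long-range interactions, unbalanced
reactions, or any quantum-chemical structure in the targets.  Passing the
recovery tests therefore demonstrates that the pipeline can identify an
additive, geometry-local ground truth from reaction-level supervision — not
that it reaches any particular accuracy on real barrier datasets.

## Numerical choices and degenerate inputs

* Coincident atoms (distance < 1e-8 Å) are rejected when building radius
  graphs; spherical harmonics of a zero vector are undefined.
* An isolated atom has no edges; its convolution output is its
  self-interaction, and empty edge pools are zero.
* Distances beyond `r_max` may not reach `radial_edge_features` (edges
  beyond the cutoff must not exist); this is an error, not a clamp.
* Neighbor-cap ties are broken by atom index; VF2 returns its first
  isomorphism under a deterministic ordering; scaffold groups are packed in
  seed-shuffled order — all so that identical seeds give identical runs.
* The Clebsch–Gordan solver verifies that the invariant subspace it
  extracts is one-dimensional and fails loudly otherwise.
* Parameters are initialized from scaled Gaussians under the caller's seed;
  `run_folds` derives fold seeds as base + fold − 1.

## Known limitations

* Unbalanced reactions are rejected (variant M needs a bijection).
* Stereochemistry is invisible to the SMILES–xyz matching and to the
  SMILES parser's descriptor extraction (chirality tags are read but not
  geometrically verified).
* The SMILES parser covers the organic subset, bracket atoms, ring
  closures and dots — not reaction agents (`>agent>`), wildcard atoms, or
  polymers.
* Internal features stop at degree 1; filters at degree 2.  Higher-order
  messages are out of scope.
* The cross-attention variant is single-head and unidirectional by design.
* Training is single-device, dense R linear algebra; problem sizes in the
  tests (up to 500 reactions of ≤ 16 atoms per side, ≤ 512 epochs) reflect
  what that comfortably supports.

## A worked example

```{r example, eval = FALSE}
synth <- make_synthetic_reactions(synthetic_spec(n_reactions = 500,
                                                 sigma = 0.1, seed = 101))
model <- withr::with_seed(11, rxn3d_model(
  graph_config(), channel_config("invariant"),
  head_config("S", "diff", "energy")))
part <- random_split(length(synth$records), split_spec("random", seed = 1))
fit <- train_model(model, synth$records, part, train_config(seed = 1))
evaluate_model(fit$model, synth$records[part$test])
```

The same pipeline runs from files (xyz + manifest) through
`curate_dataset()`, and from the shell through the `inst/cli/rxn3d`
script.
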