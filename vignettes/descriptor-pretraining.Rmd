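---
title: "Descriptor-guided pre-training for reaction yield prediction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-guided pre-training for reaction yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

High-throughput experimentation (HTE) datasets for Pd-catalysed
cross-coupling chemistry pair a few thousand reactions with measured
yields (0--100%).  A graph neural network can regress yield directly from
the reactant and product structures, but with small training sets it
overfits badly.  `ginyield` implements a transfer-learning remedy: give
the molecule encoder a chemistry-aware starting point by first teaching
it to predict classical 2D molecular descriptors, which are cheap to
compute for millions of unlabelled molecules.

The pipeline has three phases:

1. **Pseudo-labelling.**  Compute a 2D descriptor vector per molecule,
   filter and standardize it, project it onto the leading `q` principal
   components, clip and re-standardize the scores.  The resulting
   `q`-vector `z` is the molecule's pseudo-label; the PCA eigenvalues
   `lambda_j` record how much descriptor variance each dimension carries.
2. **Pre-training.**  A graph isomorphism network (GIN) encoder plus a
   one-layer auxiliary head is trained to predict `z` under the
   eigenvalue-weighted loss `(1/q) * sum_j lambda_j (z_j - zhat_j)^2`, so
   high-variance descriptor directions dominate the signal.
3. **Fine-tuning.**  The pre-trained encoder initialises a yield model
   that encodes every reactant and the product with shared weights,
   sum-pools the reactant representations, concatenates the product
   representation, and outputs a predictive mean and variance
   `(mu, sigma^2)`.  Training minimises
   `(1 - alpha) (y - mu)^2 + alpha [ (y - mu)^2 / sigma^2 + log sigma^2 ]`,
   and inference averages 30 Monte-Carlo-dropout forward passes.

## Molecular graphs

`featurize_molecule()` converts a SMILES string into a heavy-atom graph.
Open Babel is the parsing authority (sanitization, canonicalization,
kekulized bond orders, formal charges, hybridization-typed atoms); a
light tokenizer over the canonical SMILES supplies the annotations the
exchange formats do not carry (aromatic flags, chirality tags,
directional-bond E/Z assignments), and its connectivity is cross-checked
against the bond table on every molecule.  Hydrogens never appear as
nodes; they enter through the adjacent-hydrogen-count feature.  Each
bond is stored as two directed edges with identical features so the
message-passing sum can index incoming edges directly.

Encoding choices the source architecture leaves open, fixed here once:

* **Element vocabulary** -- common organics (C, N, O, S, P, halogens, B,
  Si) plus the metals of cross-coupling chemistry (Pd, Fe, Sn, K, Na, Cs,
  Li, Mg, Cu, Zn) and a trailing "other" bucket, so unseen elements never
  hard-fail.  Configurable and serializable via `write_feature_schema()`.
* **Ring sizes** -- membership flags for sizes 3--8, found by a bounded
  cycle search over the non-bridge subgraph.
* **Donor/acceptor** -- rule-based: N/O with an attached hydrogen donates;
  N/O with a lone pair (i.e. not a quaternary/positively saturated
  nitrogen) accepts.
* **Counts** -- degree, valence and H-count are one-hot over 0--6 with an
  overflow bucket.
* **Stereo** -- bond categories {none, Z, E, cis, trans, any}; E/Z is
  assigned from directional SMILES bonds flanking a double bond; a double
  bond with markers on only one side is "any".  Atom chirality is
  {none, CW, CCW, other} from the `@`/`@@` tags.
* **Conjugation** -- a bond is conjugated when both end atoms are
  pi-capable through some bond other than the one in question (or via a
  lone pair on N/O/S) and both are sp/sp2.  This marks aromatic systems,
  dienes' central bonds, amides and esters; it deliberately does not mark
  an isolated double bond.

## The descriptor engine

The reference descriptor calculator for this family of methods is a
large external Python program.  `ginyield` ships its own
deterministic 2D engine instead (131 descriptors): constitutional
counts, ring statistics, Zagreb/Randic/Kier-Hall connectivity indices,
distance-matrix topological indices (Wiener, Balaban J, eccentric
connectivity), element/degree information content, Moreau-Broto
autocorrelations over five atomic weightings and six lags, Burden
-eigenvalue bounds, and Gasteiger partial-charge summaries.  The registry
is fixed and enumerable (`descriptor_names()`); undefined values (e.g.
distance indices on disconnected structures, charge summaries when the
charge model fails) are `NA`, never silently zero.  The set is smaller
than the external reference but spans the same families, and, on the
synthetic study conditions below, leaves the pre-training task just as
well-posed: the filtering, standardization and PCA contracts are
identical.

Filtering follows a fixed order -- a deliberate decision, since the order
is otherwise ambiguous: (1) drop descriptors with more than
`missing_threshold` (default 10, an absolute count) missing values; (2)
drop descriptors whose non-missing values are all identical; (3) exclude
molecules still missing a retained descriptor; (4) standardize to mean
0 / SD 1.  Standardization uses the population SD (divide by `n`); the
difference from the sample SD is immaterial at corpus scale but must be
fixed for exact replay, and `apply_standardization()` replays the stored
statistics on new molecules without ever refitting.

## PCA pseudo-labels

`fit_pseudo_labeler()` takes the eigendecomposition route through
`prcomp` (SVD of the centred matrix; identical eigenpairs to a dense
covariance eigendecomposition, which the test suite verifies against an
independent oracle at 1e-8).  `q` is the smallest component count whose
cumulative explained variance reaches the target (default 70%); an
explicit `q` override is available.  Because PCA signs are arbitrary,
each component is flipped so its largest-magnitude loading is positive --
purely a determinism convention.

Scores are clipped at plus/minus 10 times the per-dimension fitting-set
score SD.  The clipping scale uses the empirical score SD rather than
`sqrt(lambda_j)`; the two differ only by the `n/(n-1)` factor, but one
had to be chosen.  Post-clipping means/SDs (population) are stored so
re-standardization replays bit-identically.  Clipping is a no-op on
well-behaved corpora; it exists to keep rare extreme molecules from
dominating the weighted loss.

## The GIN encoder

Widths follow the reference recipe: node/edge embedders to width 300
(ReLU / linear), `L = 3` two-layer update networks (300, ReLU hidden,
ReLU output except linear at the last layer), mean pooling, and a
projection to a 1,024-wide representation with a learnable PReLU.

The message-passing update deserves a note.  As printed, the update sums
`ReLU(h_j + e_jk)` over the edges of node `j` -- the *center* node's own
embedding inside every message, which makes messages independent of the
neighbours and cannot propagate information.  The architecture this
design cites uses the *neighbour's* embedding `h_k`.  `ginyield`
implements the neighbour form as the default (`message_mode =
"neighbor"`) and keeps the literal form behind a switch
(`"literal"`) for comparison; this is the single most consequential
reading decision in the package.

Other encoder decisions: edge embeddings are computed once and shared
across layers (one `phi_e` is defined); no batch normalization; dropout
(default rate 0.1) is applied to each update network's hidden layer and
to the final representation -- a placement choice needed so that
Monte-Carlo dropout has stochasticity to exploit at inference; weights
are initialised uniform in `[-1/sqrt(fan_in), 1/sqrt(fan_in)]` under a
fixed seed.

The forward and backward passes are hand-written dense linear algebra
(BLAS matrix products plus `rowsum` scatter-adds over a node-batched
layout).  The backward pass is verified against central finite
differences in the test suite (agreement to ~1e-11 relative error).

## Training recipes

Pre-training: 10 epochs of Adam, batch 128, learning rate 5e-4, weight
decay 1e-5 (L2 added to the gradient), eigenvalues entering the loss raw
(a normalized option exists but is off by default), no validation split
or early stopping, minibatches reshuffled each epoch under the run seed,
no gradient clipping or warmup.

Fine-tuning: Adam with batch 128 and weight decay 1e-5 over 500 epochs;
the learning rate starts at 5e-4 and drops to 5e-5 and 5e-6 at epochs
400 and 450.  Shortened runs drop schedule stages beyond the configured
epoch count.  The mixing weight `alpha` of the loss is never stated
numerically by the source; the default here is 0.1, exposed prominently,
and all loss unit tests parameterize over `alpha`.  Yields are
standardized on the training split before the loss is computed (the
`log sigma^2` term is much better behaved at unit scale) and predictions
are mapped back to percent; a raw-percent mode exists.  The variance is
parameterized as `exp(log sigma^2)`, so positivity holds by
construction.

Initialization from a checkpoint copies the encoder weights bit-for-bit
and never loads the auxiliary pre-training head (it exists only for the
pre-text task); the reaction head -- sum-pooled reactant representations
concatenated with the product representation, one 1,024-wide PReLU
hidden layer with dropout, two outputs -- is always freshly drawn.  The
head's exact depth/width is a documented stand-in: the source defers its
architecture to earlier work without layer-by-layer detail, and only the
order-invariant set aggregation is forced.

Monte-Carlo inference runs `T = 30` stochastic passes and averages the
per-pass means, which is exactly the prescribed prediction rule.  The
across-pass mean of the predicted variances is also reported
(`.pred_var`) but is an extension, kept clearly separate.

## The synthetic study conditions

Real pre-training corpora (millions of molecules) and the HTE benchmark
tables are out of reach for an offline test suite, so the package
carries a generator whose defaults define the study conditions used by
the tests and the acceptance script: 500 molecules (up to 12 heavy
atoms, from a fragment grammar of substituted aromatic/aliphatic cores
with halide, amine, ether, nitrile, boronic-acid-like substituents), 300
reactions with 2--4 reactants and one product drawn from the pool, yield
noise SD of 5 percent points.  Yields follow a fixed logistic surface in
graph-level covariates (mean reactant heavy-atom count, product ring
count, heteroatom fraction, product aromaticity) -- quantities the
descriptor set captures directly, so descriptor-guided pre-training is
informative for the synthetic task *by construction*.  An optional
heteroscedastic mode grows the noise SD with the participants' total
size, exercising the variance head (with `alpha = 1` the fitted
`sigma^2` tracks the generating noise across size terciles; tested
directionally over five seeds).

What the generator does *not* emulate: real reaction chemistry (the
product is a random pool molecule, not a transformation of the
reactants), reagent-role structure (catalyst/ligand/base), correlated
experimental error, or the scale and diversity of real corpora.  Passing
tests therefore demonstrate that the machinery is correct and that the
method's transfer mechanism works when descriptors are informative --
not that the published benchmark numbers are reproduced; those require
the external datasets and full-scale pre-training.

Problem sizes used by the suite and acceptance script (chosen as the
smallest sizes at which the directional transfer effect is visible above
seed noise): pre-training on the full 500-molecule corpus for the
prescribed 10 epochs; fine-tuning comparisons at `n_train = 100`
reactions for 20--30 epochs with batch 32; evaluation on 100 held-out
reactions; five seeds for directional claims.

## Numerical and degenerate-input choices

* Isolated nodes receive a zero neighbour sum (not an error); single-atom
  molecules are legal throughout.
* Disconnected molecules (salts written with `.`) are one graph; their
  distance-based descriptors are `NA` and fall to the missing-value
  filter.
* `R^2` is reported as `NA` when the truth is constant (SST = 0).
* A non-finite training loss aborts with the offending batch identified,
  rather than training on.
* Split sizes use `floor(train_fraction * N)`; published shuffle orders,
  when supplied, are used verbatim instead of the internal permutation.
* Checkpoints validate their manifest (schema dimensions, layer count,
  widths, message mode) before loading and refuse mismatches with a
  field-by-field diff.

## Known limitations

* The descriptor registry is a native reimplementation of the classical
  2D families, not the much larger external reference calculator;
  absolute descriptor counts and any result tied to that exact registry
  do not transfer.
* Stereochemistry coverage is pragmatic: E/Z from directional bonds and
  tetrahedral tags from the SMILES; ring cis/trans and more exotic
  stereo-centres fall into the "any"/"other" buckets.
* The conjugation and donor/acceptor rules are documented approximations,
  not a full perception algorithm.
* Training is CPU-bound dense linear algebra; it is sized for
  desk-scale corpora (hundreds to thousands of molecules), not for
  millions.
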