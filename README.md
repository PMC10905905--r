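# ginyield

Descriptor-guided pre-training of graph isomorphism networks (GINs) for
chemical reaction yield prediction, in R.

## Who this is for, and what it does

Predicting the yield of a reaction (the percentage of product obtained,
0–100%) from the structures of its reactants and product is a standard
regression task on high-throughput-experimentation (HTE) datasets such as
the Pd-catalysed Buchwald–Hartwig and Suzuki–Miyaura benchmarks.  Graph
neural networks handle the molecular-graph inputs well but overfit when
labelled reactions are scarce.  `ginyield` implements a transfer-learning
pipeline that pre-trains the molecule encoder on an *unlabelled* corpus
before fine-tuning on yields:

1. **Pseudo-labelling.**  Every molecule gets a vector of 2D molecular
   descriptors **d** (a native, deterministic registry of 131
   constitutional, topological, autocorrelation, information and charge
   descriptors).  After filtering (drop descriptors with > 10 missing
   values or constant values; exclude molecules still missing one) and
   standardization, PCA reduces the matrix to the *q* leading components
   reaching 70% explained variance; the scores **z** = (u₁ᵀd, …, u_qᵀd)
   are clipped at ±10 SD, re-standardized, and become the molecule's
   pseudo-label.

2. **Pre-training.**  A GIN encoder (3 message-passing layers of width
   300, mean pooling, 1,024-wide PReLU projection) plus a one-layer head
   is trained to predict **z** under the eigenvalue-weighted loss

       L̃(z, ẑ) = (1/q) Σⱼ λⱼ (zⱼ − ẑⱼ)²,

   where λⱼ is the j-th PCA eigenvalue — components carrying more
   descriptor variance get proportionally more training signal.
   (10 epochs, Adam, batch 128, LR 5·10⁻⁴, weight decay 10⁻⁵.)

3. **Fine-tuning.**  The pre-trained encoder initialises a yield model
   f(ℛ, 𝒫) → (μ̂, σ̂²): every reactant and the product are encoded with
   shared GIN weights, reactant representations are sum-pooled
   (order-invariant), concatenated with the product representation, and a
   prediction head outputs the mean and log-variance.  Training minimises

       L(y, μ̂, σ̂²) = (1 − α)(y − μ̂)² + α[(y − μ̂)²/σ̂² + log σ̂²],

   with a staged LR schedule (5·10⁻⁴ → 5·10⁻⁵ @ 400 → 5·10⁻⁶ @ 450 over
   500 epochs).  Inference averages T = 30 Monte-Carlo-dropout passes.

Everything is testable offline: a synthetic generator produces valid
molecules from a fragment grammar and reactions whose yields follow a
fixed smooth function of graph-level covariates, so descriptor-guided
pre-training is provably informative on the synthetic task.

## Worked example

```r
library(ginyield)
library(dplyr)

# synthetic corpus: 500 molecules, 300 reactions (the package's study
# conditions; swap in your own SMILES list / reaction CSV via
# featurize_smiles() / load_reaction_csv())
corpus <- generate_synthetic_corpus(synthetic_spec(seed = 1))

# phase 1: descriptors -> filter -> PCA pseudo-labels
desc    <- compute_descriptors(corpus$molecules, "smiles")
fs      <- filter_and_standardize(desc)
labeler <- fit_pseudo_labeler(fs$data, explained_variance_target = 0.70)
labeler
#> <pseudo_labeler> q = 5 of p = 122 descriptors (72.5% variance explained)
labels  <- make_pseudo_labels(labeler, fs$data)

# phase 2: pre-train the GIN on the pseudo-labels
mols <- featurize_smiles(corpus$molecules, "smiles") %>%
  inner_join(labels, by = c("smiles" = "molecule"))
attr(mols, "eigenvalues") <- attr(labels, "eigenvalues")
fit <- run_pretraining(mols, config = pretrain_config(epochs = 10, seed = 1))
glance(fit)
#> # A tibble: 1 x 4
#>       q epochs initial_loss final_loss
#>   <int>  <int>        <dbl>      <dbl>
#> 1     5     10         17.9       7.77

# phase 3: fine-tune on 100 reactions, evaluate on held-out reactions
rx    <- featurize_reactions(corpus$reactions)
split <- make_split(rx, "random_ratio", train_fraction = 1/3, seed = 1)
model <- run_finetuning(rx[split$train, ],
                        init_yield_model(pretrained = fit, head_init_seed = 1),
                        finetune_config(epochs = 30, batch_size = 32, seed = 1))
pred  <- predict_mc_dropout(model, rx[split$test[1:100], ], passes = 30, seed = 2)
evaluate_predictions(pred)
#> # A tibble: 1 x 3
#>    rmse   mae    r2
#>   <dbl> <dbl> <dbl>
#> 1  13.4  10.7 0.275
```

The printed numbers mean: the pre-training loss fell from 17.9 to 7.8
over 10 epochs (the encoder learned the descriptor principal
components), and the fine-tuned model predicts held-out synthetic yields
with an RMSE of ~13 percent points (R² ≈ 0.28) from only 100 training
reactions.  Averaged over several shuffles, a from-scratch
initialisation of the same architecture under the same budget has a
higher test RMSE — the package's headline property, recomputed by
`scripts/acceptance.R` below.

Result objects are tidyverse-friendly: `tidy()` returns per-epoch loss
histories or PCA spectra, `glance()` one-row summaries, `autoplot()`
loss curves and scree plots, and `plot_predictions()` an
observed-vs-predicted scatter.

A thin command-line wrapper over the same functions is installed at
`inst/cli/ginyield.R` with subcommands `synth`, `pseudolabel`,
`pretrain`, `finetune`, `predict`, `evaluate`; every artifact gets a
JSON sidecar manifest (resolved config, input digests, seed).

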