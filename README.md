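# DIPK — drug response prediction integrating gene interaction networks, expression and molecular graphs

Predicting how strongly a drug inhibits a cancer cell line — the natural
logarithm of the half-maximal inhibitory concentration, LN IC50 — is a core
problem in pharmacogenomics. Expression profiles alone miss the fact that
drug response is modulated by the concerted behaviour of interacting genes,
and fingerprint-style drug features miss molecular topology. This package
implements the DIPK framework, which addresses both gaps for researchers
working with cell line × drug sensitivity panels (GDSC/CCLE-style data).

## The model

A pair (cell line *c*, drug *d*) is represented by three learned features:

* **Interactome feature** — a graph auto-encoder embeds every gene of one or
  more weighted gene interaction networks (two-layer graph convolution,
  inner-product decoder with logistic link, binary cross-entropy against
  sampled non-edges); the feature is the mean embedding of the cell's top
  *k* = 256 most highly expressed genes.
* **Transcriptome feature** — a denoising auto-encoder with ReLU layers of
  widths [2048, 1024, 512, 1024, 2048] compresses the z-scored expression
  profile; training reconstructs the clean profile from a
  Gaussian-corrupted input under MSE loss, and the middle layer is the
  feature.
* **Atom features** — the drug's SMILES becomes a heavy-atom graph; a
  message-passing network computes, per step *t*,
  `m_i^t = M({x_i^{t-1}, x_j^{t-1}, e_ij}, j ∈ N_i)` via multi-head
  attention over the neighbours and
  `x_i^t = GRU(h_i^{t-1}, m_i^t)` with `h_i^0 = x_i^0`, the summed
  attribute embeddings. Optional self-supervised pretraining: pairwise
  half-graph discrimination and atom attribute masking.

Fusion: each cell feature passes a ReLU linear layer; its pre-activation
output is the query **Q** of an attention pool
`softmax(QKᵀ/√d_k)V` over the atom features (K, V are independent linear
maps of the atoms, `d_k` the atomic feature dimension, default 768). The
molecular feature (sum of the two attention outputs) is concatenated with
the cell summary (sum of the two ReLU outputs) and regressed through
fully connected layers [768 + 512, 512, 256, 128, 1] under MSE loss.
Parameter sharing between the twin branch layers is the default
(generalization setting) and can be disabled. Ablation variants: **DEM**
(no interactome branch) and **DIM** (raw standardized expression instead of
the DAE latent).

Evaluation utilities cover averaged k-fold cross-validation and the
cold-start protocols (cell-disjoint, drug-disjoint and doubly disjoint
folds) with an MSE / RMSE / PCC / R² metric suite.

All four networks are trained by a small reverse-mode autodiff engine built
into the package (dense matrices, Adam), verified against finite
differences in the test suite. A synthetic-fixture generator provides
community-structured networks, expression with planted community
preference, a curated pool of small molecules and a planted linear
response, so the entire pipeline is testable offline.

## Worked example

Desk-scale end-to-end run on the synthetic fixture (60 genes, 120 cells,
16 drugs, response signal-to-noise 4:1; a few minutes on one core):

```r
library(DIPK)

fx  <- simulateFixture(fixtureConfig(seed = 1))          # networks, cells, drugs, responses
dae <- trainDAE(fx$profiles, daeConfig(hidden_dims = c(128, 64, 32, 64, 128),
                                       noise_sigma = 0.1, epochs = 60,
                                       learning_rate = 1e-3, seed = 11))
reps <- buildCellRepresentations(fx$profiles, fx$table, dae, k = fx$manifest$top_k)
graphs <- Map(smilesToGraph, fx$drugs$drug_id, fx$drugs$smiles)

enc <- initDrugEncoder(encoderConfig(d_atom = 32, message_steps = 3,
                                     attention_heads = 4, seed = 12))
enc <- pretrainMask(graphs, enc, mask_rate = 0.15, epochs = 15,
                    learning_rate = 3e-3, seed = 13)

resp <- fx$responses
set.seed(21); test <- sample(nrow(resp), round(0.2 * nrow(resp)))
model <- trainResponseModel(resp[-test, ], reps, graphs, enc,
                            fusionConfig(variant = "DIPK",
                                         head_dims = c(64, 32, 16, 1),
                                         attention_heads = 4,
                                         learning_rate = 2e-3, epochs = 100,
                                         batch_size = 128, seed = 14,
                                         freeze_encoder = TRUE))
pred <- predictResponse(model, resp[test, ], reps, graphs)
computeMetrics(resp$ln_ic50[test], pred$predicted_ln_ic50)
```

```
MetricReport (n=384): MSE 3.5294, RMSE 1.8787, PCC 0.8923, R2 0.7956
```

The planted response noise sd is 1.82 (variance 3.30), so an MSE of 3.53
sits essentially at the noise floor, and the held-out Pearson correlation
of 0.892 is at the 4:1 signal-to-noise ceiling of ≈ 0.894 — the model has
recovered the planted signal. Removing the interactome branch (`variant =
"DEM"`) roughly doubles the cold-start MSE on this fixture; see the
methods vignette (`vignettes/dipk-methods.Rmd`) for the model account and
the ablation protocol.

A command-line front end over the same functions is installed at
`inst/cli/dipk.R` with subcommands `simulate`, `pretrain-gae`,
`pretrain-dae`, `train`, `predict` and `crossval`.

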