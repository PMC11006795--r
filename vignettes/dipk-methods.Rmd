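---
title: "DIPK: model, assumptions and design notes"
author: "DIPK package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DIPK: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The prediction problem

DIPK regresses the natural-log IC50 of a (cancer cell line, drug) pair from
three information sources: gene interaction networks, the cell line's gene
expression profile, and the drug's molecular graph. The package implements
the full framework — self-supervised feature extractors, attention fusion,
the cold-start cross-validation protocols and the DEM/DIM ablations — plus
a synthetic-fixture generator with a planted response function so that every
component is testable without external data.

# Cell modelling

**Interactome feature.** A graph auto-encoder (`trainGeneEmbedder`) embeds
every gene of one or more weighted, undirected interaction networks into a
common vector space (default 512 dimensions). The encoder is a two-layer
graph convolution shared across networks, applied to each network's
symmetrically degree-normalised adjacency (self-loops added); per-gene
embeddings are the mean of the per-network encoder outputs, so a single
unified vector per gene emerges however many networks are supplied. The
decoder scores a gene pair by the logistic of the embedding inner product,
and training minimises binary cross-entropy of observed edges against
uniformly sampled non-edges (`negative_sampling_ratio` per edge, resampled
each epoch). Node features are one-hot identity — an interaction network has
no node attributes — and decoupled weight decay (default `1e-3`)
regularises the encoder so embeddings reflect neighbourhood structure
rather than memorising the edge list. A cell line's interactome feature is
the element-wise mean of the embeddings of its `k` most highly expressed
genes (default `k = 256`). Ties are broken by ascending gene identifier so
selection is deterministic, and genes absent from the embedding table are
excluded *before* ranking so the average always uses exactly
`min(k, #embeddable genes)` vectors.

**Transcriptome feature.** A denoising auto-encoder (`trainDAE`) compresses
the expression profile. The hidden stack is the palindromic width list
`[2048, 1024, 512, 1024, 2048]` by default — interpreted as hidden layers
only, since the first listed width is far below realistic gene counts — with
ReLU activations and a linear output of gene-count width. Inputs are
z-scored per gene over the training cells (the scaler is stored with the
model), which makes the corruption scale-free: during training the
standardized input receives additive Gaussian noise of sd `noise_sigma`
(default 0.1) and the loss is the MSE against the clean profile. The latent
(transcriptome feature) is the post-ReLU output of the middle layer;
encoding at inference time injects no noise.

# Drug modelling

`smilesToGraph` converts SMILES (parsed by OpenBabel through
ChemmineR/ChemmineOB) into heavy-atom graphs with categorical attributes:
element, heavy-atom degree (0–6), formal charge (−2…+2), aromatic flag, and
bond types single/double/triple/aromatic. Multi-fragment SMILES are
rejected — salt stripping belongs upstream. A lexical pre-check (balanced
parentheses/brackets, paired ring-closure digits) rejects malformed strings
that OpenBabel would silently repair.

The encoder (`encodeDrug`) initialises each atom vector as the sum of its
attribute embeddings and then runs `message_steps` (default 5) rounds of
neighbour attention with GRU updates: the message for atom *i* aggregates
the states of its bonded neighbours plus the bond-type embedding through
multi-head dot-product attention (query: the atom's state; keys/values: the
neighbour state plus the edge embedding; per-head scaling by the square
root of the per-head width), and the new state is a GRU cell applied to the
message with the previous state as hidden state (the initial hidden state
is the attribute embedding itself). Parameters are shared across message
steps, in keeping with the recurrent update. Attention weights are
normalised over each atom's neighbourhood; a single-atom molecule receives
a zero message and is still encoded through the GRU path. The default atom
vector width is 768.

Two self-supervised pretext tasks are provided. *Pairwise half-graph
discrimination* (`pretrainPHD`) splits each molecule into two balanced
halves by breadth-first traversal from a random seed atom and trains a
classifier to recognise whether two halves share a source molecule. The
classifier head is a one-hidden-layer MLP on the concatenated mean-pooled
half encodings: same-source discrimination is a similarity (XOR-like)
predicate on the concatenation, which a purely linear head provably cannot
express — with a linear head the loss is pinned at ln 2. *Attribute
masking* (`pretrainMask`) replaces the element of `floor(mask_rate × atoms)`
atoms per graph with a reserved token and predicts it from the final atom
vector. Both heads are discarded after pretraining; both functions attach
their held-out pretext accuracy (measured on fresh draws never used for a
gradient step) as an attribute.

# Fusion and output

Each cell feature passes a linear layer preserving its width. The
*pre-activation* output serves as the attention query — the query
projection is explicitly a linear layer without activation — while the ReLU
output enters the cell summary; this resolves the one genuinely ambiguous
reading of the layer wiring and is fixed throughout the package. Each query
attends over the drug's atom vectors (`attentionPool`): keys and values are
two independent linear maps of the atom matrix, the soft-max scaling
constant is the square root of the *full* atomic feature dimension
(`d_k = d_atom`, per the published formulation, not the per-head width),
and heads are concatenated and linearly mixed. The molecular feature is the
sum of the two attention outputs, the cell summary the sum of the two ReLU
branch outputs, and their concatenation (width `d_atom + d_cell`, default
768 + 512 = 1280) feeds a fully connected head `[1280, 512, 256, 128, 1]`
with ReLU on the hidden layers and a linear scalar output. Training
minimises mean MSE with Adam (default lr `1e-4`, batch 64).

With `share_parameters = TRUE` (default; the generalization setting) the
two branch linears share one weight set and the two attention layers share
another; `FALSE` keeps them distinct, the setting for learned cells and
drugs. Ablations: **DEM** removes the interactome branch entirely — the
remaining branch supplies both the molecular pool and the cell summary, and
the concatenated width is unchanged. **DIM** replaces the DAE latent with
the standardized raw expression profile; because that branch must still be
summed with the interactome branch, its linear layer maps the gene count
down to the interactome width (the one place the "dimension-preserving"
rule must bend), and branch-linear sharing is disabled automatically since
the shapes differ. The drug encoder is fine-tuned during response training
by default; `freeze_encoder = TRUE` keeps it fixed and precomputes atom
features once.

# Validation protocols

`makeFolds` builds four plans: uniform pair partition; cell-disjoint and
drug-disjoint partitions (no test cell/drug in that fold's training set);
and the doubly disjoint cold-start construction, which independently
partitions cells and drugs so fold *i* tests held-out-cell × held-out-drug
pairs and trains on pairs disjoint in both — the mixed pairs are dropped
with a recorded count, the only scheme consistent with disjointness at
many folds. `averageFoldPredictions` implements the protocol of scoring a
fixed external test set with each fold's model and averaging; for plain
k-fold partitions the per-fold test predictions are concatenated instead.
`computeMetrics` reports MSE, RMSE, Pearson correlation and
`R² = 1 − SS_res/SS_tot`; with zero observed variance the correlation
measures are reported as `NA` rather than a fabricated number.

# The synthetic fixture

The generator plants recoverable structure at every level. Networks are
2-to-4-block stochastic block models (within-community edge probability
0.3, between 0.02). Expression is a constant base plus the cell's latent
preference for the gene's community (standard normal per cell × community)
plus Gaussian noise of sd `noise_sd`; with no noise, a cell's top genes all
come from its preferred community, which is exactly the signal the
interactome feature averages over. Drugs come from a curated pool of 64
small connected molecules. The planted response is linear:
`w · [interactome feature ; atom count, aromatic count, heteroatom count]`
plus Gaussian noise. Both feature blocks are z-scored before applying `w`
(the embedding scale is data-dependent), the fixture's top-k is
`n_genes %/% 4` (the published 256 would select every gene at fixture
scale), and the weights, scalers and standardized features are stored in
the manifest so an ordinary least-squares fit can verify exact recovery in
the noiseless case.

One config field, `noise_sd`, controls both noise channels: it is the
absolute expression noise sd (the community signal has sd 1), and the
response noise sd is `noise_sd × sd(signal) / 2`, so the default
`noise_sd = 1` yields a response signal-to-noise ratio of 4:1 (noise-floor
Pearson correlation ≈ 0.894) while `noise_sd = 0` keeps both channels
exact. All randomness flows from a single seed through named sub-streams,
so each component can be regenerated independently.

What the fixture does *not* emulate: real IC50 distributions, expression
covariance beyond community structure, pharmacology (the drug signal is a
graph-computable descriptor, chosen so a correct encoder *can* learn it
without claiming chemistry), assay noise structure, or dataset-scale gene
counts. Passing tests demonstrate that the machinery recovers planted
signal under controlled conditions — not that it reproduces published
benchmark accuracy on GDSC or CCLE.

# Desk-scale study settings

The stochastic end-to-end checks run the full pipeline at sizes a laptop
handles in minutes, chosen once as the package's study conditions: fixture
60 genes / 120 cells / 16 drugs / 4 blocks; gene embeddings of dimension
32; DAE stack `[128, 64, 32, 64, 128]`; drug encoder width 32 with 3
message steps and 4 heads, masking-pretrained for 15 epochs and then
frozen during response training; fusion head `[64, 32, 16, 1]`, batch 128,
Adam lr `2e-3`, 100 epochs for signal recovery and 50 epochs per arm for
the ablation comparison (3 seeds, cell-disjoint holdout — the planted
signal is a function of the interactome feature, so cold-start cells is
where removing that branch must show). The paper-scale defaults remain the
package defaults.

# Numerical choices and degenerate inputs

* All four networks are trained with a single reverse-mode autodiff engine
  on dense matrices (`R/autodiff.R`), verified against central finite
  differences; Adam uses β = (0.9, 0.999), ε = 1e−8.
* Masked soft-max subtracts the row maximum before exponentiation; an atom
  with an empty neighbourhood receives an all-zero attention row (and hence
  a zero message) instead of NaN.
* Duplicate undirected edges merge by maximum weight; self-loops are
  dropped with a message. Both rules are order-independent.
* Gene identifiers are opaque, case-sensitive strings; no alias resolution.
* Expression values are used as provided; any log-transform belongs to
  preprocessing.
* Zero-epoch training contracts return the seeded initialisation unchanged,
  so pipelines can be assembled and inspected without optimisation.
* Per-gene standard deviations of zero are replaced by 1 in every scaler.

# Known limitations

* The graph auto-encoder's held-out link ranking on a 2-block stochastic
  block model is capped by an information bound: given communities, SBM
  edges are i.i.d., so no scorer can beat community membership. At the
  fixture's densities (0.3/0.02, 60 genes) the Bayes-optimal held-out AUC
  against uniform non-edges is ≈ 0.77; the trained model reaches ≈ 0.7,
  and its near-perfect reconstruction AUC (> 0.99) is the complementary
  learnability check. Real interaction networks, with hubs and overlapping
  neighbourhoods, are far above this bound.
* Pure-R training limits practical problem sizes to roughly thousands of
  pairs and feature widths in the tens to low hundreds; the paper-scale
  defaults type-check and run, but training them on full GDSC/CCLE is out
  of desk scope.
* Stereochemistry, 3-D conformers and multi-fragment molecules are not
  represented.
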