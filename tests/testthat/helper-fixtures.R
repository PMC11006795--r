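# Shared builders for the test suite. Everything is generated in code; the
# expensive end-to-end study pipeline (fixture + DAE + cell representations
# + pretrained drug encoder) is built once and memoised for the tests that
# share it.

.cache <- new.env(parent = emptyenv())

# rank AUC of positive over negative scores (Mann-Whitney)
rankAUC <- function(pos, neg) {
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

tinyProfiles <- function(n_cells = 6, genes = sprintf("g%02d", 1:10), seed = 1) {
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_cells), function(i)
      expressionProfile(sprintf("c%02d", i), genes, rnorm(length(genes))))
    names(out) <- vapply(out, cellId, character(1))
    out
  })
}

microEncoderConfig <- function(d_atom = 8L, steps = 2L, heads = 2L, seed = 3L)
  encoderConfig(d_atom = d_atom, message_steps = steps,
                attention_heads = heads, seed = seed)

# manual atom-permutation of a MolecularGraph
permuteGraph <- function(graph, perm) {
  a <- atomTable(graph)[perm, , drop = FALSE]
  b <- bondTable(graph)
  inv <- order(perm)
  new("MolecularGraph", drugId = paste0(drugId(graph), "_perm"), atoms = a,
      bonds = data.frame(a1 = inv[b$a1], a2 = inv[b$a2], type = b$type,
                         stringsAsFactors = FALSE))
}

# study-scale pipeline on the default fixture, shared by the acceptance and
# end-to-end tests (problem sizes documented in the methods vignette)
studyPipeline <- function() {
  if (!is.null(.cache$pipeline)) return(.cache$pipeline)
  fx <- simulateFixture(fixtureConfig(seed = 1L))
  dae <- trainDAE(fx$profiles,
                  daeConfig(hidden_dims = c(128L, 64L, 32L, 64L, 128L),
                            noise_sigma = 0.1, epochs = 60L,
                            learning_rate = 1e-3, seed = 11L))
  reps <- buildCellRepresentations(fx$profiles, fx$table, dae,
                                   k = fx$manifest$top_k)
  graphs <- lapply(seq_len(nrow(fx$drugs)), function(i)
    smilesToGraph(fx$drugs$drug_id[i], fx$drugs$smiles[i]))
  names(graphs) <- fx$drugs$drug_id
  enc <- initDrugEncoder(encoderConfig(d_atom = 32L, message_steps = 3L,
                                       attention_heads = 4L, seed = 12L))
  enc <- pretrainMask(graphs, enc, mask_rate = 0.15, epochs = 15L,
                      learning_rate = 3e-3, seed = 13L)
  .cache$pipeline <- list(fx = fx, dae = dae, reps = reps, graphs = graphs,
                          enc = enc)
  .cache$pipeline
}

studyFusionConfig <- function(variant = "DIPK", epochs = 100L, seed = 14L,
                              share = TRUE) {
  fusionConfig(variant = variant, share_parameters = share,
               attention_heads = 4L, head_dims = c(64L, 32L, 16L, 1L),
               learning_rate = 2e-3, epochs = epochs, batch_size = 128L,
               seed = seed, freeze_encoder = TRUE)
}
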