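# Synthetic fixtures with planted structure: community (stochastic block
# model) gene networks, expression profiles whose top expressed genes are
# enriched for a cell's preferred community, small valid molecules, and a
# planted linear response over the interactome feature and simple drug
# descriptors. Everything is deterministic given the config seed; each
# component draws from a named sub-stream so parts can be regenerated
# independently.

#' Fixture configuration
#'
#' @param n_genes,n_cells,n_drugs fixture sizes (defaults 60 / 120 / 16).
#' @param n_blocks number of network communities.
#' @param noise_sd noise level: the expression noise sd (the community
#'   preference signal has sd 1), and the response noise sd relative to the
#'   planted signal (\code{noise_sd * sd(signal) / 2}); the default 1.0
#'   yields a response signal-to-noise ratio of 4:1.
#' @param response_weights planted linear coefficients over the
#'   concatenated (interactome feature, drug descriptor) vector; drawn
#'   from a seeded standard normal when NULL.
#' @param seed master seed for all sub-streams.
#' @return validated config list.
#' @export
fixtureConfig <- function(n_genes = 60L, n_cells = 120L, n_drugs = 16L,
                          n_blocks = 4L, noise_sd = 1.0,
                          response_weights = NULL, seed = 1L) {
  stopifnot(n_genes >= 1L, n_cells >= 1L, n_drugs >= 1L, n_blocks >= 1L,
            n_blocks <= n_genes, noise_sd >= 0)
  list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
       n_drugs = as.integer(n_drugs), n_blocks = as.integer(n_blocks),
       noise_sd = noise_sd, response_weights = response_weights,
       seed = as.integer(seed))
}

.fixture_genes <- function(config) sprintf("g%03d", seq_len(config$n_genes))
.fixture_cells <- function(config) sprintf("c%03d", seq_len(config$n_cells))

# contiguous, deterministic community assignment
.gene_blocks <- function(config) {
  rep(seq_len(config$n_blocks),
      each = ceiling(config$n_genes / config$n_blocks))[seq_len(config$n_genes)]
}

#' Generate stochastic-block-model gene networks
#'
#' Within-community edge probability 0.3, between 0.02, unit weights.
#'
#' @param config a \code{\link{fixtureConfig}}.
#' @param n_networks how many independent draws to generate.
#' @param p_within,p_between edge probabilities.
#' @return list of \linkS4class{GeneNetwork}.
#' @export
makeGeneNetworks <- function(config, n_networks = 1L, p_within = 0.3,
                             p_between = 0.02) {
  genes <- .fixture_genes(config)
  blocks <- .gene_blocks(config)
  withr::with_seed(subSeed(config$seed, 1L), {
    lapply(seq_len(n_networks), function(k) {
      pairs <- which(upper.tri(matrix(0, config$n_genes, config$n_genes)),
                     arr.ind = TRUE)
      p <- ifelse(blocks[pairs[, 1L]] == blocks[pairs[, 2L]],
                  p_within, p_between)
      keep <- stats::runif(nrow(pairs)) < p
      geneNetwork(sprintf("sbm%d", k),
                  data.frame(gene_a = genes[pairs[keep, 1L]],
                             gene_b = genes[pairs[keep, 2L]],
                             weight = 1))
    })
  })
}

#' Generate expression profiles with planted community preference
#'
#' Each cell receives a latent preference per community (standard normal);
#' a gene's expression is a constant base plus the preference of its
#' community plus Gaussian noise of sd \code{noise_sd}. With no noise, a
#' cell's most highly expressed genes all belong to its preferred
#' community.
#'
#' @param config a \code{\link{fixtureConfig}}.
#' @param base constant baseline expression.
#' @return named list of \linkS4class{ExpressionProfile}.
#' @export
makeExpression <- function(config, base = 5) {
  genes <- .fixture_genes(config)
  cells <- .fixture_cells(config)
  blocks <- .gene_blocks(config)
  withr::with_seed(subSeed(config$seed, 2L), {
    pref <- matrix(stats::rnorm(config$n_cells * config$n_blocks),
                   config$n_cells, config$n_blocks)
    noise <- matrix(stats::rnorm(config$n_cells * config$n_genes,
                                 0, config$noise_sd),
                    config$n_cells, config$n_genes)
    out <- lapply(seq_len(config$n_cells), function(i)
      expressionProfile(cells[i], genes, base + pref[i, blocks] + noise[i, ]))
    names(out) <- cells
    out
  })
}

# curated pool of small, connected, parseable molecules: alkanes,
# aromatics, heteroaromatics, acids, amines, ethers, thio compounds
SMILES_POOL <- c(
  "CCO", "CC(=O)O", "c1ccccc1", "Cc1ccccc1", "CCN", "CCCCCC", "CC(C)O",
  "c1ccncc1", "c1ccoc1", "c1ccsc1", "c1cc[nH]c1",
  "CC(=O)Oc1ccccc1C(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CC(N)C(=O)O",
  "NCC(=O)O", "C1CCCCC1", "CCOC(=O)C", "CCOCC", "CC(C)=O", "CC#N",
  "ClCCl", "Oc1ccccc1", "Nc1ccccc1", "OCc1ccccc1", "CC(=O)Nc1ccccc1",
  "O=Cc1ccccc1", "OC(=O)c1ccccc1", "COc1ccccc1", "Clc1ccccc1",
  "Brc1ccccc1", "Fc1ccccc1", "c1ccc2ccccc2c1", "c1ccc2[nH]ccc2c1",
  "c1ccc2ncccc2c1", "OCCO", "OCC(O)CO", "C=CC=C", "CC(C)(C)O", "CCCCO",
  "CCC(=O)O", "CCCCCCCC", "CC(C)CC(C)(C)C", "CNC", "CN(C)C", "NCCN",
  "NCCO", "CCS", "CSC", "CS(=O)C", "NC(N)=O", "CC(N)=O", "C1CCOC1",
  "C1CCNC1", "C1CCNCC1", "C1COCCN1", "c1cnccn1", "c1ccnnc1", "c1cncnc1",
  "Cc1ccco1", "Cc1cccs1", "CCBr", "OC(=O)C=C", "CCC#N", "COC(=O)c1ccccc1")

#' Draw drugs from the built-in SMILES pool
#'
#' @param config a \code{\link{fixtureConfig}}; \code{n_drugs} must not
#'   exceed the pool size.
#' @return data.frame with \code{drug_id}, \code{smiles}.
#' @export
makeDrugs <- function(config) {
  if (config$n_drugs > length(SMILES_POOL))
    stop(sprintf("n_drugs exceeds the SMILES pool size (%d)",
                 length(SMILES_POOL)), call. = FALSE)
  withr::with_seed(subSeed(config$seed, 3L), {
    sel <- sample(SMILES_POOL, config$n_drugs)
    data.frame(drug_id = sprintf("drug%02d", seq_len(config$n_drugs)),
               smiles = sel, stringsAsFactors = FALSE)
  })
}

.zscore_cols <- function(m) {
  center <- colMeans(m)
  scale <- apply(m, 2L, stats::sd)
  scale[scale == 0] <- 1
  list(std = sweep(sweep(m, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

# graph-computable drug descriptors: heavy atoms, aromatic atoms, heteroatoms
.drug_descriptors <- function(drugs) {
  rows <- lapply(seq_len(nrow(drugs)), function(i) {
    g <- smilesToGraph(drugs$drug_id[i], drugs$smiles[i])
    a <- atomTable(g)
    c(n_atoms = nrow(a), n_aromatic = sum(a$aromatic),
      n_hetero = sum(a$element != "C"))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- drugs$drug_id
  m
}

#' Generate responses from the planted linear ground truth
#'
#' The planted LN IC50 of a (cell, drug) pair is
#' \code{w . [interactome feature ; drug descriptors] + noise}, where the
#' interactome feature uses the top \code{n_genes \%/\% 4} genes, both
#' feature blocks are z-scored (scalers kept in the manifest), and the
#' noise sd is \code{noise_sd * sd(signal) / 2}. The manifest (attribute
#' \code{"manifest"}) records the weights and standardized features so
#' recovery tests can quantify the signal.
#'
#' @param config a \code{\link{fixtureConfig}}.
#' @param profiles output of \code{\link{makeExpression}}.
#' @param drugs output of \code{\link{makeDrugs}}.
#' @param table a \linkS4class{GeneEmbeddingTable} over the fixture genes.
#' @param response_noise_sd absolute response noise sd override; the
#'   default NULL uses \code{noise_sd * sd(signal) / 2}.
#' @return data.frame of responses with attribute \code{manifest}.
#' @export
makeResponses <- function(config, profiles, drugs, table,
                          response_noise_sd = NULL) {
  top_k <- max(1L, config$n_genes %/% 4L)
  fint <- do.call(rbind, lapply(profiles, interactomeFeature, table = table,
                                k = top_k))
  fz <- .zscore_cols(fint)
  desc <- .drug_descriptors(drugs)
  dz <- .zscore_cols(desc)
  d_feat <- ncol(fint) + ncol(desc)
  withr::with_seed(subSeed(config$seed, 4L), {
    w <- config$response_weights
    if (is.null(w)) w <- stats::rnorm(d_feat)
    if (length(w) != d_feat)
      stop(sprintf("response_weights must have length %d (embedding dim + %d descriptors)",
                   d_feat, ncol(desc)), call. = FALSE)
    grid <- expand.grid(cell_id = names(profiles), drug_id = drugs$drug_id,
                        stringsAsFactors = FALSE)
    feats <- cbind(fz$std[grid$cell_id, , drop = FALSE],
                   dz$std[grid$drug_id, , drop = FALSE])
    signal <- as.vector(feats %*% w)
    noise_sd <- if (is.null(response_noise_sd))
      config$noise_sd * stats::sd(signal) / 2 else response_noise_sd
    ln <- signal + stats::rnorm(length(signal), 0, noise_sd)
    out <- data.frame(cell_id = grid$cell_id, drug_id = grid$drug_id,
                      ln_ic50 = ln, stringsAsFactors = FALSE)
    attr(out, "manifest") <- list(
      weights = w, top_k = top_k, response_noise_sd = noise_sd,
      signal_sd = stats::sd(signal),
      fint_std = fz$std, desc_std = dz$std,
      fint_center = fz$center, fint_scale = fz$scale,
      desc_center = dz$center, desc_scale = dz$scale)
    out
  })
}

#' Generate a complete end-to-end fixture
#'
#' Networks, a trained gene embedding table, expression profiles, drugs and
#' planted responses, bundled with the generation manifest.
#'
#' @param config a \code{\link{fixtureConfig}}.
#' @param embedding_dim gene embedding dimensionality used for the fixture
#'   table.
#' @param gae_epochs training epochs for the fixture embedding table.
#' @param n_networks number of SBM network draws.
#' @return list with elements \code{networks}, \code{table},
#'   \code{profiles}, \code{drugs}, \code{responses}, \code{manifest},
#'   \code{config}.
#' @export
simulateFixture <- function(config = fixtureConfig(), embedding_dim = 32L,
                            gae_epochs = 120L, n_networks = 1L) {
  networks <- makeGeneNetworks(config, n_networks = n_networks)
  table <- suppressWarnings(trainGeneEmbedder(
    networks,
    gaeConfig(dim = embedding_dim, epochs = gae_epochs, learning_rate = 0.05,
              seed = subSeed(config$seed, 11L)),
    extra_genes = .fixture_genes(config)))
  profiles <- makeExpression(config)
  drugs <- makeDrugs(config)
  responses <- makeResponses(config, profiles, drugs, table)
  list(networks = networks, table = table, profiles = profiles,
       drugs = drugs, responses = responses,
       manifest = attr(responses, "manifest"), config = config)
}

#' Write a fixture directory in the package's delimited formats
#'
#' @param fixture output of \code{\link{simulateFixture}}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeFixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpressionMatrix(fixture$profiles, file.path(dir, "expression.tsv"))
  for (k in seq_along(fixture$networks))
    writeEdgeList(fixture$networks[[k]],
                  file.path(dir, sprintf("network_%d.tsv", k)))
  writeGeneEmbeddingTable(fixture$table, file.path(dir, "gene_embeddings.tsv"))
  utils::write.table(fixture$drugs, file.path(dir, "drugs.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeResponseTable(fixture$responses, file.path(dir, "responses.tsv"))
  manifest <- fixture$manifest
  manifest$fint_std <- NULL; manifest$desc_std <- NULL
  jsonlite::write_json(
    c(list(config = fixture$config[setdiff(names(fixture$config),
                                           "response_weights")]), manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
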