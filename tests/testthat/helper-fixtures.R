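# Shared fixtures, computed once per test run (the chemistry backend is a
# subprocess, so batching molecules into one call keeps the suite fast).

fixture_env <- new.env()

fixture_smiles <- c(
  ethanol = "CCO", co2 = "O=C=O", benzene = "c1ccccc1",
  ethyl_acetate = "CCOC(C)=O", peroxide = "CCOO", neopentane = "CC(C)(C)C",
  toluene = "Cc1ccccc1", acetic = "CC(=O)O", cysteamine = "NCCS",
  isopentane = "CCC(C)C", selenol = "[SeH]C", chiral = "N[C@@H](C)C(=O)O"
)

fixture_geometry <- function() {
  if (is.null(fixture_env$geo)) {
    fixture_env$geo <- compute_geometry(unname(fixture_smiles), embed_seed = 7)
    names(fixture_env$geo$graphs) <- names(fixture_smiles)
  }
  fixture_env$geo
}

fixture_graphs <- function(which = names(fixture_smiles)) {
  fixture_geometry()$graphs[which]
}

# raw per-atom/bond description (no 3D) for the SMARTS oracle
fixture_described <- function(smiles) {
  molattn:::backend_describe(smiles, coords = "none")
}

# a small trained-model-free batch for model plumbing tests
fixture_batch <- function(k = 5, n_targets = 3, seed = 11) {
  withr::with_seed(seed, {
    graphs <- fixture_graphs(c("ethanol", "benzene", "ethyl_acetate",
                               "peroxide", "neopentane"))[seq_len(k)]
    labels <- matrix(rbinom(k * n_targets, 1, 0.5), k, n_targets)
    build_batch(graphs, labels)
  })
}

tiny_config <- function(...) {
  molattn_config(n_heads = 2L, head_dim = 4L, n_encoder_layers = 1L,
                 n_decoder_layers = 1L, dropout = 0, seed = 5L, ...)
}

tiny_params <- function(config, n_targets = 3) {
  withr::with_seed(config$seed, molattn:::init_params(config, n_targets))
}
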