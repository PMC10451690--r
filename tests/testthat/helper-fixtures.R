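# Shared fixtures: small synthetic datasets and models, built once per
# test session and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

fixture_dataset <- function(n, seed, image_size = 32, noise_sd = 0.02) {
  key <- sprintf("ds_%d_%d_%d", n, seed, image_size)
  if (is.null(.fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("crossviewrg_", key))
    unlink(dir, recursive = TRUE)
    cfg <- synth_config(n, image_size = image_size, noise_sd = noise_sd,
                        seed = seed)
    .fixture_cache[[key]] <- make_dataset(cfg, dir)
  }
  .fixture_cache[[key]]
}

# an untrained toy model with a small vocabulary, for op-level tests
fixture_model <- function(seed = 42) {
  key <- sprintf("model_%d", seed)
  if (is.null(.fixture_cache[[key]])) {
    ds <- fixture_dataset(6, 99)
    vocab <- build_vocabulary(lapply(ds$studies, `[[`, "report"), 1L)
    cfg <- rg_toy_config(seed = seed)
    .fixture_cache[[key]] <- init_model(cfg, ds$catalog, vocab)
  }
  .fixture_cache[[key]]
}

rand_mat <- function(nr, nc, sd = 1) matrix(rnorm(nr * nc, sd = sd), nr, nc)

random_token_corpus <- function(n_pairs, vocab_words, max_len = 8) {
  cands <- list(); refs <- list()
  for (i in seq_len(n_pairs)) {
    cands[[i]] <- sample(vocab_words, sample(1:max_len, 1), replace = TRUE)
    refs[[i]] <- lapply(seq_len(sample(1:2, 1)), function(j) {
      sample(vocab_words, sample(2:max_len, 1), replace = TRUE)
    })
  }
  list(cands = cands, refs = refs)
}
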