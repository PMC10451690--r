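test_that("tokenize lowercases, strips punctuation and splits on whitespace", {
  expect_identical(tokenize("The heart is Normal."),
                   c("the", "heart", "is", "normal"))
  expect_identical(tokenize(""), character(0))
  expect_length(tokenize("no acute cardiopulmonary abnormality"), 4L)
  expect_identical(tokenize('Heart: enlarged, (mildly) "so".'),
                   c("heart", "enlarged", "mildly", "so"))
})

test_that("vocabulary respects the frequency threshold and ordering", {
  v <- build_vocabulary(list(c("a a a b")), min_count = 3)
  expect_identical(v$tokens, c("<pad>", "<unk>", "<bos>", "<eos>", "a"))
  expect_identical(unname(v$index[["a"]]), 5L)

  v0 <- build_vocabulary(list(), min_count = 3)
  expect_identical(v0$tokens, c("<pad>", "<unk>", "<bos>", "<eos>"))

  # frequency-descending order, lexicographic ties
  v2 <- build_vocabulary(list(c("b b c c a a a")), min_count = 2)
  expect_identical(v2$tokens[5:7], c("a", "b", "c"))
})

test_that("vocabulary size matches an independent frequency count", {
  ds <- fixture_dataset(20, 7)
  reports <- lapply(ds$studies, `[[`, "report")
  v <- build_vocabulary(reports, min_count = 3)
  # independent pass: plain table over all tokenized words
  words <- unlist(lapply(unlist(reports), tokenize))
  n_expected <- sum(table(words) >= 3)
  expect_length(v$tokens, n_expected + 4L)
  # determinism
  expect_identical(v, build_vocabulary(reports, min_count = 3))
})

test_that("encode_report builds stop vectors, truncates and round-trips", {
  v <- build_vocabulary(list(c("the heart is normal", "the lungs are clear")),
                        min_count = 1)
  e <- encode_report(c("the heart is normal", "the lungs are clear"), v,
                     s_max = 6, w_max = 30)
  expect_equal(e$n_sentences, 2)
  expect_equal(e$stop, c(0, 1, 1, 1, 1, 1))
  expect_equal(sum(e$stop == 0), min(2, 6) - 1)

  # more sentences than slots: first 6 kept, stop only at the end
  rep8 <- rep("the heart is normal", 8)
  e8 <- encode_report(rep8, v, s_max = 6, w_max = 30)
  expect_equal(e8$n_sentences, 6)
  expect_equal(e8$stop, c(0, 0, 0, 0, 0, 1))

  # 40-token sentence is clipped to 30 slots (bos + 28 words + eos)
  long <- paste(rep("the", 40), collapse = " ")
  el <- encode_report(long, v, s_max = 2, w_max = 30)
  expect_equal(el$lengths[1], 30)
  expect_equal(el$token_ids[1, 1], 3L)     # <bos>
  expect_equal(el$token_ids[1, 30], 4L)    # <eos>

  # decode reproduces the truncated lowercased report
  toks <- decode_tokens(e$token_ids[1, ], v)
  expect_identical(toks, tokenize("the heart is normal"))

  expect_error(encode_report(character(0), v), "invalid study")
})

test_that("out-of-vocabulary words map to the unknown token", {
  v <- build_vocabulary(list("a a a b"), min_count = 3)
  e <- encode_report("a b a", v, s_max = 1, w_max = 10)
  ids <- e$token_ids[1, 2:4]
  expect_equal(ids, c(v$index[["a"]], 2L, v$index[["a"]]), ignore_attr = TRUE)
})

test_that("tag encoding is exact, idempotent under duplicates, strict on names", {
  cat10 <- tag_catalog(paste0("tag", 1:10))
  expect_equal(encode_tags(character(0), cat10), rep(0L, 10))
  one <- encode_tags("tag3", cat10)
  expect_equal(sum(one), 1L)
  expect_equal(which(one == 1L), 3L)
  expect_equal(encode_tags(c("tag3", "tag3", "tag5"), cat10),
               encode_tags(c("tag5", "tag3"), cat10))
  expect_error(encode_tags("nope", cat10), "nope")
})

test_that("manifest, catalog and vocabulary files round-trip losslessly", {
  ds <- fixture_dataset(5, 13)
  dir <- file.path(tempdir(), "roundtrip")
  unlink(dir, recursive = TRUE)
  dir.create(dir)
  mpath <- file.path(dir, "m.jsonl")
  write_manifest(ds$studies, mpath)
  back <- read_manifest(mpath)
  expect_equal(lapply(back, unclass), lapply(ds$studies, unclass))

  cpath <- file.path(dir, "tags.csv")
  write_tag_catalog(ds$catalog, cpath)
  expect_equal(read_tag_catalog(cpath), ds$catalog)

  v <- build_vocabulary(lapply(ds$studies, `[[`, "report"), 1L)
  vpath <- file.path(dir, "vocab.txt")
  write_vocabulary(v, vpath)
  expect_identical(read_vocabulary(vpath)$tokens, v$tokens)
})

test_that("manifest reading rejects malformed input with line context", {
  dir <- file.path(tempdir(), "badmanifest")
  unlink(dir, recursive = TRUE)
  dir.create(dir)
  p <- file.path(dir, "m.jsonl")
  writeLines('{"study_id": "s1", "frontal_path": "a.png"', p)
  expect_error(read_manifest(p), "line 1")
  writeLines('{"study_id": "s1", "frontal_path": "a.png", "tags": [], "report": ["x"]}', p)
  expect_error(read_manifest(p), "lateral_path")
  writeLines(character(0), p)
  expect_length(read_manifest(p), 0L)
  writeLines(paste0('{"study_id": "s9", "frontal_path": "missing.png", ',
                    '"lateral_path": "also.png", "tags": [], "report": ["x"]}'), p)
  expect_error(read_manifest(p), "s9")
})
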