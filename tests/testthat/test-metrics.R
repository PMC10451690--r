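test_that("BLEU identities: exact match, disjoint, clipping and brevity", {
  cand <- list(c("the", "heart", "is", "normal"))
  refs <- list(list(c("the", "heart", "is", "normal")))
  for (n in 1:4) expect_equal(bleu_n(cand, refs, n), 1)
  expect_equal(bleu_n(list(c("x", "y")), list(list(c("a", "b"))), 1), 0)
  # clipped unigram precision: "the the the" vs "the cat" is 1/3 (c > r, BP = 1)
  expect_equal(bleu_n(list(rep("the", 3)), list(list(c("the", "cat"))), 1),
               1 / 3, tolerance = 1e-12)
  # short candidate: p1 = 1 but BP = exp(1 - 3/2)
  expect_equal(bleu_n(list(c("the", "cat")),
                      list(list(c("the", "cat", "sat"))), 1),
               exp(1 - 3 / 2), tolerance = 1e-12)
  expect_equal(bleu_n(list(character(0)), list(list(c("a")))), 0)
})

test_that("corpus BLEU agrees with the loop reference on 50 random corpora", {
  set.seed(501)
  words <- c("the", "heart", "lungs", "clear", "normal", "effusion", "is",
             "are", "no", "seen")
  for (rep in 1:50) {
    corp <- random_token_corpus(sample(2:5, 1), words)
    for (n in 1:4) {
      expect_equal(bleu_n(corp$cands, corp$refs, n),
                   ref_bleu(corp$cands, corp$refs, n), tolerance = 1e-6)
    }
  }
})

test_that("ROUGE-L matches hand-computed dynamic-programming cases", {
  a <- c("a", "b", "c", "d")
  expect_equal(rouge_l(a, list(a)), 1)
  expect_equal(rouge_l(c("x", "y"), list(c("a", "b"))), 0)
  # LCS("a b c d", "a c b d") = 3; P = R = 3/4 so F = 0.75 for any beta
  expect_equal(rouge_l(a, list(c("a", "c", "b", "d"))), 0.75,
               tolerance = 1e-12)
  # asymmetric case, computed by hand: LCS = 2, P = 2/3, R = 2/4,
  # beta = 1.2: F = (1 + 1.44) * P * R / (R + 1.44 * P)
  p <- 2 / 3; r <- 2 / 4
  expect_equal(rouge_l(c("a", "b", "x"), list(c("a", "q", "b", "z"))),
               2.44 * p * r / (r + 1.44 * p), tolerance = 1e-12)
})

test_that("ROUGE-L agrees with the recursive LCS oracle on random cases", {
  set.seed(502)
  words <- letters[1:6]
  for (rep in 1:30) {
    cand <- sample(words, sample(1:7, 1), replace = TRUE)
    refs <- lapply(1:2, function(i) sample(words, sample(2:7, 1), TRUE))
    expect_equal(rouge_l(cand, refs), ref_rouge_l(cand, refs),
                 tolerance = 1e-9)
  }
})

test_that("CIDEr identities: consensus, disjoint and degenerate corpora", {
  refs <- list(list(c("the", "lungs", "are", "clear")),
               list(c("the", "heart", "is", "enlarged", "today")),
               list(c("no", "acute", "abnormality", "is", "seen")))
  cands <- lapply(refs, `[[`, 1)
  # candidate == its reference and all orders present: cosine 1 throughout
  expect_equal(cider(cands, refs), 10, tolerance = 1e-9)
  expect_equal(cider(list(c("x", "y", "z")), refs[1]), 0)
  # single-pair corpus: all idf = log(1) = 0
  expect_equal(cider(cands[1], refs[1]), 0)
})

test_that("CIDEr agrees with an independent direct implementation", {
  set.seed(503)
  words <- c("the", "heart", "lungs", "clear", "normal", "is", "are", "no")
  for (rep in 1:10) {
    corp <- random_token_corpus(3, words)
    expect_equal(cider(corp$cands, corp$refs),
                 ref_cider(corp$cands, corp$refs), tolerance = 1e-6)
  }
})

test_that("macro AUC: separation, ties, exclusions and the pairwise oracle", {
  s <- matrix(c(0.9, 0.8, 0.2, 0.1), 4, 1)
  y <- matrix(c(1, 1, 0, 0), 4, 1)
  expect_equal(macro_auc(s, y)$macro, 1)
  expect_equal(macro_auc(matrix(0.5, 4, 1), y)$macro, 0.5)
  # single-class columns are excluded
  r <- macro_auc(cbind(s, 0.3), cbind(y, 1))
  expect_equal(r$excluded, 2L)
  expect_equal(r$macro, 1)
  set.seed(504)
  for (rep in 1:20) {
    scores <- matrix(round(runif(60), 1), 20, 3)  # rounded to force ties
    labels <- matrix(rbinom(60, 1, 0.4), 20, 3)
    got <- macro_auc(scores, labels)
    for (j in 1:3) {
      if (j %in% got$excluded) next
      expect_equal(got$per_class[j], ref_auc(scores[, j], labels[, j]),
                   tolerance = 1e-9)
    }
  }
})

test_that("macro AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(505)
  for (rep in 1:10) {
    scores <- rnorm(30)
    labels <- rbinom(30, 1, 0.5)
    if (length(unique(labels)) < 2) next
    got <- macro_auc(matrix(scores), matrix(labels))$macro
    want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("metrics are invariant to corpus order and stay in range", {
  set.seed(506)
  words <- c("the", "a", "b", "c", "d", "e")
  corp <- random_token_corpus(6, words)
  perm <- sample(6)
  for (n in 1:4) {
    b <- bleu_n(corp$cands, corp$refs, n)
    expect_equal(b, bleu_n(corp$cands[perm], corp$refs[perm], n),
                 tolerance = 1e-12)
    expect_gte(b, 0); expect_lte(b, 1)
  }
  expect_equal(cider(corp$cands, corp$refs),
               cider(corp$cands[perm], corp$refs[perm]), tolerance = 1e-9)
  rl <- rouge_l(corp$cands, corp$refs)
  expect_gte(rl, 0); expect_lte(rl, 1)
})
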