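test_that("sentence step matches the straight-line reference", {
  model <- fixture_model()
  h <- model$config$hidden
  set.seed(401)
  for (rep in 1:20) {
    mvs <- rnorm(h)
    state <- decoder_init_state(h)
    if (rep %% 2 == 0) {
      state$h <- rand_mat(1, h, 0.3)
      state$c <- rand_mat(1, h, 0.3)
    }
    got <- sentence_step(mvs, state, model)
    want <- ref_sentence_step(mvs, state, model$params)
    expect_equal(got$topic, want$topic, tolerance = 1e-6)
    expect_equal(got$stop_logits, want$stop_logits, tolerance = 1e-6)
    expect_true(all(abs(got$topic) < 1))
  }
})

test_that("zero input and zero state give a zero topic", {
  model <- fixture_model()
  h <- model$config$hidden
  out <- sentence_step(rep(0, h), decoder_init_state(h), model)
  # zero MVS + zero state: the sentence LSTM's candidate gate is tanh(0),
  # so h stays 0 and the topic is tanh(0) = 0
  expect_equal(out$topic, rep(0, h))
  expect_equal(out$stop_logits, c(0, 0))
})

test_that("word step emits a normalized distribution matching the reference", {
  model <- fixture_model()
  h <- model$config$hidden
  set.seed(402)
  for (rep in 1:20) {
    prev <- sample(length(model$vocab$tokens), 1)
    topic <- tanh(rnorm(h))
    state <- list(h = rand_mat(1, h, 0.3), c = rand_mat(1, h, 0.3))
    got <- word_step(prev, topic, state, model)
    want <- ref_word_step(prev, topic, state, model$params)
    expect_equal(got$probs, want$probs, tolerance = 1e-6)
    expect_equal(sum(got$probs), 1, tolerance = 1e-6)
  }
})

test_that("tied logits give the uniform distribution", {
  model <- fixture_model()
  model$params[["dec.out.Woutput"]][] <- 0
  v <- length(model$vocab$tokens)
  out <- word_step(1L, rep(0, model$config$hidden),
                   list(h = rand_mat(1, model$config$hidden),
                        c = rand_mat(1, model$config$hidden)), model)
  expect_equal(out$probs, rep(1 / v, v), tolerance = 1e-12)
})

test_that("stop loss follows its closed forms and loop reference", {
  # confident correct predictions: near-zero loss
  conf <- matrix(c(20, -20, -20, 20), 2, 2, byrow = TRUE)
  expect_lt(stop_loss(conf, c(0, 1)), 1e-8)
  # uniform logits over 6 steps: 6 log 2
  expect_equal(stop_loss(matrix(0, 6, 2), c(0, 0, 0, 0, 0, 1)),
               6 * log(2), tolerance = 1e-12)
  set.seed(403)
  for (rep in 1:20) {
    s <- sample(2:6, 1)
    lg <- rand_mat(s, 2)
    tg <- c(rep(0, s - 1), 1)
    mk <- as.numeric(seq_len(s) <= sample(s, 1))
    want <- 0
    for (i in seq_len(s)) {
      p <- exp(lg[i, ]) / sum(exp(lg[i, ]))
      want <- want - mk[i] * log(p[tg[i] + 1])
    }
    expect_equal(stop_loss(lg, tg, mk), want, tolerance = 1e-6)
  }
})

test_that("word loss follows its closed forms, reference, and masking", {
  # perfect one-hot predictions: zero loss
  p <- diag(4)[c(2, 3), ]
  expect_equal(word_loss(p, c(2L, 3L)), 0, tolerance = 1e-9)
  # uniform over 100 at 10 positions: 10 log 100
  expect_equal(word_loss(matrix(1 / 100, 10, 100), sample(100, 10)),
               10 * log(100), tolerance = 1e-9)
  set.seed(404)
  for (rep in 1:20) {
    tt <- sample(12, 5)
    pp <- matrix(runif(5 * 12), 5, 12)
    pp <- pp / rowSums(pp)
    mk <- rbinom(5, 1, 0.7)
    want <- -sum(mk * log(pp[cbind(1:5, tt)]))
    expect_equal(word_loss(pp, tt, mk), want, tolerance = 1e-6)
  }
  # appending fully-masked positions leaves the loss unchanged
  base <- word_loss(p, c(2L, 3L), c(1, 1))
  padded <- word_loss(rbind(p, matrix(1 / 4, 3, 4)),
                      c(2L, 3L, 1L, 1L, 1L), c(1, 1, 0, 0, 0))
  expect_equal(padded, base, tolerance = 1e-12)
  sbase <- stop_loss(matrix(0, 2, 2), c(0, 1), c(1, 1))
  spad <- stop_loss(matrix(c(0, 5), 4, 2), c(0, 1, 1, 1), c(1, 1, 0, 0))
  expect_equal(spad, sbase, tolerance = 1e-12)
})

test_that("total loss is the weighted sum of its parts", {
  expect_equal(total_loss(2, 1, 3), 6)
  expect_equal(total_loss(2, 1, 3, weights = c(0, 0, 0)), 0)
  expect_equal(total_loss(1, 2, 3, weights = c(1, 0.5, 2)), 8)
})

test_that("greedy generation is deterministic and respects the limits", {
  ds <- fixture_dataset(6, 99)
  model <- fixture_model()
  s <- ds$studies[[1]]
  g1 <- generate_report(s$frontal_path, s$lateral_path, model)
  g2 <- generate_report(s$frontal_path, s$lateral_path, model)
  expect_identical(g1$sentences, g2$sentences)
  expect_lte(length(g1$sentences), model$config$s_max)
  for (sent in g1$sentences) {
    expect_lte(length(tokenize(sent)), model$config$w_max)
  }
  expect_length(g1$tags, model$config$k_top)
})

test_that("a neutral stop head generates until the sentence limit", {
  # with zeroed stop projections the logits tie and argmax stays on
  # "continue", so generation runs to s_max
  model <- fixture_model()
  model$params[["dec.stop.Wprev"]][] <- 0
  model$params[["dec.stop.Wcur"]][] <- 0
  ds <- fixture_dataset(6, 99)
  s <- ds$studies[[2]]
  g <- generate_report(s$frontal_path, s$lateral_path, model, s_max = 3)
  expect_length(g$attention, 3L)
})
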