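test_that("squeeze-excitation matches a two-loop reference on random maps", {
  set.seed(201)
  for (rep in 1:20) {
    p <- se_params(8L, 4L)
    v <- rand_mat(4, 8)
    expect_equal(se_attention(v, p), ref_se(v, p), tolerance = 1e-6)
  }
})

test_that("squeeze-excitation edge cases: saturated gate and zero input", {
  set.seed(202)
  p <- se_params(8L)
  # a large positive output bias drives every gate to 1: f becomes identity
  p$b2 <- matrix(30, 1, 8)
  v <- rand_mat(5, 8)
  expect_equal(se_attention(v, p), v, tolerance = 1e-8)
  # zero map: gated zeros stay zero whatever the gate
  expect_equal(se_attention(matrix(0, 4, 8), se_params(8L)), matrix(0, 4, 8))
  expect_error(se_params(8L, 3L), "divide")
})

test_that("cross-view mixing obeys its identities and matches the reference", {
  set.seed(203)
  p <- se_params(8L)
  vf <- rand_mat(4, 8)
  vl <- rand_mat(4, 8)
  # lambda = 1 reduces to the per-view gated maps
  m1 <- cross_view_mix(vf, vl, p, 1)
  expect_equal(m1$vaf, se_attention(vf, p), tolerance = 1e-12)
  expect_equal(m1$val, se_attention(vl, p), tolerance = 1e-12)
  # swapping the views swaps the outputs (shared f)
  m <- cross_view_mix(vf, vl, p, 0.5)
  ms <- cross_view_mix(vl, vf, p, 0.5)
  expect_equal(m$vaf, ms$val, tolerance = 1e-12)
  expect_equal(m$val, ms$vaf, tolerance = 1e-12)
  # the published operating point against the naive reference
  for (rep in 1:20) {
    vf <- rand_mat(4, 8); vl <- rand_mat(4, 8)
    expect_equal(cross_view_mix(vf, vl, p, 0.6), ref_mix(vf, vl, p, 0.6),
                 tolerance = 1e-6)
  }
  expect_error(cross_view_mix(vf, vl[1:2, ], p, 0.6), "shape")
})

test_that("mixing is linear when the gates are saturated to identity", {
  set.seed(204)
  p <- se_params(8L)
  p$b2 <- matrix(30, 1, 8)  # f ~ identity
  vf <- rand_mat(4, 8)
  vl <- rand_mat(4, 8)
  m <- cross_view_mix(vf, vl, p, 0.7)
  mc <- cross_view_mix(3 * vf, 3 * vl, p, 0.7)
  expect_equal(mc$vaf, 3 * m$vaf, tolerance = 1e-6)
  expect_equal(mc$val, 3 * m$val, tolerance = 1e-6)
})

test_that("branch heads are pooled affine-sigmoid maps with outputs in (0,1)", {
  set.seed(205)
  for (rep in 1:20) {
    v <- rand_mat(6, 8)
    w <- rand_mat(8, 5)
    b <- rnorm(5)
    y <- classify_branch(v, w, b)
    expect_equal(y, ref_head(v, w, b), tolerance = 1e-6)
    expect_true(all(y > 0 & y < 1))
  }
  # zero map leaves only the bias
  expect_equal(classify_branch(matrix(0, 6, 8), rand_mat(8, 5), rep(0.3, 5)),
               rep(1 / (1 + exp(-0.3)), 5), tolerance = 1e-12)
})

test_that("consistency loss follows its closed forms and the loop reference", {
  z <- rep(0.4, 10)
  expect_equal(cvam_loss(list(y_f = z, y_l = z, y_af = z, y_al = z))$l_cvam, 0)
  # 0.1 gap at all 10 tags in the single-view pair only
  r <- cvam_loss(list(y_f = z + 0.1, y_l = z, y_af = z, y_al = z))
  expect_equal(r$l_cvam, 0.1, tolerance = 1e-12)
  set.seed(206)
  for (rep in 1:20) {
    ys <- lapply(1:4, function(i) runif(7))
    got <- cvam_loss(list(y_f = ys[[1]], y_l = ys[[2]],
                          y_af = ys[[3]], y_al = ys[[4]]))
    want <- ref_cvam_loss(ys[[1]], ys[[2]], ys[[3]], ys[[4]])
    expect_equal(got$l_cvam, want$l_cvam, tolerance = 1e-6)
    expect_gte(got$l_cvam, 0)
  }
})

test_that("branch BCE matches the closed form and the loop reference", {
  m <- 155
  preds <- replicate(4, rep(0.5, m), simplify = FALSE)
  names(preds) <- c("y_f", "y_l", "y_af", "y_al")
  t <- rbinom(m, 1, 0.3)
  expect_equal(bce_loss(preds, t), 4 * m * log(2), tolerance = 1e-9)
  # near-perfect predictions give near-zero loss
  perfect <- lapply(1:4, function(i) ifelse(t == 1, 1, 0))
  expect_lt(bce_loss(perfect, t), 1e-4)
  set.seed(207)
  for (rep in 1:20) {
    ps <- lapply(1:4, function(i) runif(12, 0.01, 0.99))
    tt <- rbinom(12, 1, 0.5)
    expect_equal(bce_loss(ps, tt), ref_bce(ps, tt), tolerance = 1e-6)
  }
})

test_that("encoder loss combines its terms with the configured weights", {
  expect_equal(encoder_loss(2, 0.4, alpha = 1, beta = 0.05), 2.02)
  expect_equal(encoder_loss(2, 0.4, alpha = 1, beta = 0), 2)
  expect_equal(encoder_loss(2, 0.4, alpha = 0, beta = 1), 0.4)
})

test_that("top-k tag selection is ordered and tie-stable", {
  p <- c(0.1, 0.9, 0.1, 0.1)
  expect_equal(select_top_tags(p, 2)[1], 2L)
  expect_equal(select_top_tags(rep(0.5, 6), 3), 1:3)
  set.seed(208)
  for (rep in 1:20) {
    pr <- runif(30)
    got <- select_top_tags(pr, 10)
    expect_equal(pr[got], sort(pr, decreasing = TRUE)[1:10])
  }
})

test_that("every parameter receives gradient from the total loss", {
  ds <- fixture_dataset(6, 99)
  model <- fixture_model()
  data <- crossviewrg:::prepare_data(ds$studies, model$catalog, model$vocab,
                                     model$config)
  batch <- crossviewrg:::make_batch(data, 1:6, model$config)
  tape <- new_tape()
  pn <- crossviewrg:::param_nodes(tape, model$params, grad = TRUE)
  g <- crossviewrg:::build_loss_graph(tape, pn, model, batch)
  ad_backward(g$total)
  for (nm in names(pn)) {
    grad <- pn[[nm]]$grad
    expect_false(is.null(grad), label = paste("gradient reaches", nm))
    expect_gt(max(abs(grad)), 0, label = paste("nonzero gradient in", nm))
  }
})
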