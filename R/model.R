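## Model assembly: configuration, parameter initialisation and the tape
## graph builders shared by training and inference.
##
## Architecture: two small convolutional backbones (one per view) produce
## N x D feature maps; shared squeeze-excitation gates recalibrate each map
## channel-wise and the gated maps are mixed across views by a convex
## lambda / (1 - lambda) combination. Four sigmoid classification heads
## (frontal, lateral and the two cross-view maps) predict the M lesion
## tags. The top-k predicted tags are embedded; three recurrent streams
## (frontal visual, lateral visual, tag semantic) with additive attention
## produce one fused visual-semantic vector per sentence, which drives a
## sentence-level LSTM (topic + stop control) and a word-level LSTM.

#' Model and training configuration
#'
#' Defaults follow the published training conventions of the architecture:
#' mixing weight `lambda_mix = 0.6`, `k_top = 10` tags fed to the decoder,
#' 6 sentences of up to 30 token slots, 512-dimensional embeddings and
#' hidden states, encoder loss weights `alpha = 1`, `beta = 0.05`, total
#' loss weights `lambda_e = lambda_s = lambda_w = 1`, and Adam learning
#' rates 1e-3 (encoder), 1e-4 (visual-semantic fusion), 1e-4 (decoder).
#' The convolutional backbone is the package's small test backbone: three
#' stride-2 blocks ending in `channels[3]` feature channels.
#'
#' @param image_size input image side length (pixels)
#' @param channels channel widths of the three conv blocks; `channels[3]`
#'   is the feature depth D
#' @param se_reduction squeeze-excitation bottleneck ratio r (must divide D)
#' @param k_top number of highest-probability tags passed to the decoder
#' @param lambda_mix cross-view retention weight, in `[0.5, 1]`
#' @param alpha,beta encoder loss weights on BCE and consistency terms
#' @param lambda_e,lambda_s,lambda_w total-loss weights
#' @param lr_encoder,lr_mvsl,lr_decoder Adam learning rates per group
#' @param hidden LSTM hidden size H (all recurrent streams)
#' @param embed_tag tag embedding dimension E
#' @param embed_word word embedding dimension
#' @param attn_dim additive-attention score dimension
#' @param s_max,w_max sentence and per-sentence token limits
#' @param min_count vocabulary frequency threshold
#' @param batch_size,epochs training loop controls
#' @param seed integer seed controlling initialisation and batch order
#' @param branch_mode which classification branches to build:
#'   `"both"`, `"single"` or `"cross"`
#' @param mvsl_input `"cross"` feeds the mixed maps to the fusion streams,
#'   `"single"` the raw per-view maps
#' @param semantic_source `"predicted"` (top-k of averaged branch
#'   predictions) or `"gold"` (ground-truth tags first, padded with top
#'   predictions)
#' @param mode `"full"` trains encoder + decoder; `"encoder"` trains the
#'   classification branches only
#' @param split train/val/test fractions (seeded shuffle)
#' @return list of class `rg_config`
#' @export
rg_config <- function(image_size = 64L,
                      channels = c(8L, 16L, 64L),
                      se_reduction = 4L,
                      k_top = 10L,
                      lambda_mix = 0.6,
                      alpha = 1, beta = 0.05,
                      lambda_e = 1, lambda_s = 1, lambda_w = 1,
                      lr_encoder = 1e-3, lr_mvsl = 1e-4, lr_decoder = 1e-4,
                      hidden = 512L,
                      embed_tag = 512L,
                      embed_word = 512L,
                      attn_dim = 256L,
                      s_max = 6L, w_max = 30L,
                      min_count = 3L,
                      batch_size = 8L, epochs = 30L,
                      seed = 1L,
                      branch_mode = c("both", "single", "cross"),
                      mvsl_input = c("cross", "single"),
                      semantic_source = c("predicted", "gold"),
                      mode = c("full", "encoder"),
                      split = c(train = 0.6, val = 0.2, test = 0.2)) {
  branch_mode <- match.arg(branch_mode)
  mvsl_input <- match.arg(mvsl_input)
  semantic_source <- match.arg(semantic_source)
  mode <- match.arg(mode)
  if (lambda_mix < 0.5 || lambda_mix > 1) {
    stopf("lambda_mix must lie in [0.5, 1]")
  }
  if (alpha < 0 || beta < 0) stopf("loss weights must be >= 0")
  d <- channels[3]
  if (d %% se_reduction != 0) {
    stopf("se_reduction (%d) must divide the feature depth D (%d)",
          se_reduction, d)
  }
  cfg <- as.list(environment())
  class(cfg) <- "rg_config"
  cfg
}

#' Desk-scale configuration profile
#'
#' The configuration used by the package's own tests and examples: 32 px
#' images (N = 16 spatial positions, D = 64 channels), 64-dimensional
#' hidden states, 4 decoder tags, and Adam learning rates scaled up
#' (3e-3 / 1e-3 / 3e-3) for the few hundred optimizer steps of a
#' desk-scale run. Everything else inherits [rg_config()] defaults. Any
#' field can still be overridden.
#' @param ... overrides passed to [rg_config()]
#' @export
rg_toy_config <- function(...) {
  defaults <- list(image_size = 32L, hidden = 64L, embed_tag = 32L,
                   embed_word = 64L, attn_dim = 32L, k_top = 4L,
                   batch_size = 5L, lr_encoder = 3e-3, lr_mvsl = 1e-3,
                   lr_decoder = 3e-3)
  args <- utils::modifyList(defaults, list(...))
  do.call(rg_config, args)
}

init_mat <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- 1 / sqrt(nr)
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

init_lstm <- function(params, prefix, d_in, h) {
  params[[paste0(prefix, ".Wx")]] <- init_mat(d_in, 4L * h)
  params[[paste0(prefix, ".Wh")]] <- init_mat(h, 4L * h)
  b <- matrix(0, 1L, 4L * h)
  b[1, (h + 1L):(2L * h)] <- 1  # forget-gate bias
  params[[paste0(prefix, ".b")]] <- b
  params
}

#' Initialise a model
#'
#' @param config an [rg_config()]
#' @param catalog an `rg_tag_catalog` (fixes M)
#' @param vocab an `rg_vocabulary` (fixes the output vocabulary); may be
#'   `NULL` for `mode = "encoder"`
#' @return list of class `rg_model` with `params`, `config`, `catalog`,
#'   `vocab` and conv geometries
#' @export
init_model <- function(config, catalog, vocab = NULL) {
  stopifnot(inherits(config, "rg_config"))
  if (config$k_top > length(catalog$names)) {
    stopf("k_top (%d) cannot exceed the catalog size (%d)",
          config$k_top, length(catalog$names))
  }
  sz <- config$image_size
  g1 <- conv_geom(sz, sz)
  g2 <- conv_geom(g1$hout, g1$wout)
  g3 <- conv_geom(g2$hout, g2$wout)
  ch <- config$channels
  d <- ch[3]
  h <- config$hidden
  a <- config$attn_dim
  e <- config$embed_tag
  m <- length(catalog$names)
  params <- with_local_seed(config$seed, {
    p <- list()
    for (view in c("f", "l")) {
      cin <- c(1L, ch[1], ch[2])
      for (i in 1:3) {
        p[[sprintf("enc.%s.conv%d.W", view, i)]] <- init_mat(9L * cin[i], ch[i])
        p[[sprintf("enc.%s.conv%d.b", view, i)]] <- matrix(0, 1L, ch[i])
      }
    }
    p[["enc.se.W1"]] <- init_mat(d, d %/% config$se_reduction)
    p[["enc.se.b1"]] <- matrix(0, 1L, d %/% config$se_reduction)
    p[["enc.se.W2"]] <- init_mat(d %/% config$se_reduction, d)
    p[["enc.se.b2"]] <- matrix(0, 1L, d)
    for (br in c("f", "l", "af", "al")) {
      p[[sprintf("enc.head.%s.W", br)]] <- init_mat(d, m)
      p[[sprintf("enc.head.%s.b", br)]] <- matrix(0, 1L, m)
    }
    p[["mvsl.embed"]] <- init_mat(m, e, scale = 0.1)
    p <- init_lstm(p, "mvsl.lstm.vf", d, h)
    p <- init_lstm(p, "mvsl.lstm.vl", d, h)
    p <- init_lstm(p, "mvsl.lstm.ms", e, h)
    for (st in c("vf", "vl")) {
      p[[sprintf("mvsl.att.%s.Wf", st)]] <- init_mat(d, a)
      p[[sprintf("mvsl.att.%s.Wh", st)]] <- init_mat(h, a)
      p[[sprintf("mvsl.att.%s.Wa", st)]] <- init_mat(a, 1L)
    }
    p[["mvsl.att.ms.Wf"]] <- init_mat(e, a)
    p[["mvsl.att.ms.Wh"]] <- init_mat(h, a)
    p[["mvsl.att.ms.Wa"]] <- init_mat(a, 1L)
    p[["mvsl.msproj"]] <- init_mat(e, d)
    p[["mvsl.fuse.W"]] <- init_mat(d, h)
    p <- init_lstm(p, "dec.sent", h, h)
    p[["dec.topic.Wsent"]] <- init_mat(h, h)
    p[["dec.topic.Wmvs"]] <- init_mat(h, h)
    p[["dec.stop.Wprev"]] <- init_mat(h, h)
    p[["dec.stop.Wcur"]] <- init_mat(h, h)
    p[["dec.stop.W"]] <- init_mat(h, 2L)
    if (!is.null(vocab)) {
      v <- length(vocab$tokens)
      p[["dec.wembed"]] <- init_mat(v, config$embed_word, scale = 0.1)
      p <- init_lstm(p, "dec.word", config$embed_word + h, h)
      p[["dec.out.Wword"]] <- init_mat(h, h)
      p[["dec.out.Woutput"]] <- init_mat(h, v)
    }
    p
  })
  model <- list(params = params, config = config, catalog = catalog,
                vocab = vocab, geoms = list(g1, g2, g3),
                n_pos = g3$pout, depth = d)
  class(model) <- "rg_model"
  model
}

# wrap every parameter matrix as a tape leaf (training) or const (inference)
param_nodes <- function(tape, params, grad = TRUE) {
  f <- if (grad) ad_leaf else ad_const
  lapply(params, function(p) f(tape, p))
}

## ---- graph builders ------------------------------------------------------

graph_backbone <- function(tape, pn, x, view, geoms, batch) {
  h <- x
  for (i in 1:3) {
    h <- ad_relu(ad_conv2d(h,
                           pn[[sprintf("enc.%s.conv%d.W", view, i)]],
                           pn[[sprintf("enc.%s.conv%d.b", view, i)]],
                           geoms[[i]], batch))
  }
  h
}

# shared squeeze-excitation gating f: (B*N) x D -> (B*N) x D
graph_se <- function(tape, pn, v, batch, n_pos) {
  s <- ad_segment_mean(v, batch, n_pos)
  z <- ad_relu(ad_add_bias(ad_mm(s, pn[["enc.se.W1"]]), pn[["enc.se.b1"]]))
  g <- ad_sigmoid(ad_add_bias(ad_mm(z, pn[["enc.se.W2"]]), pn[["enc.se.b2"]]))
  ad_mul(v, ad_rows(g, rep(seq_len(batch), each = n_pos)))
}

graph_head <- function(tape, pn, v, branch, batch, n_pos) {
  pool <- ad_segment_mean(v, batch, n_pos)
  ad_sigmoid(ad_add_bias(ad_mm(pool, pn[[sprintf("enc.head.%s.W", branch)]]),
                         pn[[sprintf("enc.head.%s.b", branch)]]))
}

# full encoder: images to feature maps, branch predictions and the maps the
# fusion module consumes
graph_encoder <- function(tape, pn, xf, xl, model, batch) {
  cfg <- model$config
  n_pos <- model$n_pos
  vf <- graph_backbone(tape, pn, xf, "f", model$geoms, batch)
  vl <- graph_backbone(tape, pn, xl, "l", model$geoms, batch)
  preds <- list()
  vaf <- val <- NULL
  if (cfg$branch_mode %in% c("both", "single")) {
    preds$y_f <- graph_head(tape, pn, vf, "f", batch, n_pos)
    preds$y_l <- graph_head(tape, pn, vl, "l", batch, n_pos)
  }
  if (cfg$branch_mode %in% c("both", "cross")) {
    fvf <- graph_se(tape, pn, vf, batch, n_pos)
    fvl <- graph_se(tape, pn, vl, batch, n_pos)
    lam <- cfg$lambda_mix
    vaf <- ad_add(ad_scale(fvf, lam), ad_scale(fvl, 1 - lam))
    val <- ad_add(ad_scale(fvl, lam), ad_scale(fvf, 1 - lam))
    preds$y_af <- graph_head(tape, pn, vaf, "af", batch, n_pos)
    preds$y_al <- graph_head(tape, pn, val, "al", batch, n_pos)
  }
  feed <- if (cfg$mvsl_input == "cross" && !is.null(vaf)) {
    list(vf = vaf, vl = val)
  } else {
    list(vf = vf, vl = vl)
  }
  list(vf = vf, vl = vl, vaf = vaf, val = val, preds = preds, feed = feed)
}

graph_lstm_step <- function(pn, prefix, x, h, c, hidden) {
  gates <- ad_add_bias(ad_add(ad_mm(x, pn[[paste0(prefix, ".Wx")]]),
                              ad_mm(h, pn[[paste0(prefix, ".Wh")]])),
                       pn[[paste0(prefix, ".b")]])
  i <- ad_sigmoid(ad_cols(gates, 1L, hidden))
  f <- ad_sigmoid(ad_cols(gates, hidden + 1L, 2L * hidden))
  g <- ad_tanh(ad_cols(gates, 2L * hidden + 1L, 3L * hidden))
  o <- ad_sigmoid(ad_cols(gates, 3L * hidden + 1L, 4L * hidden))
  c2 <- ad_add(ad_mul(f, c), ad_mul(i, g))
  list(h = ad_mul(o, ad_tanh(c2)), c = c2)
}

# additive attention over the rows of one stream:
# scores_i = Wa' tanh(Wf F_i + Wh h); softmax over the stream's rows
graph_attention <- function(tape, pn, stream, feat, h, batch, rows) {
  pf <- pn[[sprintf("mvsl.att.%s.Wf", stream)]]
  ph <- pn[[sprintf("mvsl.att.%s.Wh", stream)]]
  pa <- pn[[sprintf("mvsl.att.%s.Wa", stream)]]
  hx <- ad_rows(ad_mm(h, ph), rep(seq_len(batch), each = rows))
  sc <- ad_mm(ad_tanh(ad_add(ad_mm(feat, pf), hx)), pa)  # (B*rows) x 1
  scm <- ad_node(tape, matrix(sc$val, batch, rows, byrow = TRUE), list(sc),
                 function(nd) {
                   acc_grad(nd$parents[[1L]],
                            matrix(as.vector(t(nd$grad)), ncol = 1L))
                 })
  w <- ad_rowsoftmax(scm)                                 # B x rows
  list(weights = w, attended = ad_attend(feat, w, batch, rows))
}

# one sentence step of the visual-semantic fusion module; state holds h/c
# nodes for the three streams
graph_mvsl_step <- function(tape, pn, feed, ms, state, model, batch) {
  cfg <- model$config
  h <- cfg$hidden
  n_pos <- model$n_pos
  k <- nrow(ms$val) / batch
  streams <- list(vf = feed$vf, vl = feed$vl, ms = ms)
  rows <- list(vf = n_pos, vl = n_pos, ms = k)
  att <- list()
  new_state <- state
  for (st in names(streams)) {
    xin <- ad_segment_mean(streams[[st]], batch, rows[[st]])
    upd <- graph_lstm_step(pn, paste0("mvsl.lstm.", st), xin,
                           state[[st]]$h, state[[st]]$c, h)
    new_state[[st]] <- upd
    att[[st]] <- graph_attention(tape, pn, st, streams[[st]], upd$h,
                                 batch, rows[[st]])
  }
  ms_att_d <- ad_mm(att$ms$attended, pn[["mvsl.msproj"]])
  fused <- ad_add(ad_add(att$vf$attended, att$vl$attended), ms_att_d)
  mvs <- ad_mm(fused, pn[["mvsl.fuse.W"]])
  list(mvs = mvs,
       weights = list(a_vf = att$vf$weights, a_vl = att$vl$weights,
                      a_ms = att$ms$weights),
       state = new_state)
}

# sentence-level decoder step: topic vector + 2-class stop logits
graph_sentence_step <- function(tape, pn, mvs, state, hidden) {
  h_prev <- state$h
  upd <- graph_lstm_step(pn, "dec.sent", mvs, state$h, state$c, hidden)
  topic <- ad_tanh(ad_add(ad_mm(upd$h, pn[["dec.topic.Wsent"]]),
                          ad_mm(mvs, pn[["dec.topic.Wmvs"]])))
  stop_in <- ad_tanh(ad_add(ad_mm(h_prev, pn[["dec.stop.Wprev"]]),
                            ad_mm(upd$h, pn[["dec.stop.Wcur"]])))
  stop_logits <- ad_mm(stop_in, pn[["dec.stop.W"]])
  list(topic = topic, stop_logits = stop_logits, state = upd)
}

# word-level decoder step: embeds the previous token, conditions on the
# topic by concatenation, emits vocabulary logits
graph_word_step <- function(tape, pn, prev_ids, topic, state, hidden) {
  x <- ad_rows(pn[["dec.wembed"]], prev_ids)
  upd <- graph_lstm_step(pn, "dec.word", ad_concat_cols(x, topic),
                         state$h, state$c, hidden)
  logits <- ad_mm(ad_mm(upd$h, pn[["dec.out.Wword"]]), pn[["dec.out.Woutput"]])
  list(logits = logits, state = upd)
}

zero_state <- function(tape, batch, hidden) {
  list(h = ad_const(tape, matrix(0, batch, hidden)),
       c = ad_const(tape, matrix(0, batch, hidden)))
}

zero_mvsl_state <- function(tape, batch, hidden) {
  list(vf = zero_state(tape, batch, hidden),
       vl = zero_state(tape, batch, hidden),
       ms = zero_state(tape, batch, hidden))
}
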