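## Hierarchical sentence/word decoder: operation-level API, decoder losses
## and greedy report generation.

#' Initial (zero) decoder LSTM state
#' @param hidden hidden size H
#' @export
decoder_init_state <- function(hidden) {
  z <- matrix(0, 1L, hidden)
  list(h = z, c = z, s = 0L)
}

#' One sentence-level decoder step
#'
#' The sentence LSTM consumes the visual-semantic feature of the current
#' sentence; the topic vector is
#' `tanh(W_sent h_s + W_mvs MVS_s)` and the 2-class stop logits are
#' `W_stop tanh(W_prev h_(s-1) + W_cur h_s)` (column 1 = continue,
#' column 2 = stop).
#'
#' @param mvs length-H visual-semantic feature
#' @param state decoder state from [decoder_init_state()] or a previous step
#' @param model an `rg_model`
#' @return list with `topic` (length-H, entries in (-1, 1)), `stop_logits`
#'   (length-2) and the advanced `state`
#' @export
sentence_step <- function(mvs, state, model) {
  tape <- new_tape()
  nms <- c("dec.sent.Wx", "dec.sent.Wh", "dec.sent.b", "dec.topic.Wsent",
           "dec.topic.Wmvs", "dec.stop.Wprev", "dec.stop.Wcur", "dec.stop.W")
  pn <- param_nodes(tape, model$params[nms], grad = FALSE)
  out <- graph_sentence_step(tape, pn, ad_const(tape, matrix(mvs, 1L)),
                             list(h = ad_const(tape, state$h),
                                  c = ad_const(tape, state$c)),
                             model$config$hidden)
  list(topic = as.vector(out$topic$val),
       stop_logits = as.vector(out$stop_logits$val),
       state = list(h = out$state$h$val, c = out$state$c$val,
                    s = state$s + 1L))
}

#' One word-level decoder step
#'
#' Embeds the previous token, concatenates it with the sentence topic as
#' the word LSTM input, and returns the softmax distribution over the
#' vocabulary: `p = softmax(W_output (W_word h))`.
#'
#' @param prev_token_id previous token id (1-based; `<bos>` at t = 0)
#' @param topic length-H topic vector
#' @param state list with `h` and `c` (1 x H matrices)
#' @param model an `rg_model`
#' @return list with `probs` (sums to 1) and the advanced `state`
#' @export
word_step <- function(prev_token_id, topic, state, model) {
  tape <- new_tape()
  nms <- c("dec.wembed", "dec.word.Wx", "dec.word.Wh", "dec.word.b",
           "dec.out.Wword", "dec.out.Woutput")
  pn <- param_nodes(tape, model$params[nms], grad = FALSE)
  out <- graph_word_step(tape, pn, as.integer(prev_token_id),
                         ad_const(tape, matrix(topic, 1L)),
                         list(h = ad_const(tape, state$h),
                              c = ad_const(tape, state$c)),
                         model$config$hidden)
  probs <- ad_rowsoftmax(out$logits)$val
  list(probs = as.vector(probs),
       state = list(h = out$state$h$val, c = out$state$c$val))
}

as_sample_list <- function(x) if (is.list(x)) x else list(x)

#' Stop-control loss
#'
#' Cross-entropy of the 2-way stop softmax against the per-sentence stop
#' targets, masked past the true report end and averaged over samples.
#'
#' @param logits `S x 2` matrix (one sample) or list of such matrices
#' @param targets 0/1 vector of length `S` per sample (1 = stop)
#' @param mask 0/1 vector per sample; steps with 0 are ignored
#' @return scalar loss
#' @export
stop_loss <- function(logits, targets, mask = NULL) {
  logits <- as_sample_list(logits)
  targets <- if (is.list(targets)) targets else list(targets)
  mask <- if (is.null(mask)) {
    lapply(targets, function(t) rep(1, length(t)))
  } else if (is.list(mask)) mask else list(mask)
  per <- mapply(function(lg, tg, mk) {
    z <- lg - apply(lg, 1L, max)
    lp <- z - log(rowSums(exp(z)))
    sum(mk * -lp[cbind(seq_len(nrow(lg)), tg + 1L)])
  }, logits, targets, mask)
  mean(per)
}

#' Word generation loss
#'
#' `-sum_t log p_t(target_t)` over unmasked positions, averaged over
#' samples. Distributions are clamped away from zero before the log.
#'
#' @param probs `T x V` matrix of per-position distributions (one sample)
#'   or a list of such matrices
#' @param targets integer token-id vector per sample
#' @param mask 0/1 vector per sample (pad positions get 0)
#' @param eps log clamp
#' @return scalar loss
#' @export
word_loss <- function(probs, targets, mask = NULL, eps = 1e-12) {
  probs <- as_sample_list(probs)
  targets <- if (is.list(targets)) targets else list(targets)
  mask <- if (is.null(mask)) {
    lapply(targets, function(t) rep(1, length(t)))
  } else if (is.list(mask)) mask else list(mask)
  per <- mapply(function(p, tg, mk) {
    sum(mk * -log(pmax(p[cbind(seq_along(tg), tg)], eps)))
  }, probs, targets, mask)
  mean(per)
}

#' Total training loss `lambda_e L_enc + lambda_s L_stop + lambda_w L_word`
#' @param l_encoder,l_stop,l_word component losses
#' @param weights length-3 nonnegative vector `(lambda_e, lambda_s, lambda_w)`
#' @export
total_loss <- function(l_encoder, l_stop, l_word, weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3, all(weights >= 0))
  weights[1] * l_encoder + weights[2] * l_stop + weights[3] * l_word
}

#' Generate a report for one image pair
#'
#' Runs the encoder, selects the top-k tags, embeds them, and decodes
#' greedily: per sentence one fusion step and one sentence step; words are
#' emitted from `<bos>` until `<eos>` or the per-sentence limit; the
#' sentence is appended and generation halts when the stop softmax argmax
#' says stop (or after `s_max` sentences). Deterministic given the model
#' and images.
#'
#' @param frontal,lateral image matrices in `[0, 1]` or PNG file paths
#' @param model a trained `rg_model`
#' @param s_max,w_max optional overrides of the model's sentence/token limits
#' @return list with `sentences`, `tags` (selected tag names, descending
#'   probability), `tag_probs`, and `attention` (per sentence: `a_vf`,
#'   `a_vl`, and `a_ms` with tag names)
#' @export
generate_report <- function(frontal, lateral, model,
                            s_max = NULL, w_max = NULL) {
  if (is.null(model$vocab)) stopf("model has no decoder (encoder-only mode)")
  cfg <- model$config
  s_max <- s_max %||% cfg$s_max
  w_max <- w_max %||% cfg$w_max
  if (is.character(frontal)) frontal <- png::readPNG(frontal)
  if (is.character(lateral)) lateral <- png::readPNG(lateral)
  tape <- new_tape()
  pn <- param_nodes(tape, model$params, grad = FALSE)
  xf <- ad_const(tape, matrix(as.vector(t(frontal)), ncol = 1L))
  xl <- ad_const(tape, matrix(as.vector(t(lateral)), ncol = 1L))
  enc <- graph_encoder(tape, pn, xf, xl, model, 1L)
  probs <- as.vector(combined_probs(lapply(enc$preds, function(p) p$val)))
  sel <- select_top_tags(probs, cfg$k_top)
  ms <- ad_rows(pn[["mvsl.embed"]], sel)
  h <- cfg$hidden
  mstate <- zero_mvsl_state(tape, 1L, h)
  sstate <- zero_state(tape, 1L, h)
  sentences <- character(0)
  attention <- list()
  for (s in seq_len(s_max)) {
    mv <- graph_mvsl_step(tape, pn, enc$feed, ms, mstate, model, 1L)
    mstate <- mv$state
    sent <- graph_sentence_step(tape, pn, mv$mvs, sstate, h)
    sstate <- sent$state
    wstate <- zero_state(tape, 1L, h)
    prev <- BOS_ID
    words <- integer(0)
    for (t in seq_len(w_max - 2L)) {
      wd <- graph_word_step(tape, pn, prev, sent$topic, wstate, h)
      wstate <- wd$state
      nxt <- which.max(wd$logits$val[1L, ])
      if (nxt == EOS_ID) break
      words <- c(words, nxt)
      prev <- nxt
    }
    sentences <- c(sentences, paste(decode_tokens(words, model$vocab),
                                    collapse = " "))
    attention[[s]] <- list(
      sentence_idx = s,
      a_vf = as.vector(mv$weights$a_vf$val),
      a_vl = as.vector(mv$weights$a_vl$val),
      a_ms = data.frame(tag = model$catalog$names[sel],
                        weight = as.vector(mv$weights$a_ms$val)))
    if (which.max(sent$stop_logits$val[1L, ]) == 2L) break
  }
  list(sentences = sentences,
       tags = model$catalog$names[sel],
       tag_probs = probs[sel],
       attention = attention)
}
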