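## Training pipeline: data preparation, the end-to-end loss graph, the
## three-group Adam loop, checkpointing, evaluation and the lambda sweep.

flatten_image <- function(img) matrix(as.vector(t(img)), ncol = 1L)

# precompute per-study tensors: flattened images, multi-hot tags, encoded report
prepare_data <- function(studies, catalog, vocab, cfg) {
  lapply(studies, function(s) {
    imgs <- load_study_images(s)
    if (nrow(imgs$frontal) != cfg$image_size) {
      stopf("study %s: image size %d does not match config image_size %d",
            s$study_id, nrow(imgs$frontal), cfg$image_size)
    }
    enc <- if (!is.null(vocab)) {
      encode_report(s$report, vocab, cfg$s_max, cfg$w_max)
    }
    list(study = s,
         xf = flatten_image(imgs$frontal),
         xl = flatten_image(imgs$lateral),
         tags = encode_tags(s$tags, catalog),
         enc = enc)
  })
}

make_batch <- function(data, idx, cfg) {
  b <- length(idx)
  sub <- data[idx]
  batch <- list(
    B = b,
    xf = do.call(rbind, lapply(sub, `[[`, "xf")),
    xl = do.call(rbind, lapply(sub, `[[`, "xl")),
    tags = do.call(rbind, lapply(sub, `[[`, "tags")))
  if (!is.null(sub[[1]]$enc)) {
    s_max <- cfg$s_max
    batch$tok <- array(PAD_ID, dim = c(b, s_max, cfg$w_max))
    batch$lens <- matrix(0L, b, s_max)
    batch$stop <- matrix(1L, b, s_max)
    batch$n_sent <- integer(b)
    for (i in seq_len(b)) {
      e <- sub[[i]]$enc
      batch$tok[i, , ] <- e$token_ids
      batch$lens[i, ] <- e$lengths
      batch$stop[i, ] <- e$stop
      batch$n_sent[i] <- e$n_sentences
    }
    batch$smask <- outer(batch$n_sent, seq_len(s_max), `>=`) * 1
  }
  batch
}

# builds the full training loss graph on `tape`; returns loss nodes plus
# teacher-forced word statistics computed from the eager forward values
build_loss_graph <- function(tape, pn, model, batch) {
  cfg <- model$config
  b <- batch$B
  xf <- ad_const(tape, batch$xf)
  xl <- ad_const(tape, batch$xl)
  enc <- graph_encoder(tape, pn, xf, xl, model, b)
  bce_terms <- lapply(enc$preds, function(p) ad_bce_sum(p, batch$tags))
  l_bce <- ad_scale(Reduce(ad_add, bce_terms), 1 / b)
  l_cvam <- if (cfg$branch_mode == "both") {
    sq <- function(a, bb) {
      d <- ad_sub(a, bb)
      ad_sum(ad_mul(d, d))
    }
    ad_scale(ad_add(sq(enc$preds$y_f, enc$preds$y_l),
                    sq(enc$preds$y_af, enc$preds$y_al)), 1 / b)
  } else {
    ad_const(tape, matrix(0, 1L, 1L))
  }
  l_encoder <- ad_add(ad_scale(l_bce, cfg$alpha), ad_scale(l_cvam, cfg$beta))
  out <- list(enc = enc, l_bce = l_bce, l_cvam = l_cvam,
              l_encoder = l_encoder)
  if (cfg$mode == "encoder") {
    out$total <- ad_scale(l_encoder, cfg$lambda_e)
    return(out)
  }
  probs <- combined_probs(lapply(enc$preds, function(p) p$val))
  score <- if (cfg$semantic_source == "gold") 2 * batch$tags + probs else probs
  sel <- t(apply(score, 1L, function(p) {
    order(-p, seq_along(p))[seq_len(cfg$k_top)]
  }))
  if (cfg$k_top == 1L) sel <- matrix(sel, ncol = 1L)
  ms <- ad_rows(pn[["mvsl.embed"]], as.vector(t(sel)))
  h <- cfg$hidden
  mstate <- zero_mvsl_state(tape, b, h)
  sstate <- zero_state(tape, b, h)
  l_stop <- NULL
  l_word <- NULL
  n_correct <- 0
  n_words <- 0
  s_use <- max(batch$n_sent)
  for (s in seq_len(s_use)) {
    mv <- graph_mvsl_step(tape, pn, enc$feed, ms, mstate, model, b)
    mstate <- mv$state
    sent <- graph_sentence_step(tape, pn, mv$mvs, sstate, h)
    sstate <- sent$state
    term <- ad_ce_loss(sent$stop_logits, batch$stop[, s] + 1L,
                       batch$smask[, s] / b)
    l_stop <- if (is.null(l_stop)) term else ad_add(l_stop, term)
    max_len <- max(batch$lens[, s])
    if (max_len < 2L) next
    wstate <- zero_state(tape, b, h)
    for (t in seq_len(max_len - 1L)) {
      prev <- batch$tok[, s, t]
      tgt <- batch$tok[, s, t + 1L]
      wt <- (tgt != PAD_ID) / b
      wd <- graph_word_step(tape, pn, prev, sent$topic, wstate, h)
      wstate <- wd$state
      term <- ad_ce_loss(wd$logits, tgt, wt)
      l_word <- if (is.null(l_word)) term else ad_add(l_word, term)
      live <- wt > 0
      if (any(live)) {
        pred <- max.col(wd$logits$val, ties.method = "first")
        n_correct <- n_correct + sum(pred[live] == tgt[live])
        n_words <- n_words + sum(live)
      }
    }
  }
  out$l_stop <- l_stop
  out$l_word <- l_word %||% ad_const(tape, matrix(0, 1L, 1L))
  out$total <- ad_add(ad_add(ad_scale(l_encoder, cfg$lambda_e),
                             ad_scale(l_stop, cfg$lambda_s)),
                      ad_scale(out$l_word, cfg$lambda_w))
  out$word_correct <- n_correct
  out$word_total <- n_words
  out
}

lr_for_params <- function(params, cfg) {
  nm <- names(params)
  lr <- ifelse(startsWith(nm, "enc."), cfg$lr_encoder,
               ifelse(startsWith(nm, "mvsl."), cfg$lr_mvsl, cfg$lr_decoder))
  stats::setNames(lr, nm)
}

#' Split studies into train/validation/test subsets
#' @param studies list of studies
#' @param split named fractions summing to 1
#' @param seed shuffle seed
#' @export
split_studies <- function(studies, split = c(train = 0.6, val = 0.2, test = 0.2),
                          seed = 1L) {
  n <- length(studies)
  idx <- with_local_seed(seed, sample.int(n))
  n_train <- round(split[[1]] * n)
  n_val <- round(split[[2]] * n)
  list(train = studies[idx[seq_len(n_train)]],
       val = studies[idx[seq_len(n_val) + n_train]],
       test = studies[idx[setdiff(seq_len(n), seq_len(n_train + n_val))]])
}

#' Train a model
#'
#' Optimizes the total loss (encoder BCE + consistency, stop-control and
#' word cross-entropies) end to end with teacher forcing, using Adam with
#' three learning-rate groups (encoder / fusion / decoder). Fully seeded:
#' the same inputs and config give the same final parameters.
#'
#' @param config an [rg_config()]
#' @param studies list of studies (e.g. from [read_manifest()] or
#'   [make_dataset()])
#' @param catalog an `rg_tag_catalog`
#' @param vocab optional pre-built vocabulary; built from the training
#'   reports at `config$min_count` when `NULL`
#' @param val_studies optional validation studies; when supplied, the
#'   checkpoint with the lowest validation word loss (teacher-forced) is
#'   returned
#' @param out_dir optional directory for `runlog.jsonl` and
#'   `checkpoint.rds`
#' @param verbose print per-epoch losses
#' @return list with `model`, `history` (data.frame of per-step losses)
#'   and `final` (last-epoch training stats incl. `word_accuracy`)
#' @export
train <- function(config, studies, catalog, vocab = NULL,
                  val_studies = NULL, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "rg_config"))
  if (length(studies) == 0L) stopf("no training studies")
  if (is.null(vocab) && config$mode == "full") {
    vocab <- build_vocabulary(lapply(studies, `[[`, "report"),
                              config$min_count)
  }
  model <- init_model(config, catalog, vocab)
  data <- prepare_data(studies, catalog, vocab, config)
  val_data <- if (length(val_studies)) {
    prepare_data(val_studies, catalog, vocab, config)
  }
  lr <- lr_for_params(model$params, config)
  opt <- adam_state(model$params)
  log_path <- if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.path(out_dir, "runlog.jsonl")
  }
  if (!is.null(log_path) && file.exists(log_path)) file.remove(log_path)
  history <- list()
  best <- list(loss = Inf, params = model$params)
  step <- 0L
  final <- NULL
  with_local_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(data))
      epoch_stats <- c(total = 0, n = 0, correct = 0, words = 0)
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        batch <- make_batch(data, idx, config)
        tape <- new_tape()
        pn <- param_nodes(tape, model$params, grad = TRUE)
        g <- build_loss_graph(tape, pn, model, batch)
        comps <- c(encoder = g$l_encoder$val[1],
                   stop = if (!is.null(g$l_stop)) g$l_stop$val[1] else NA,
                   word = if (!is.null(g$l_word)) g$l_word$val[1] else NA,
                   total = g$total$val[1])
        if (!is.finite(comps[["total"]])) {
          bad <- names(comps)[!is.finite(comps)]
          stopf("non-finite loss at epoch %d (offending term: %s)",
                epoch, paste(bad, collapse = ", "))
        }
        ad_backward(g$total)
        grads <- lapply(pn, function(nd) nd$grad)
        upd <- adam_step(model$params, grads, opt, lr)
        model$params <- upd$params
        opt <- upd$state
        step <- step + 1L
        rec <- list(epoch = epoch, step = step,
                    l_encoder = unname(comps[["encoder"]]),
                    l_stop = unname(comps[["stop"]]),
                    l_word = unname(comps[["word"]]),
                    total = unname(comps[["total"]]))
        history[[step]] <- rec
        if (!is.null(log_path)) {
          cat(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"),
              "\n", sep = "", file = log_path, append = TRUE)
        }
        epoch_stats["total"] <- epoch_stats["total"] + comps[["total"]]
        epoch_stats["n"] <- epoch_stats["n"] + 1
        epoch_stats["correct"] <- epoch_stats["correct"] +
          (g$word_correct %||% 0)
        epoch_stats["words"] <- epoch_stats["words"] + (g$word_total %||% 0)
      }
      val_loss <- if (!is.null(val_data) && config$mode == "full") {
        forward_word_loss(model, val_data)
      } else {
        epoch_stats[["total"]] / epoch_stats[["n"]]
      }
      if (val_loss <= best$loss) {
        best <- list(loss = val_loss, params = model$params)
      }
      final <- list(
        epoch = epoch,
        mean_total = epoch_stats[["total"]] / epoch_stats[["n"]],
        word_accuracy = if (epoch_stats[["words"]] > 0) {
          epoch_stats[["correct"]] / epoch_stats[["words"]]
        } else NA_real_,
        val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  word_acc %s  val %.4f",
                        epoch, final$mean_total,
                        if (is.na(final$word_accuracy)) "-" else
                          sprintf("%.3f", final$word_accuracy),
                        val_loss))
      }
    }
  })
  model$params <- best$params
  history <- do.call(rbind, lapply(history, as.data.frame))
  if (!is.null(out_dir)) {
    save_checkpoint(model, file.path(out_dir, "checkpoint.rds"))
  }
  list(model = model, history = history, final = final)
}

# teacher-forced mean total word loss on a prepared dataset (no gradients)
forward_word_loss <- function(model, data) {
  losses <- vapply(seq(1L, length(data), by = model$config$batch_size),
    function(start) {
      idx <- start:min(start + model$config$batch_size - 1L, length(data))
      batch <- make_batch(data, idx, model$config)
      tape <- new_tape()
      pn <- param_nodes(tape, model$params, grad = FALSE)
      g <- build_loss_graph(tape, pn, model, batch)
      g$l_word$val[1]
    }, numeric(1))
  mean(losses)
}

#' Teacher-forced word accuracy of a model on a set of studies
#' @param model an `rg_model`
#' @param studies list of studies
#' @return fraction of next-word predictions that match the gold token
#' @export
word_accuracy <- function(model, studies) {
  data <- prepare_data(studies, model$catalog, model$vocab, model$config)
  batch <- make_batch(data, seq_along(data), model$config)
  tape <- new_tape()
  pn <- param_nodes(tape, model$params, grad = FALSE)
  g <- build_loss_graph(tape, pn, model, batch)
  g$word_correct / g$word_total
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: parameters, configuration, tag
#' catalog and vocabulary in one archive.
#' @param model an `rg_model`
#' @param path file path (`.rds`)
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(params = model$params, config = model$config,
               catalog = model$catalog, vocab = model$vocab), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  for (f in c("params", "config", "catalog")) {
    if (is.null(obj[[f]])) stopf("checkpoint %s is missing '%s'", path, f)
  }
  init <- init_model(obj$config, obj$catalog, obj$vocab)
  if (!identical(sort(names(init$params)), sort(names(obj$params)))) {
    stopf("checkpoint %s parameters do not match its configuration", path)
  }
  init$params <- obj$params
  init
}

#' Branch predictions for a set of studies
#' @param model an `rg_model`
#' @param studies list of studies
#' @return list of `n x M` probability matrices (`y_f`, `y_l`, `y_af`,
#'   `y_al`; absent branches NULL) plus `tags` (`n x M` labels)
#' @export
encoder_predict <- function(model, studies) {
  data <- prepare_data(studies, model$catalog, NULL, model$config)
  batch <- make_batch(data, seq_along(data), model$config)
  tape <- new_tape()
  pn <- param_nodes(tape, model$params, grad = FALSE)
  enc <- graph_encoder(tape, pn, ad_const(tape, batch$xf),
                       ad_const(tape, batch$xl), model, batch$B)
  c(lapply(enc$preds, function(p) p$val), list(tags = batch$tags))
}

#' Evaluate a checkpoint on a set of studies
#'
#' Generates a report per study, scores the generated corpus against the
#' references (reports flattened to one token sequence per study) with
#' BLEU-1..4, ROUGE-L and CIDEr, and computes macro AUC of the per-view
#' single-branch heads (`AUC-f`, `AUC-l`) and of the averaged branch
#' prediction (`AUC`) against the tag labels.
#'
#' @param model an `rg_model` or a checkpoint path
#' @param studies list of studies
#' @param out_json optional path to write the metrics as JSON
#' @return named list of metrics
#' @export
evaluate_checkpoint <- function(model, studies, out_json = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (length(studies) == 0L) stopf("no studies to evaluate")
  cands <- list()
  refs <- list()
  for (i in seq_along(studies)) {
    s <- studies[[i]]
    gen <- generate_report(s$frontal_path, s$lateral_path, model)
    cands[[i]] <- unlist(lapply(gen$sentences, tokenize))
    refs[[i]] <- list(unlist(lapply(s$report, tokenize)))
  }
  preds <- encoder_predict(model, studies)
  auc_f <- if (!is.null(preds$y_f)) macro_auc(preds$y_f, preds$tags)$macro
           else NA_real_
  auc_l <- if (!is.null(preds$y_l)) macro_auc(preds$y_l, preds$tags)$macro
           else NA_real_
  comb <- combined_probs(preds[c("y_f", "y_l", "y_af", "y_al")])
  metrics <- list(
    "BLEU-1" = bleu_n(cands, refs, 1L),
    "BLEU-2" = bleu_n(cands, refs, 2L),
    "BLEU-3" = bleu_n(cands, refs, 3L),
    "BLEU-4" = bleu_n(cands, refs, 4L),
    "ROUGE-L" = rouge_l(cands, refs),
    "CIDEr" = cider(cands, refs),
    "AUC" = macro_auc(comb, preds$tags)$macro,
    "AUC-f" = auc_f,
    "AUC-l" = auc_l)
  if (!is.null(out_json)) {
    jsonlite::write_json(metrics, out_json, auto_unbox = TRUE, digits = NA)
  }
  metrics
}

#' Sweep the cross-view mixing weight
#'
#' Trains one seeded encoder-only model per lambda and reports the
#' classification AUC grid (frontal head, lateral head, averaged
#' prediction).
#'
#' @param config an [rg_config()] (its `lambda_mix` is overridden)
#' @param lambdas values in `[0.5, 1]`
#' @param studies,catalog training data
#' @param eval_studies studies to compute AUC on (defaults to `studies`)
#' @return data.frame with columns `lambda`, `auc_f`, `auc_l`, `auc`
#' @export
lambda_sweep <- function(config, lambdas, studies, catalog,
                         eval_studies = NULL) {
  if (any(lambdas < 0.5 | lambdas > 1)) {
    stopf("lambda values must lie in [0.5, 1]")
  }
  eval_studies <- eval_studies %||% studies
  rows <- lapply(lambdas, function(lam) {
    cfg <- config
    cfg$lambda_mix <- lam
    cfg$mode <- "encoder"
    fit <- train(cfg, studies, catalog)
    preds <- encoder_predict(fit$model, eval_studies)
    comb <- combined_probs(preds[c("y_f", "y_l", "y_af", "y_al")])
    data.frame(
      lambda = lam,
      auc_f = if (!is.null(preds$y_f)) macro_auc(preds$y_f, preds$tags)$macro
              else NA_real_,
      auc_l = if (!is.null(preds$y_l)) macro_auc(preds$y_l, preds$tags)$macro
              else NA_real_,
      auc = macro_auc(comb, preds$tags)$macro)
  })
  do.call(rbind, rows)
}

#' Dump per-sentence attention weights as JSON
#'
#' Numeric counterpart of an attention-overlay visualization: for each
#' generated sentence, the spatial attention over the frontal and lateral
#' feature-map positions and the weight on each selected tag.
#'
#' @param model an `rg_model` or checkpoint path
#' @param frontal,lateral PNG paths or image matrices
#' @param out_json optional output path
#' @return the attention records, invisibly when written to file
#' @export
attn_dump <- function(model, frontal, lateral, out_json = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  gen <- generate_report(frontal, lateral, model)
  recs <- lapply(gen$attention, function(a) {
    list(sentence_idx = a$sentence_idx, a_vf = a$a_vf, a_vl = a$a_vl,
         a_ms = lapply(seq_len(nrow(a$a_ms)), function(i) {
           list(tag = a$a_ms$tag[i], weight = a$a_ms$weight[i])
         }))
  })
  if (!is.null(out_json)) {
    jsonlite::write_json(recs, out_json, auto_unbox = TRUE, digits = NA)
    return(invisible(recs))
  }
  recs
}
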