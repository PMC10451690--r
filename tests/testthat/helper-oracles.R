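# Independent straight-line / loop reference implementations used as
# oracles. These are deliberately naive (explicit loops, no shared code
# with R/) and implement each operation directly from its definition.

sigm <- function(x) 1 / (1 + exp(-x))

# squeeze-excitation, two explicit loops
ref_se <- function(v, p) {
  n <- nrow(v); d <- ncol(v)
  s <- numeric(d)
  for (j in seq_len(d)) s[j] <- mean(v[, j])
  z <- pmax(as.vector(s %*% p$W1 + p$b1), 0)
  g <- sigm(as.vector(z %*% p$W2 + p$b2))
  out <- matrix(0, n, d)
  for (i in seq_len(n)) for (j in seq_len(d)) out[i, j] <- v[i, j] * g[j]
  out
}

ref_mix <- function(vf, vl, p, lam) {
  fvf <- ref_se(vf, p); fvl <- ref_se(vl, p)
  list(vaf = lam * fvf + (1 - lam) * fvl,
       val = lam * fvl + (1 - lam) * fvf)
}

ref_head <- function(v, w, b) {
  pool <- numeric(ncol(v))
  for (j in seq_len(ncol(v))) pool[j] <- mean(v[, j])
  sigm(as.vector(pool %*% w) + as.vector(b))
}

ref_cvam_loss <- function(yf, yl, yaf, yal) {
  ls <- 0; lc <- 0
  for (i in seq_along(yf)) ls <- ls + (yf[i] - yl[i])^2
  for (i in seq_along(yaf)) lc <- lc + (yaf[i] - yal[i])^2
  list(l_single = ls, l_cross = lc, l_cvam = ls + lc)
}

ref_bce <- function(preds, t, eps = 1e-7) {
  total <- 0
  for (p in preds) {
    for (i in seq_along(t)) {
      pi <- min(max(p[i], eps), 1 - eps)
      total <- total - (t[i] * log(pi) + (1 - t[i]) * log(1 - pi))
    }
  }
  total
}

ref_lstm_step <- function(x, h, c, wx, wh, b) {
  hh <- length(h)
  gates <- as.vector(x %*% wx) + as.vector(h %*% wh) + as.vector(b)
  i <- sigm(gates[1:hh])
  f <- sigm(gates[(hh + 1):(2 * hh)])
  g <- tanh(gates[(2 * hh + 1):(3 * hh)])
  o <- sigm(gates[(3 * hh + 1):(4 * hh)])
  c2 <- f * c + i * g
  list(h = o * tanh(c2), c = c2)
}

ref_softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# one fusion step: per stream, LSTM on the row mean, additive attention
# over rows, attended sum; semantic projected; fused through W
ref_mvsl_step <- function(vf, vl, ms, state, p) {
  streams <- list(vf = vf, vl = vl, ms = ms)
  att <- list(); hs <- list(); new_state <- state
  for (st in names(streams)) {
    f <- streams[[st]]
    xin <- numeric(ncol(f))
    for (j in seq_len(ncol(f))) xin[j] <- mean(f[, j])
    upd <- ref_lstm_step(matrix(xin, 1), state[[st]]$h, state[[st]]$c,
                         p[[paste0("mvsl.lstm.", st, ".Wx")]],
                         p[[paste0("mvsl.lstm.", st, ".Wh")]],
                         p[[paste0("mvsl.lstm.", st, ".b")]])
    new_state[[st]] <- upd
    wf <- p[[paste0("mvsl.att.", st, ".Wf")]]
    wh <- p[[paste0("mvsl.att.", st, ".Wh")]]
    wa <- p[[paste0("mvsl.att.", st, ".Wa")]]
    sc <- numeric(nrow(f))
    for (i in seq_len(nrow(f))) {
      sc[i] <- as.vector(tanh(f[i, ] %*% wf + upd$h %*% wh) %*% wa)
    }
    a <- ref_softmax(sc)
    attended <- numeric(ncol(f))
    for (i in seq_len(nrow(f))) attended <- attended + a[i] * f[i, ]
    att[[st]] <- list(a = a, v = attended)
  }
  msd <- as.vector(att$ms$v %*% p[["mvsl.msproj"]])
  mvs <- as.vector((att$vf$v + att$vl$v + msd) %*% p[["mvsl.fuse.W"]])
  list(mvs = mvs,
       weights = list(a_vf = att$vf$a, a_vl = att$vl$a, a_ms = att$ms$a),
       state = new_state)
}

ref_sentence_step <- function(mvs, state, p) {
  h_prev <- state$h
  upd <- ref_lstm_step(matrix(mvs, 1), state$h, state$c,
                       p[["dec.sent.Wx"]], p[["dec.sent.Wh"]],
                       p[["dec.sent.b"]])
  topic <- tanh(as.vector(upd$h %*% p[["dec.topic.Wsent"]]) +
                as.vector(mvs %*% p[["dec.topic.Wmvs"]]))
  stop_in <- tanh(as.vector(h_prev %*% p[["dec.stop.Wprev"]]) +
                  as.vector(upd$h %*% p[["dec.stop.Wcur"]]))
  list(topic = topic,
       stop_logits = as.vector(stop_in %*% p[["dec.stop.W"]]),
       state = upd)
}

ref_word_step <- function(prev_id, topic, state, p) {
  x <- p[["dec.wembed"]][prev_id, ]
  upd <- ref_lstm_step(matrix(c(x, topic), 1), state$h, state$c,
                       p[["dec.word.Wx"]], p[["dec.word.Wh"]],
                       p[["dec.word.b"]])
  logits <- as.vector(
    (upd$h %*% p[["dec.out.Wword"]]) %*% p[["dec.out.Woutput"]])
  list(probs = ref_softmax(logits), state = upd)
}

# ---- metric oracles ------------------------------------------------------

ref_ngram_counts <- function(tokens, n) {
  out <- list()
  if (length(tokens) >= n) {
    for (i in 1:(length(tokens) - n + 1)) {
      key <- paste(tokens[i:(i + n - 1)], collapse = " ")
      out[[key]] <- (out[[key]] %||% 0) + 1
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# corpus BLEU straight from the definition
ref_bleu <- function(cands, refss, n) {
  clip <- numeric(n); tot <- numeric(n); clen <- 0; rlen <- 0
  for (i in seq_along(cands)) {
    cand <- cands[[i]]; refs <- refss[[i]]
    clen <- clen + length(cand)
    dists <- sapply(refs, function(r) abs(length(r) - length(cand)))
    lens <- sapply(refs, length)
    best <- lens[order(dists, lens)][1]
    rlen <- rlen + best
    for (g in 1:n) {
      cc <- ref_ngram_counts(cand, g)
      for (key in names(cc)) {
        tot[g] <- tot[g] + cc[[key]]
        mx <- 0
        for (r in refs) {
          rc <- ref_ngram_counts(r, g)
          mx <- max(mx, rc[[key]] %||% 0)
        }
        clip[g] <- clip[g] + min(cc[[key]], mx)
      }
    }
  }
  if (clen == 0 || any(tot == 0) || any(clip == 0)) return(0)
  bp <- if (clen > rlen) 1 else exp(1 - rlen / clen)
  bp * prod((clip / tot)^(1 / n))
}

# recursive LCS (exponential; only for short sequences)
ref_lcs <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  if (a[length(a)] == b[length(b)]) {
    return(1L + ref_lcs(a[-length(a)], b[-length(b)]))
  }
  max(ref_lcs(a[-length(a)], b), ref_lcs(a, b[-length(b)]))
}

ref_rouge_l <- function(cand, refs, beta = 1.2) {
  if (!length(cand)) return(0)
  best <- 0
  for (r in refs) {
    l <- ref_lcs(cand, r)
    if (l == 0) next
    p <- l / length(cand); rr <- l / length(r)
    best <- max(best, (1 + beta^2) * p * rr / (rr + beta^2 * p))
  }
  best
}

# CIDEr with explicit dictionaries and loop cosine
ref_cider <- function(cands, refss) {
  n_img <- length(refss)
  total <- 0
  for (g in 1:4) {
    df <- list()
    for (refs in refss) {
      seen <- character(0)
      for (r in refs) seen <- union(seen, names(ref_ngram_counts(r, g)))
      for (w in seen) df[[w]] <- (df[[w]] %||% 0) + 1
    }
    vec <- function(tokens) {
      ct <- ref_ngram_counts(tokens, g)
      tt <- sum(unlist(ct))
      v <- list()
      for (w in names(ct)) {
        v[[w]] <- ct[[w]] / tt * (log(n_img) - log(max(1, df[[w]] %||% 0)))
      }
      v
    }
    pair_sum <- 0
    for (i in seq_along(cands)) {
      vc <- vec(cands[[i]])
      nc <- sqrt(sum(unlist(vc)^2))
      sim <- 0
      for (r in refss[[i]]) {
        vr <- vec(r)
        nr <- sqrt(sum(unlist(vr)^2))
        dot <- 0
        for (w in names(vc)) dot <- dot + vc[[w]] * (vr[[w]] %||% 0)
        sim <- sim + if (nc > 0 && nr > 0) dot / (nc * nr) else 0
      }
      pair_sum <- pair_sum + sim / length(refss[[i]])
    }
    total <- total + pair_sum / length(cands)
  }
  10 * total / 4
}

# AUC by brute-force concordant-pair counting with half credit for ties
ref_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}
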