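## Caption and classification metrics, implemented from first principles:
## corpus/sentence BLEU with modified n-gram precision and brevity penalty,
## LCS-based ROUGE-L, TF-IDF-cosine CIDEr, and rank-statistic macro AUC.

ngrams <- function(tokens, n) {
  len <- length(tokens)
  if (len < n) return(character(0))
  if (n == 1L) return(tokens)
  vapply(seq_len(len - n + 1L),
         function(i) paste(tokens[i:(i + n - 1L)], collapse = "\r"),
         character(1))
}

count_table <- function(x) {
  if (!length(x)) return(integer(0))
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

#' BLEU-n score
#'
#' Geometric mean of the modified (reference-clipped) i-gram precisions for
#' `i = 1..n`, multiplied by the brevity penalty
#' `exp(min(0, 1 - r/c))` where `c` is the total candidate length and `r`
#' the (closest-match) total reference length. The default corpus level
#' aggregates clipped counts over all pairs before taking precisions; the
#' sentence level averages per-pair scores with epsilon smoothing of zero
#' counts.
#'
#' @param candidates list of token vectors
#' @param references list (parallel to `candidates`) of lists of token
#'   vectors
#' @param n maximum n-gram order (1..4)
#' @param level `"corpus"` or `"sentence"`
#' @param smooth_eps numerator added to zero clipped counts at sentence level
#' @return score in `[0, 1]`
#' @export
bleu_n <- function(candidates, references, n = 4L,
                   level = c("corpus", "sentence"), smooth_eps = 0.1) {
  level <- match.arg(level)
  stopifnot(n >= 1, n <= 4, length(candidates) == length(references))
  if (level == "sentence") {
    scores <- mapply(function(cand, refs) {
      bleu_pair(cand, refs, n, smooth_eps)
    }, candidates, references)
    return(mean(scores))
  }
  clipped <- numeric(n)
  totals <- numeric(n)
  c_len <- 0
  r_len <- 0
  for (i in seq_along(candidates)) {
    cand <- candidates[[i]]
    refs <- references[[i]]
    if (!length(refs)) stopf("pair %d has no reference", i)
    c_len <- c_len + length(cand)
    rl <- vapply(refs, length, integer(1))
    r_len <- r_len + rl[order(abs(rl - length(cand)), rl)][1]
    for (g in seq_len(n)) {
      cc <- count_table(ngrams(cand, g))
      totals[g] <- totals[g] + sum(cc)
      if (!length(cc)) next
      rmax <- integer(length(cc))
      names(rmax) <- names(cc)
      for (r in refs) {
        rc <- count_table(ngrams(r, g))
        common <- intersect(names(cc), names(rc))
        rmax[common] <- pmax(rmax[common], rc[common])
      }
      clipped[g] <- clipped[g] + sum(pmin(cc, rmax))
    }
  }
  if (c_len == 0 || any(totals == 0) || any(clipped == 0)) return(0)
  bp <- exp(min(0, 1 - r_len / c_len))
  bp * exp(mean(log(clipped / totals)))
}

bleu_pair <- function(cand, refs, n, smooth_eps) {
  if (!length(cand)) return(0)
  logp <- numeric(n)
  for (g in seq_len(n)) {
    cc <- count_table(ngrams(cand, g))
    total <- sum(cc)
    if (total == 0) return(0)
    rmax <- integer(length(cc))
    names(rmax) <- names(cc)
    for (r in refs) {
      rc <- count_table(ngrams(r, g))
      common <- intersect(names(cc), names(rc))
      rmax[common] <- pmax(rmax[common], rc[common])
    }
    clip <- sum(pmin(cc, rmax))
    if (clip == 0) clip <- smooth_eps
    logp[g] <- log(clip / total)
  }
  rl <- vapply(refs, length, integer(1))
  r <- rl[order(abs(rl - length(cand)), rl)][1]
  exp(min(0, 1 - r / length(cand))) * exp(mean(logp))
}

lcs_length <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    match_row <- a[i] == b
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (match_row[j]) prev[j] + 1L
                     else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' ROUGE-L score
#'
#' Longest-common-subsequence F-measure
#' `F = (1 + beta^2) P R / (R + beta^2 P)` with `P = LCS/|candidate|`,
#' `R = LCS/|reference|`; the caption-evaluation convention `beta = 1.2`
#' weights recall more heavily. Multi-reference pairs take the maximum
#' over references; the corpus score is the mean over pairs.
#'
#' @param candidates list of token vectors (or a single token vector)
#' @param references parallel list of lists of token vectors
#' @param beta recall weight
#' @return score in `[0, 1]`
#' @export
rouge_l <- function(candidates, references, beta = 1.2) {
  if (!is.list(candidates)) {
    candidates <- list(candidates)
    references <- list(references)
  }
  scores <- mapply(function(cand, refs) {
    if (!is.list(refs)) refs <- list(refs)
    if (!length(cand)) return(0)
    max(vapply(refs, function(r) {
      if (!length(r)) return(0)
      l <- lcs_length(cand, r)
      if (l == 0L) return(0)
      p <- l / length(cand)
      rr <- l / length(r)
      (1 + beta^2) * p * rr / (rr + beta^2 * p)
    }, numeric(1)))
  }, candidates, references)
  mean(scores)
}

#' CIDEr score
#'
#' Consensus metric: per n-gram order `n = 1..4`, candidate and reference
#' sentences are mapped to TF-IDF n-gram vectors (term frequency normalised
#' by the sentence's n-gram total; IDF `log(|I|) - log(max(1, df))`
#' computed over the reference corpus of `|I|` pairs), and the candidate's
#' cosine similarity to each reference is averaged; the final score is 10
#' times the mean over the four orders. With a single-pair corpus every IDF
#' is zero and the score degenerates to 0.
#'
#' @param candidates list of token vectors
#' @param references parallel list of lists of token vectors
#' @return score `>= 0` (at most 10)
#' @export
cider <- function(candidates, references) {
  stopifnot(length(candidates) == length(references))
  n_img <- length(references)
  score_n <- numeric(4)
  for (g in 1:4) {
    df <- new.env(parent = emptyenv())
    for (refs in references) {
      seen <- unique(unlist(lapply(refs, function(r) unique(ngrams(r, g)))))
      for (w in seen) assign(w, (get0(w, df) %||% 0) + 1, envir = df)
    }
    idf <- function(w) log(n_img) - log(max(1, get0(w, df) %||% 0))
    tfidf <- function(tokens) {
      ct <- count_table(ngrams(tokens, g))
      if (!length(ct)) return(numeric(0))
      v <- (ct / sum(ct)) * vapply(names(ct), idf, numeric(1))
      v
    }
    pair_scores <- mapply(function(cand, refs) {
      vc <- tfidf(cand)
      nc <- sqrt(sum(vc^2))
      if (nc == 0) return(0)
      mean(vapply(refs, function(r) {
        vr <- tfidf(r)
        nr <- sqrt(sum(vr^2))
        if (nr == 0) return(0)
        common <- intersect(names(vc), names(vr))
        sum(vc[common] * vr[common]) / (nc * nr)
      }, numeric(1)))
    }, candidates, references)
    score_n[g] <- mean(pair_scores)
  }
  10 * mean(score_n)
}

#' Macro-averaged multi-label AUC
#'
#' Per class, the area under the ROC curve via the rank statistic
#' `AUC = (sum of positive ranks - n_pos (n_pos + 1) / 2) / (n_pos n_neg)`
#' with midranks for tied scores. Classes without both a positive and a
#' negative label are excluded and reported.
#'
#' @param scores `n x M` numeric score matrix
#' @param labels `n x M` 0/1 label matrix
#' @return list with `per_class` (NA for excluded classes), `macro` (mean
#'   over valid classes) and `excluded` (indices)
#' @export
macro_auc <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.matrix(labels)
  stopifnot(all(dim(scores) == dim(labels)))
  m <- ncol(scores)
  per <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    y <- labels[, j]
    npos <- sum(y == 1)
    nneg <- sum(y == 0)
    if (npos == 0 || nneg == 0) next
    r <- rank(scores[, j], ties.method = "average")
    per[j] <- (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  valid <- !is.na(per)
  list(per_class = per,
       macro = if (any(valid)) mean(per[valid]) else NA_real_,
       excluded = which(!valid))
}
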