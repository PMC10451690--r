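## Cross-view attention encoder: operation-level API and encoder losses.
##
## These functions expose the encoder's building blocks on plain matrices;
## each runs the same tape graph the training loop uses (with constants, so
## no gradients are recorded).

se_param_list <- function(params) {
  list("enc.se.W1" = params$W1, "enc.se.b1" = as_mat_row(params$b1),
       "enc.se.W2" = params$W2, "enc.se.b2" = as_mat_row(params$b2))
}

as_mat_row <- function(x) if (is.matrix(x)) x else matrix(x, 1L)

#' Squeeze-excitation channel attention
#'
#' Recalibrates an `N x D` feature map channel-wise:
#' `f(V)[n, d] = V[n, d] * g_d` with
#' `g = sigmoid(W2 relu(W1 mean_n(V) + b1) + b2)`. The same gates apply at
#' every spatial position, so the spatial layout is preserved.
#'
#' @param v `N x D` feature map
#' @param params list with `W1` (`D x D/r`), `b1`, `W2` (`D/r x D`), `b2`
#' @return the gated `N x D` feature map
#' @export
se_attention <- function(v, params) {
  if (ncol(v) != nrow(params$W1)) {
    stopf("feature depth %d does not match SE params (%d)",
          ncol(v), nrow(params$W1))
  }
  tape <- new_tape()
  pn <- param_nodes(tape, se_param_list(params), grad = FALSE)
  graph_se(tape, pn, ad_const(tape, v), 1L, nrow(v))$val
}

#' Random squeeze-excitation parameters (for examples and tests)
#' @param d feature depth
#' @param r reduction ratio (must divide `d`)
#' @export
se_params <- function(d, r = 4L) {
  if (d %% r != 0) stopf("reduction ratio r (%d) must divide D (%d)", r, d)
  list(W1 = init_mat(d, d %/% r), b1 = matrix(0, 1L, d %/% r),
       W2 = init_mat(d %/% r, d), b2 = matrix(0, 1L, d))
}

#' Cross-view mixing of squeeze-excited feature maps
#'
#' Applies the shared squeeze-excitation transform `f` to both views and
#' mixes them convexly:
#' `vaf = lambda f(vf) + (1 - lambda) f(vl)` and
#' `val = lambda f(vl) + (1 - lambda) f(vf)`.
#'
#' @param vf,vl `N x D` feature maps of the frontal and lateral views
#' @param params shared squeeze-excitation parameters (see [se_params()])
#' @param lambda_mix retention weight in `[0.5, 1]`
#' @return list with `vaf` and `val`
#' @export
cross_view_mix <- function(vf, vl, params, lambda_mix) {
  if (!all(dim(vf) == dim(vl))) stopf("view feature maps differ in shape")
  if (lambda_mix < 0.5 || lambda_mix > 1) stopf("lambda_mix must be in [0.5, 1]")
  fvf <- se_attention(vf, params)
  fvl <- se_attention(vl, params)
  list(vaf = lambda_mix * fvf + (1 - lambda_mix) * fvl,
       val = lambda_mix * fvl + (1 - lambda_mix) * fvf)
}

#' Branch classification head
#'
#' Mean-pools a feature map over its spatial positions and applies an
#' affine map with an elementwise sigmoid, yielding `M` per-tag
#' probabilities in `(0, 1)`.
#'
#' @param v `N x D` feature map
#' @param w `D x M` weight matrix
#' @param b length-`M` bias
#' @return length-`M` probability vector
#' @export
classify_branch <- function(v, w, b) {
  as.vector(1 / (1 + exp(-(colMeans(v) %*% w + as.vector(b)))))
}

#' Cross-view consistency loss
#'
#' `l_single = sum_i (y_f - y_l)^2`, `l_cross = sum_i (y_af - y_al)^2`,
#' `l_cvam = l_single + l_cross`; sums run over the M tags and results are
#' averaged over the batch when predictions are matrices (rows = samples).
#'
#' @param preds list with `y_f`, `y_l`, `y_af`, `y_al` (vectors or
#'   `B x M` matrices)
#' @return list with `l_single`, `l_cross`, `l_cvam`
#' @export
cvam_loss <- function(preds) {
  pair <- function(a, b) {
    a <- rbind(a); b <- rbind(b)
    sum((a - b)^2) / nrow(a)
  }
  l_single <- pair(preds$y_f, preds$y_l)
  l_cross <- pair(preds$y_af, preds$y_al)
  list(l_single = l_single, l_cross = l_cross, l_cvam = l_single + l_cross)
}

#' Multi-label binary cross-entropy over the four branches
#'
#' `-sum_j sum_i [T_i log p_ji + (1 - T_i) log(1 - p_ji)]` with
#' `j in {f, l, af, al}`, probabilities clamped to `[eps, 1 - eps]`,
#' averaged over the batch. Branches absent from `preds` are skipped (used
#' by the single-/cross-branch ablations).
#'
#' @param preds list of branch probability vectors or `B x M` matrices
#' @param t multi-hot target vector or `B x M` matrix
#' @param eps log clamp
#' @return scalar loss
#' @export
bce_loss <- function(preds, t, eps = 1e-7) {
  t <- rbind(t)
  total <- 0
  for (p in preds[!vapply(preds, is.null, logical(1))]) {
    p <- pmin(pmax(rbind(p), eps), 1 - eps)
    total <- total - sum(t * log(p) + (1 - t) * log1p(-p)) / nrow(t)
  }
  total
}

#' Combined encoder loss `alpha * L_BCE + beta * L_CVAM`
#' @param l_bce,l_cvam component losses
#' @param alpha,beta nonnegative weights (defaults 1 and 0.05)
#' @export
encoder_loss <- function(l_bce, l_cvam, alpha = 1, beta = 0.05) {
  stopifnot(alpha >= 0, beta >= 0)
  alpha * l_bce + beta * l_cvam
}

#' Select the k highest-probability tags
#'
#' Returns the indices of the `k` largest entries in descending
#' probability order; ties are broken by ascending index.
#'
#' @param probs length-`M` probability vector
#' @param k number of tags to keep (`1 <= k <= M`)
#' @return integer vector of `k` 1-based tag indices
#' @export
select_top_tags <- function(probs, k) {
  stopifnot(k >= 1, k <= length(probs))
  order(-probs, seq_along(probs))[seq_len(k)]
}

# averaged branch probabilities used for tag selection (rows = samples)
combined_probs <- function(preds) {
  ps <- preds[!vapply(preds, is.null, logical(1))]
  Reduce(`+`, ps) / length(ps)
}
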