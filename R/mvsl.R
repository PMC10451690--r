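## Visual-semantic fusion: operation-level API.
##
## Per sentence step, three LSTMs consume the frontal visual stream, the
## lateral visual stream and the embedded tag stream (each stream's
## per-step input is the mean over its rows); each hidden state drives
## additive attention over that stream's rows, and the three attended
## vectors are fused into one visual-semantic feature.

#' Embed selected tags
#'
#' @param tag_indices integer vector of 1-based tag indices (repeats allowed)
#' @param table `M x E` embedding matrix
#' @return `length(tag_indices) x E` matrix of embedding rows
#' @export
embed_tags <- function(tag_indices, table) {
  tag_indices <- as.integer(tag_indices)
  if (any(tag_indices < 1L | tag_indices > nrow(table))) {
    stopf("tag index out of range (catalog has %d tags)", nrow(table))
  }
  table[tag_indices, , drop = FALSE]
}

#' Initial (zero) fusion state
#' @param hidden hidden size H
#' @export
mvsl_init_state <- function(hidden) {
  z <- matrix(0, 1L, hidden)
  list(vf = list(h = z, c = z), vl = list(h = z, c = z),
       ms = list(h = z, c = z), s = 0L)
}

mvsl_param_names <- function() {
  c(sapply(c("vf", "vl", "ms"), function(st) {
      c(sprintf("mvsl.lstm.%s.Wx", st), sprintf("mvsl.lstm.%s.Wh", st),
        sprintf("mvsl.lstm.%s.b", st), sprintf("mvsl.att.%s.Wf", st),
        sprintf("mvsl.att.%s.Wh", st), sprintf("mvsl.att.%s.Wa", st))
    }),
    "mvsl.msproj", "mvsl.fuse.W")
}

#' One sentence step of the visual-semantic fusion module
#'
#' For each stream `F` in \{frontal visual, lateral visual, tag semantic\}:
#' the stream's LSTM consumes the mean over the stream's rows and its new
#' hidden state scores every row through
#' `a = softmax(Wa' tanh(Wf F_i + Wh h))`; the attended vectors
#' `sum_i a_i F_i` are combined (the semantic one through a learned E-to-D
#' projection) and mapped by the fusion matrix to the visual-semantic
#' feature for this sentence.
#'
#' @param vf,vl `N x D` visual feature maps
#' @param ms `k x E` semantic embedding matrix
#' @param state fusion state from [mvsl_init_state()] or a previous step
#' @param model an `rg_model` (supplies the fusion parameters)
#' @return list with `mvs` (length-H vector), `weights` (list `a_vf`,
#'   `a_vl`, `a_ms`, each summing to 1) and the advanced `state`
#' @export
mvsl_step <- function(vf, vl, ms, state, model) {
  cfg <- model$config
  d <- model$depth
  if (ncol(vf) != d || ncol(vl) != d) {
    stopf("visual stream depth mismatch: expected D = %d", d)
  }
  if (ncol(ms) != cfg$embed_tag) {
    stopf("semantic stream width mismatch: expected E = %d", cfg$embed_tag)
  }
  tape <- new_tape()
  pn <- param_nodes(tape, model$params[mvsl_param_names()], grad = FALSE)
  st_nodes <- lapply(state[c("vf", "vl", "ms")], function(s) {
    list(h = ad_const(tape, s$h), c = ad_const(tape, s$c))
  })
  fake_model <- list(config = cfg, n_pos = nrow(vf), depth = d)
  out <- graph_mvsl_step(tape, pn,
                         list(vf = ad_const(tape, vf), vl = ad_const(tape, vl)),
                         ad_const(tape, ms), st_nodes, fake_model, 1L)
  list(mvs = as.vector(out$mvs$val),
       weights = list(a_vf = as.vector(out$weights$a_vf$val),
                      a_vl = as.vector(out$weights$a_vl$val),
                      a_ms = as.vector(out$weights$a_ms$val)),
       state = c(lapply(out$state, function(s) list(h = s$h$val, c = s$c$val)),
                 list(s = state$s + 1L)))
}
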