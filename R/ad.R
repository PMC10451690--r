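#' Reverse-mode automatic differentiation tape
#'
#' The model in this package is trained with a small reverse-mode autodiff
#' engine operating on dense base-R matrices. Every operation evaluates its
#' forward value eagerly and records a node on a tape; [ad_backward()] then
#' sweeps the tape in reverse, accumulating gradients into every node with
#' `needs_grad = TRUE`. All values are numeric matrices; scalars are 1x1.
#'
#' The engine deliberately supports only the operations the model needs
#' (matrix product, elementwise arithmetic and nonlinearities, row softmax,
#' row gather/segment reductions, fused cross-entropy and binary
#' cross-entropy, strided 2-d convolution via im2col).
#'
#' @return `new_tape()` returns an empty tape environment.
#' @export
new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, val, parents = list(), backward = NULL,
                    needs_grad = NULL) {
  if (is.null(needs_grad)) {
    needs_grad <- length(parents) > 0L &&
      any(vapply(parents, function(p) p$needs_grad, logical(1)))
  }
  nd <- new.env(parent = emptyenv())
  dimnames(val) <- NULL
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$needs_grad <- needs_grad
  nd$tape <- tape
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

#' @rdname new_tape
#' @param tape a tape from [new_tape()]
#' @param val numeric matrix (vectors are promoted to column matrices)
#' @export
ad_leaf <- function(tape, val) ad_node(tape, as_mat(val), needs_grad = TRUE)

#' @rdname new_tape
#' @export
ad_const <- function(tape, val) ad_node(tape, as_mat(val), needs_grad = FALSE)

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

acc_grad <- function(node, g) {
  if (!node$needs_grad) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' @rdname new_tape
#' @param root scalar (1x1) node the backward sweep starts from
#' @export
ad_backward <- function(root) {
  stopifnot(length(root$val) == 1L)
  root$grad <- matrix(1, 1L, 1L)
  tape <- root$tape
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backward) && !is.null(nd$grad) && nd$needs_grad) {
      nd$backward(nd)
    }
  }
  invisible(NULL)
}


#' Tape operations
#'
#' Elementary differentiable operations on tape nodes. Each evaluates
#' eagerly and records its backward rule; see [new_tape()].
#'
#' @param a,b operand nodes
#' @param feat,w,x,p,logits operand nodes of the structured ops
#' @param idx,from,to,target,weight,nseg,len,batch,geom,s,eps,hin,win,k,stride,pad,params,grads,state,lr,beta1,beta2,target_idx plain (non-node) arguments
#' @name tape-ops
NULL

## ---- elementary ops ------------------------------------------------------

#' @rdname tape-ops
#' @export
ad_mm <- function(a, b) {
  ad_node(a$tape, a$val %*% b$val, list(a, b), function(nd) {
    g <- nd$grad
    acc_grad(nd$parents[[1L]], g %*% t(nd$parents[[2L]]$val))
    acc_grad(nd$parents[[2L]], t(nd$parents[[1L]]$val) %*% g)
  })
}

#' @rdname tape-ops
#' @export
ad_add <- function(a, b) {
  ad_node(a$tape, a$val + b$val, list(a, b), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad)
    acc_grad(nd$parents[[2L]], nd$grad)
  })
}

#' @rdname tape-ops
#' @export
ad_sub <- function(a, b) {
  ad_node(a$tape, a$val - b$val, list(a, b), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad)
    acc_grad(nd$parents[[2L]], -nd$grad)
  })
}

#' @rdname tape-ops
#' @export
ad_mul <- function(a, b) {
  ad_node(a$tape, a$val * b$val, list(a, b), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad * nd$parents[[2L]]$val)
    acc_grad(nd$parents[[2L]], nd$grad * nd$parents[[1L]]$val)
  })
}

# scale by a plain scalar (not a node)
#' @rdname tape-ops
#' @export
ad_scale <- function(a, s) {
  ad_node(a$tape, a$val * s, list(a), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad * s)
  })
}

# add a 1xK bias row to every row of a
#' @rdname tape-ops
#' @export
ad_add_bias <- function(a, b) {
  bv <- matrix(b$val, nrow(a$val), ncol(a$val), byrow = TRUE)
  ad_node(a$tape, a$val + bv, list(a, b), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad)
    acc_grad(nd$parents[[2L]], matrix(colSums(nd$grad), 1L))
  })
}

#' @rdname tape-ops
#' @export
ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$val))
  ad_node(a$tape, v, list(a), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad * nd$val * (1 - nd$val))
  })
}

#' @rdname tape-ops
#' @export
ad_tanh <- function(a) {
  v <- tanh(a$val)
  ad_node(a$tape, v, list(a), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad * (1 - nd$val^2))
  })
}

#' @rdname tape-ops
#' @export
ad_relu <- function(a) {
  v <- pmax(a$val, 0)
  ad_node(a$tape, v, list(a), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad * (nd$parents[[1L]]$val > 0))
  })
}

#' @rdname tape-ops
#' @export
ad_sum <- function(a) {
  ad_node(a$tape, matrix(sum(a$val), 1L, 1L), list(a), function(nd) {
    p <- nd$parents[[1L]]
    acc_grad(p, matrix(nd$grad[1L], nrow(p$val), ncol(p$val)))
  })
}

# numerically stable softmax over each row
#' @rdname tape-ops
#' @export
ad_rowsoftmax <- function(a) {
  z <- a$val - apply(a$val, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  ad_node(a$tape, p, list(a), function(nd) {
    g <- nd$grad
    acc_grad(nd$parents[[1L]], nd$val * (g - rowSums(g * nd$val)))
  })
}

# gather rows of a by integer index (with repetition); used for embedding
# lookup and for broadcasting per-sample vectors over spatial positions
#' @rdname tape-ops
#' @export
ad_rows <- function(a, idx) {
  idx <- as.integer(idx)
  ad_node(a$tape, a$val[idx, , drop = FALSE], list(a), function(nd) {
    p <- nd$parents[[1L]]
    if (!p$needs_grad) return(invisible(NULL))
    rs <- rowsum(nd$grad, idx)
    gfull <- matrix(0, nrow(p$val), ncol(p$val))
    gfull[as.integer(rownames(rs)), ] <- rs
    acc_grad(p, gfull)
  })
}

#' @rdname tape-ops
#' @export
ad_cols <- function(a, from, to) {
  ad_node(a$tape, a$val[, from:to, drop = FALSE], list(a), function(nd) {
    p <- nd$parents[[1L]]
    gfull <- matrix(0, nrow(p$val), ncol(p$val))
    gfull[, from:to] <- nd$grad
    acc_grad(p, gfull)
  })
}

#' @rdname tape-ops
#' @export
ad_concat_cols <- function(a, b) {
  na <- ncol(a$val)
  ad_node(a$tape, cbind(a$val, b$val), list(a, b), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad[, seq_len(na), drop = FALSE])
    acc_grad(nd$parents[[2L]], nd$grad[, -seq_len(na), drop = FALSE])
  })
}

# mean over `len` consecutive rows per segment: (nseg*len) x D -> nseg x D
#' @rdname tape-ops
#' @export
ad_segment_mean <- function(a, nseg, len) {
  grp <- rep(seq_len(nseg), each = len)
  ad_node(a$tape, rowsum(a$val, grp) / len, list(a), function(nd) {
    acc_grad(nd$parents[[1L]], nd$grad[grp, , drop = FALSE] / len)
  })
}

# attention pooling: feat is (nseg*len) x D (rows segment-major), w is
# nseg x len nonnegative weights; returns nseg x D, row b = sum_n w[b,n] feat[b,n,]
#' @rdname tape-ops
#' @export
ad_attend <- function(feat, w, nseg, len) {
  grp <- rep(seq_len(nseg), each = len)
  wflat <- as.vector(t(w$val))
  ad_node(feat$tape, rowsum(feat$val * wflat, grp), list(feat, w), function(nd) {
    g <- nd$grad
    fp <- nd$parents[[1L]]
    wp <- nd$parents[[2L]]
    gex <- g[grp, , drop = FALSE]
    acc_grad(fp, gex * wflat)
    if (wp$needs_grad) {
      acc_grad(wp, matrix(rowSums(fp$val * gex), nseg, len, byrow = TRUE))
    }
  })
}

# fused multinomial cross-entropy: sum_r weight[r] * (logsumexp(logits[r,]) -
# logits[r, target[r]]); returns scalar node
#' @rdname tape-ops
#' @export
ad_ce_loss <- function(logits, target, weight) {
  lv <- logits$val
  m <- apply(lv, 1L, max)
  lse <- m + log(rowSums(exp(lv - m)))
  li <- lv[cbind(seq_len(nrow(lv)), target)]
  loss <- sum(weight * (lse - li))
  ad_node(logits$tape, matrix(loss, 1L, 1L), list(logits), function(nd) {
    p <- exp(lv - lse)
    p[cbind(seq_len(nrow(lv)), target)] <-
      p[cbind(seq_len(nrow(lv)), target)] - 1
    acc_grad(nd$parents[[1L]], nd$grad[1L] * weight * p)
  })
}

# fused binary cross-entropy on probabilities with log clamping:
# -sum(t*log(p) + (1-t)*log(1-p)), p clamped to [eps, 1-eps]
#' @rdname tape-ops
#' @export
ad_bce_sum <- function(p, target, eps = 1e-7) {
  pc <- pmin(pmax(p$val, eps), 1 - eps)
  loss <- -sum(target * log(pc) + (1 - target) * log1p(-pc))
  inner <- p$val > eps & p$val < 1 - eps
  ad_node(p$tape, matrix(loss, 1L, 1L), list(p), function(nd) {
    g <- (-target / pc + (1 - target) / (1 - pc)) * inner
    acc_grad(nd$parents[[1L]], nd$grad[1L] * g)
  })
}

## ---- convolution ---------------------------------------------------------

# geometry of a k x k, stride-s, pad-p convolution over hin x win images;
# pixel order within an image is row-major: pixel (r, c) -> (r-1)*win + c
#' @rdname tape-ops
#' @export
conv_geom <- function(hin, win, k = 3L, stride = 2L, pad = 1L) {
  hout <- (hin + 2L * pad - k) %/% stride + 1L
  wout <- (win + 2L * pad - k) %/% stride + 1L
  pout <- hout * wout
  idx <- matrix(NA_integer_, pout, k * k)
  pos <- 0L
  for (r in seq_len(hout)) {
    for (c in seq_len(wout)) {
      pos <- pos + 1L
      r0 <- (r - 1L) * stride - pad
      c0 <- (c - 1L) * stride - pad
      j <- 0L
      for (dr in seq_len(k)) {
        for (dc in seq_len(k)) {
          j <- j + 1L
          rr <- r0 + dr
          cc <- c0 + dc
          if (rr >= 1L && rr <= hin && cc >= 1L && cc <= win) {
            idx[pos, j] <- (rr - 1L) * win + cc
          }
        }
      }
    }
  }
  list(hin = hin, win = win, hout = hout, wout = wout,
       pin = hin * win, pout = pout, k = k, idx = idx)
}

# x: (B*pin) x Cin stacked images; w: (k*k*Cin) x Cout; b: 1 x Cout
#' @rdname tape-ops
#' @export
ad_conv2d <- function(x, w, b, geom, batch) {
  k2 <- geom$k^2
  cin <- ncol(x$val)
  xa <- rbind(x$val, 0)
  zrow <- nrow(xa)
  offs <- rep((seq_len(batch) - 1L) * geom$pin, each = geom$pout)
  idx_list <- vector("list", k2)
  pm <- matrix(0, batch * geom$pout, k2 * cin)
  for (j in seq_len(k2)) {
    ij <- rep(geom$idx[, j], batch) + offs
    ij[is.na(ij)] <- zrow
    idx_list[[j]] <- ij
    pm[, ((j - 1L) * cin + 1L):(j * cin)] <- xa[ij, , drop = FALSE]
  }
  out <- pm %*% w$val
  out <- out + matrix(b$val, nrow(out), ncol(out), byrow = TRUE)
  ad_node(x$tape, out, list(x, w, b), function(nd) {
    g <- nd$grad
    xp <- nd$parents[[1L]]
    wp <- nd$parents[[2L]]
    bp <- nd$parents[[3L]]
    acc_grad(wp, t(pm) %*% g)
    acc_grad(bp, matrix(colSums(g), 1L))
    if (xp$needs_grad) {
      gpm <- g %*% t(wp$val)
      gx <- matrix(0, zrow, cin)
      for (j in seq_len(k2)) {
        rs <- rowsum(gpm[, ((j - 1L) * cin + 1L):(j * cin), drop = FALSE],
                     idx_list[[j]])
        rn <- as.integer(rownames(rs))
        gx[rn, ] <- gx[rn, ] + rs
      }
      acc_grad(xp, gx[-zrow, , drop = FALSE])
    }
  })
}

## ---- optimiser -----------------------------------------------------------

adam_state <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# params, grads: named lists of matrices; lr: named numeric vector per param
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    params[[nm]] <- params[[nm]] - lr[[nm]] * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
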