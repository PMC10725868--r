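# Minimal reverse-mode automatic differentiation on a define-by-run tape.
# Values are numeric vectors/matrices/3-d arrays; nodes are environments
# appended to the tape in creation order, so reversing that order is a valid
# topological order for backpropagation. Internal to the package.

adTape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- list()
  tape$params <- list()
  tape
}

adNode <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tape$nodes[[length(tape$nodes) + 1L]] <- nd
  nd
}

adAccum <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
}

adConst <- function(tape, x) adNode(tape, x)

adParam <- function(tape, x, name) {
  nd <- adNode(tape, x)
  tape$params[[name]] <- nd
  nd
}

adBackward <- function(tape, loss) {
  loss$grad <- array(1, dim = if (is.null(dim(loss$value))) length(loss$value) else dim(loss$value))
  for (i in rev(seq_along(tape$nodes))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(tape)
}

adGrads <- function(tape) lapply(tape$params, function(nd) {
  if (is.null(nd$grad)) array(0, dim = dim(nd$value)) else nd$grad
})

# ---- elementary operations ----

adMatmul <- function(tape, a, b) {
  adNode(tape, a$value %*% b$value, list(a, b), function(nd) {
    adAccum(a, nd$grad %*% t(b$value))
    adAccum(b, t(a$value) %*% nd$grad)
  })
}

# add a length-ncol bias vector to every row of a matrix
adAddBias <- function(tape, a, b) {
  adNode(tape, sweep(a$value, 2, as.numeric(b$value), "+"), list(a, b), function(nd) {
    adAccum(a, nd$grad)
    adAccum(b, matrix(colSums(nd$grad), nrow = 1))
  })
}

adAdd <- function(tape, a, b) {
  adNode(tape, a$value + b$value, list(a, b), function(nd) {
    adAccum(a, nd$grad)
    adAccum(b, nd$grad)
  })
}

adScale <- function(tape, a, s) {
  adNode(tape, a$value * s, list(a), function(nd) adAccum(a, nd$grad * s))
}

# multiply an array by a scalar-valued (1x1) parameter node
adSMul <- function(tape, a, s) {
  adNode(tape, a$value * as.numeric(s$value), list(a, s), function(nd) {
    adAccum(a, nd$grad * as.numeric(s$value))
    adAccum(s, matrix(sum(nd$grad * a$value), 1, 1))
  })
}

adRelu <- function(tape, a) {
  adNode(tape, pmax(a$value, 0), list(a), function(nd) {
    adAccum(a, nd$grad * (a$value > 0))
  })
}

adTanh <- function(tape, a) {
  v <- tanh(a$value)
  adNode(tape, v, list(a), function(nd) adAccum(a, nd$grad * (1 - v^2)))
}

adReshape <- function(tape, a, dims) {
  old <- dim(a$value)
  adNode(tape, array(a$value, dim = dims), list(a), function(nd) {
    adAccum(a, array(nd$grad, dim = old))
  })
}

adAperm <- function(tape, a, perm) {
  inv <- order(perm)
  adNode(tape, aperm(a$value, perm), list(a), function(nd) {
    adAccum(a, aperm(nd$grad, inv))
  })
}

adConcatCols <- function(tape, parts) {
  widths <- vapply(parts, function(p) ncol(p$value), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  adNode(tape, do.call(cbind, lapply(parts, function(p) p$value)), parts, function(nd) {
    for (i in seq_along(parts)) {
      adAccum(parts[[i]], nd$grad[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

# concatenate 3-d arrays (B, T, k_i) along the third dimension
adConcat3 <- function(tape, parts) {
  ks <- vapply(parts, function(p) dim(p$value)[3], integer(1))
  ends <- cumsum(ks)
  starts <- c(1L, head(ends, -1L) + 1L)
  d <- dim(parts[[1]]$value)
  out <- array(0, dim = c(d[1], d[2], sum(ks)))
  for (i in seq_along(parts)) out[, , starts[i]:ends[i]] <- parts[[i]]$value
  adNode(tape, out, parts, function(nd) {
    for (i in seq_along(parts)) {
      adAccum(parts[[i]], nd$grad[, , starts[i]:ends[i], drop = FALSE])
    }
  })
}

adDropout <- function(tape, a, rate, training) {
  if (!training || rate <= 0) return(a)
  keep <- array(stats::runif(length(a$value)) >= rate, dim = dim(a$value)) / (1 - rate)
  adNode(tape, a$value * keep, list(a), function(nd) adAccum(a, nd$grad * keep))
}

adSumSq <- function(tape, a) {
  adNode(tape, matrix(sum(a$value^2), 1, 1), list(a), function(nd) {
    adAccum(a, 2 * a$value * as.numeric(nd$grad))
  })
}

# ---- batched dot-product attention core ----
# q, k, v: arrays (B, Tq|Tk, dk). Per sample b: S = q_b k_b' (optionally
# scaled by 1/sqrt(dk)); W = row-softmax(S); out_b = W v_b.
adAttention <- function(tape, q, k, v, scale = FALSE) {
  dq <- dim(q$value)
  B <- dq[1]; Tq <- dq[2]; D <- dq[3]
  Tk <- dim(k$value)[2]
  sc <- if (scale) 1 / sqrt(D) else 1
  qa <- q$value; ka <- k$value; va <- v$value
  W <- array(0, dim = c(B, Tq, Tk))
  O <- array(0, dim = c(B, Tq, D))
  for (b in seq_len(B)) {
    S <- tcrossprod(matrix(qa[b, , ], Tq, D), matrix(ka[b, , ], Tk, D)) * sc
    E <- exp(S - S[cbind(seq_len(Tq), max.col(S, ties.method = "first"))])
    Wb <- E / rowSums(E)
    W[b, , ] <- Wb
    O[b, , ] <- Wb %*% matrix(va[b, , ], Tk, D)
  }
  nd <- adNode(tape, O, list(q, k, v), function(nd) {
    dq_ <- array(0, dim = dim(qa))
    dk_ <- array(0, dim = dim(ka))
    dv_ <- array(0, dim = dim(va))
    for (b in seq_len(B)) {
      dO <- matrix(nd$grad[b, , ], Tq, D)
      Wb <- matrix(W[b, , ], Tq, Tk)
      Vb <- matrix(va[b, , ], Tk, D)
      dW <- tcrossprod(dO, Vb)
      dv_[b, , ] <- crossprod(Wb, dO)
      dS <- Wb * (dW - rowSums(Wb * dW))
      dq_[b, , ] <- dS %*% matrix(ka[b, , ], Tk, D) * sc
      dk_[b, , ] <- crossprod(dS, matrix(qa[b, , ], Tq, D)) * sc
    }
    adAccum(q, dq_); adAccum(k, dk_); adAccum(v, dv_)
  })
  nd$attn_weights <- W
  nd
}

# ---- losses ----

adMSELoss <- function(tape, pred, target) {
  r <- as.numeric(pred$value) - as.numeric(target)
  n <- length(r)
  adNode(tape, matrix(mean(r^2), 1, 1), list(pred), function(nd) {
    adAccum(pred, array(2 * r / n * as.numeric(nd$grad), dim = dim(pred$value)))
  })
}

# logits: B x K; y: integer classes 1..K
adCrossEntropyLoss <- function(tape, logits, y) {
  L <- logits$value
  B <- nrow(L)
  m <- apply(L, 1, max)
  lse <- m + log(rowSums(exp(L - m)))
  picked <- L[cbind(seq_len(B), y)]
  p <- exp(L - lse)
  adNode(tape, matrix(mean(lse - picked), 1, 1), list(logits), function(nd) {
    g <- p
    g[cbind(seq_len(B), y)] <- g[cbind(seq_len(B), y)] - 1
    adAccum(logits, g / B * as.numeric(nd$grad))
  })
}

softmaxRows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(sweep(x, 1, m, "-"))
  sweep(e, 1, rowSums(e), "/")
}

# ---- AdamW ----

adamWInit <- function(params) {
  list(step = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p))),
       v = lapply(params, function(p) array(0, dim = dim(p))))
}

adamWStep <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  t <- state$step
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}
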