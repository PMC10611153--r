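#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## A small reverse-mode automatic-differentiation engine on matrices.
##
## Define-by-run: every operation appends a node to a tape; nodes created
## later can only depend on earlier ones, so the tape order is a topological
## order and the backward pass simply walks it in reverse. Values are plain
## numeric matrices. Batched sequences are stored sample-major: a batch of
## nb sequences of length L with C features is an (nb*L) x C matrix whose
## rows (b-1)*L + t hold time step t of sequence b.
##
## Nodes are environments: $value, $grad (NULL until touched), $backward
## (closure accumulating into parents). Parameters are tape-less leaf nodes
## whose $grad the optimizer reads.
## ---------------------------------------------------------------------------

adTape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

adNode <- function(tape, value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- NULL
  if (!is.null(tape)) {
    if (tape$n == length(tape$nodes))
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$n <- tape$n + 1L
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

#' Create a trainable parameter (autodiff leaf)
#' @param value Initial numeric matrix/vector.
#' @return A leaf node.
#' @keywords internal
adParam <- function(value) adNode(NULL, value)

adAccum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run the backward pass from a scalar loss node
#' @keywords internal
adBackward <- function(tape, root) {
  root$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

## ----- primitive operations -------------------------------------------------

adMatmul <- function(tape, a, b) {
  out <- adNode(tape, a$value %*% b$value)
  out$backward <- function(g) {
    adAccum(a, g %*% t(b$value))
    adAccum(b, crossprod(a$value, g))
  }
  out
}

## add a row-vector bias to every row
adBias <- function(tape, x, b) {
  out <- adNode(tape, x$value + rep(b$value, each = nrow(x$value)))
  out$backward <- function(g) {
    adAccum(x, g)
    adAccum(b, colSums(g))
  }
  out
}

adAdd <- function(tape, a, b) {
  out <- adNode(tape, a$value + b$value)
  out$backward <- function(g) {
    adAccum(a, g)
    adAccum(b, g)
  }
  out
}

adMul <- function(tape, a, b) {
  out <- adNode(tape, a$value * b$value)
  out$backward <- function(g) {
    adAccum(a, g * b$value)
    adAccum(b, g * a$value)
  }
  out
}

adScale <- function(tape, x, k) {
  out <- adNode(tape, x$value * k)
  out$backward <- function(g) adAccum(x, g * k)
  out
}

adRelu <- function(tape, x) {
  mask <- x$value > 0
  out <- adNode(tape, x$value * mask)
  out$backward <- function(g) adAccum(x, g * mask)
  out
}

adSigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  out <- adNode(tape, s)
  out$backward <- function(g) adAccum(x, g * s * (1 - s))
  out
}

adTanh <- function(tape, x) {
  s <- tanh(x$value)
  out <- adNode(tape, s)
  out$backward <- function(g) adAccum(x, g * (1 - s^2))
  out
}

adCols <- function(tape, x, idx) {
  out <- adNode(tape, x$value[, idx, drop = FALSE])
  out$backward <- function(g) {
    dx <- matrix(0, nrow(x$value), ncol(x$value))
    dx[, idx] <- g
    adAccum(x, dx)
  }
  out
}

adConcatCols <- function(tape, parts) {
  out <- adNode(tape, do.call(cbind, lapply(parts, function(p) p$value)))
  widths <- vapply(parts, function(p) ncol(p$value), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  out$backward <- function(g) {
    for (i in seq_along(parts))
      adAccum(parts[[i]], g[, starts[i]:ends[i], drop = FALSE])
  }
  out
}

adDropout <- function(tape, x, rate, training) {
  if (!training || rate <= 0) return(x)
  mask <- (matrix(stats::runif(length(x$value)), nrow(x$value)) >= rate) /
    (1 - rate)
  out <- adNode(tape, x$value * mask)
  out$backward <- function(g) adAccum(x, g * mask)
  out
}

## Valid 1D convolution over batched sequences ((nb*L) x C sample-major),
## via an explicit im2col expansion; w is (k*C) x F, b length F.
## inputGrad = FALSE skips the gradient w.r.t. x (first-layer shortcut).
adConv1d <- function(tape, x, w, b, nb, L, k, inputGrad = TRUE) {
  C <- ncol(x$value)
  Lout <- L - k + 1L
  if (Lout < 1L)
    stop(sprintf("sequence length %d shorter than kernel size %d", L, k))
  base <- as.vector(outer(seq_len(Lout), (seq_len(nb) - 1L) * L, "+"))
  Xc <- matrix(0, nb * Lout, k * C)
  for (j in seq_len(k))
    Xc[, ((j - 1L) * C + 1L):(j * C)] <- x$value[base + (j - 1L), , drop = FALSE]
  v <- Xc %*% w$value
  v <- v + rep(b$value, each = nrow(v))
  out <- adNode(tape, v)
  out$backward <- function(g) {
    adAccum(w, crossprod(Xc, g))
    adAccum(b, colSums(g))
    if (inputGrad) {
      dXc <- tcrossprod(g, w$value)
      dx <- matrix(0, nrow(x$value), C)
      for (j in seq_len(k)) {
        rows <- base + (j - 1L)
        dx[rows, ] <- dx[rows, ] + dXc[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
      }
      adAccum(x, dx)
    }
  }
  out
}

## Max pooling with width = stride = pool along time (trailing remainder
## dropped), per feature column.
adMaxPool <- function(tape, x, nb, L, pool) {
  C <- ncol(x$value)
  Lout <- L %/% pool
  if (Lout < 1L)
    stop(sprintf("sequence length %d shorter than pool size %d", L, pool))
  base <- as.vector(outer((seq_len(Lout) - 1L) * pool + 1L,
                          (seq_len(nb) - 1L) * L, "+"))
  vals <- x$value[base, , drop = FALSE]
  arg <- matrix(base, nb * Lout, C)
  if (pool > 1L) {
    nr <- nb * Lout
    for (r in 2:pool) {
      rows <- base + (r - 1L)
      cand <- x$value[rows, , drop = FALSE]
      upd <- which(cand > vals)
      if (length(upd)) {
        vals[upd] <- cand[upd]
        arg[upd] <- rows[((upd - 1L) %% nr) + 1L]
      }
    }
  }
  out <- adNode(tape, vals)
  out$backward <- function(g) {
    dx <- matrix(0, nrow(x$value), C)
    idx <- cbind(as.vector(arg), rep(seq_len(C), each = nrow(arg)))
    dx[idx] <- dx[idx] + as.vector(g)
    adAccum(x, dx)
  }
  out
}

## Batch normalization over all rows (i.e. batch x time for conv features),
## per column; biased variance as is conventional. In training mode batch
## statistics are used and running statistics updated in `state`; in
## inference mode the running statistics are used.
adBatchNorm <- function(tape, x, gamma, beta, state, training,
                        momentum = 0.9, eps = 1e-3) {
  if (training) {
    n <- nrow(x$value)
    mu <- colMeans(x$value)
    xc <- x$value - rep(mu, each = n)
    va <- colMeans(xc^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
    istd <- 1 / sqrt(va + eps)
    xhat <- xc * rep(istd, each = n)
    out <- adNode(tape, xhat * rep(gamma$value, each = n) +
                    rep(beta$value, each = n))
    out$backward <- function(g) {
      adAccum(gamma, colSums(g * xhat))
      adAccum(beta, colSums(g))
      dxhat <- g * rep(gamma$value, each = n)
      dx <- (dxhat - rep(colMeans(dxhat), each = n) -
               xhat * rep(colMeans(dxhat * xhat), each = n)) *
        rep(istd, each = n)
      adAccum(x, dx)
    }
    out
  } else {
    n <- nrow(x$value)
    istd <- 1 / sqrt(state$var + eps)
    xhat <- (x$value - rep(state$mean, each = n)) * rep(istd, each = n)
    out <- adNode(tape, xhat * rep(gamma$value, each = n) +
                    rep(beta$value, each = n))
    out$backward <- function(g) {
      adAccum(gamma, colSums(g * xhat))
      adAccum(beta, colSums(g))
      adAccum(x, g * rep(gamma$value * istd, each = n))
    }
    out
  }
}

## Layer normalization across columns, per row, with affine rescale.
adLayerNorm <- function(tape, x, gamma, beta, eps = 1e-6) {
  C <- ncol(x$value)
  mu <- rowMeans(x$value)
  xc <- x$value - mu
  va <- rowMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  out <- adNode(tape, xhat * rep(gamma$value, each = nrow(xhat)) +
                  rep(beta$value, each = nrow(xhat)))
  out$backward <- function(g) {
    adAccum(gamma, colSums(g * xhat))
    adAccum(beta, colSums(g))
    dxhat <- g * rep(gamma$value, each = nrow(g))
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * istd
    adAccum(x, dx)
  }
  out
}

## Row-wise softmax (used for attention weights).
adSoftmaxRows <- function(tape, x) {
  m <- x$value - apply(x$value, 1, max)
  e <- exp(m)
  y <- e / rowSums(e)
  out <- adNode(tape, y)
  out$backward <- function(g) {
    adAccum(x, y * (g - rowSums(g * y)))
  }
  out
}

## Batched (per-sample block) matrix multiply for attention:
## a is (nb*La) x da, b is (nb*Lb) x db.
## transposeB = TRUE:  out_i = A_i %*% t(B_i)  -> (nb*La) x Lb  (da == db)
## transposeB = FALSE: out_i = A_i %*% B_i     -> (nb*La) x db  (da == Lb)
adBmm <- function(tape, a, b, nb, transposeB = FALSE) {
  La <- nrow(a$value) %/% nb
  Lb <- nrow(b$value) %/% nb
  outCols <- if (transposeB) Lb else ncol(b$value)
  v <- matrix(0, nb * La, outCols)
  for (i in seq_len(nb)) {
    ar <- ((i - 1L) * La + 1L):(i * La)
    br <- ((i - 1L) * Lb + 1L):(i * Lb)
    A <- a$value[ar, , drop = FALSE]
    B <- b$value[br, , drop = FALSE]
    v[ar, ] <- if (transposeB) tcrossprod(A, B) else A %*% B
  }
  out <- adNode(tape, v)
  out$backward <- function(g) {
    da <- matrix(0, nrow(a$value), ncol(a$value))
    db <- matrix(0, nrow(b$value), ncol(b$value))
    for (i in seq_len(nb)) {
      ar <- ((i - 1L) * La + 1L):(i * La)
      br <- ((i - 1L) * Lb + 1L):(i * Lb)
      G <- g[ar, , drop = FALSE]
      A <- a$value[ar, , drop = FALSE]
      B <- b$value[br, , drop = FALSE]
      if (transposeB) {
        da[ar, ] <- G %*% B
        db[br, ] <- crossprod(G, A)
      } else {
        da[ar, ] <- tcrossprod(G, B)
        db[br, ] <- crossprod(A, G)
      }
    }
    adAccum(a, da)
    adAccum(b, db)
  }
  out
}

## Flatten batched sequences (nb*L) x C -> nb x (L*C), time-major per sample
## (row b holds [t1 features, t2 features, ...]).
adFlatten <- function(tape, x, nb, L) {
  C <- ncol(x$value)
  arr <- array(x$value, dim = c(L, nb, C))
  v <- t(matrix(aperm(arr, c(3, 1, 2)), L * C, nb))
  out <- adNode(tape, v)
  out$backward <- function(g) {
    garr <- array(t(g), dim = c(C, L, nb))
    adAccum(x, matrix(aperm(garr, c(2, 3, 1)), nb * L, C))
  }
  out
}

## Fused softmax + mean cross-entropy over integer labels in 0..K-1.
## Returns a scalar node; $probs holds the row-wise class probabilities.
adSoftmaxCrossEntropy <- function(tape, logits, labels) {
  n <- nrow(logits$value)
  m <- logits$value - apply(logits$value, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  out <- adNode(tape, loss)
  out$probs <- p
  out$backward <- function(g) {
    y <- matrix(0, n, ncol(p))
    y[idx] <- 1
    adAccum(logits, g * (p - y) / n)
  }
  out
}

## ----- initializers ----------------------------------------------------------

glorotUniform <- function(fanIn, fanOut, dims = c(fanIn, fanOut)) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(prod(dims), -lim, lim), dims[1], dims[2])
}
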