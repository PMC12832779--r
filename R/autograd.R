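# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every tensor is an environment holding `value` (a matrix; vectors are
# single-column matrices), `grad`, the `parents` it was computed from and a
# `backfn(g, need)` returning one gradient per parent. Multi-channel volumes
# are [C, V] matrices with V voxels in R's column-major array order; the
# spatial dims travel alongside in the layer code, not in the tensor.
# Gradients accumulate across backward() calls, which is what gives
# mini-batch accumulation; call ag_zero_grad() between optimizer steps.

ag_counter <- new.env(parent = emptyenv())
ag_counter$epoch <- 0L

ag_tensor <- function(value, requires_grad = FALSE) {
  if (!is.matrix(value)) value <- as.matrix(value)
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$requires_grad <- requires_grad
  e$needs <- requires_grad
  e$parents <- list()
  e$backfn <- NULL
  e$tag <- 0L
  class(e) <- "ag_tensor"
  e
}

is_ag <- function(x) inherits(x, "ag_tensor")

ag_wrap <- function(x) if (is_ag(x)) x else ag_tensor(x)

ag_op <- function(value, parents, backfn) {
  e <- ag_tensor(value)
  e$parents <- parents
  e$backfn <- backfn
  e$needs <- any(vapply(parents, function(p) p$needs, logical(1)))
  e
}

#' @noRd
ag_backward <- function(root, seed = NULL) {
  if (is.null(seed)) {
    stopifnot(length(root$value) == 1L)
    seed <- matrix(1, 1, 1)
  }
  ag_counter$epoch <- ag_counter$epoch + 1L
  epoch <- ag_counter$epoch
  # iterative DFS post-order -> topological order
  order <- vector("list", 256L)
  n_ord <- 0L
  stack <- list(list(node = root, i = 0L))
  root$tag <- epoch
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    node <- top$node
    if (top$i < length(node$parents)) {
      stack[[length(stack)]]$i <- top$i + 1L
      p <- node$parents[[top$i + 1L]]
      if (p$tag != epoch && p$needs) {
        p$tag <- epoch
        stack[[length(stack) + 1L]] <- list(node = p, i = 0L)
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  root$grad <- if (is.null(root$grad)) seed else root$grad + seed
  for (j in seq(n_ord, 1L)) {
    node <- order[[j]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    need <- vapply(node$parents, function(p) p$needs, logical(1))
    grads <- node$backfn(node$grad, need)
    for (i in seq_along(node$parents)) {
      p <- node$parents[[i]]
      if (!need[i] || is.null(grads[[i]])) next
      g <- grads[[i]]
      if (!is.matrix(g)) g <- matrix(g, nrow(p$value), ncol(p$value))
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise / linear algebra ops ---------------------------------------

ag_add <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  ag_op(a$value + b$value, list(a, b), function(g, need) list(g, g))
}

ag_sub <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  ag_op(a$value - b$value, list(a, b), function(g, need) list(g, -g))
}

ag_neg <- function(a) ag_op(-a$value, list(a), function(g, need) list(-g))

ag_mul <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  av <- a$value; bv <- b$value
  ag_op(av * bv, list(a, b), function(g, need) list(g * bv, g * av))
}

ag_smul <- function(a, s) ag_op(a$value * s, list(a), function(g, need) list(g * s))

# add a per-channel bias (length nrow) to every column
ag_add_bias <- function(x, b) {
  ag_op(x$value + b$value[, 1L], list(x, b),
        function(g, need) list(g, matrix(rowSums(g), ncol = 1L)))
}

ag_matmul <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  av <- a$value; bv <- b$value
  ag_op(av %*% bv, list(a, b), function(g, need) {
    list(if (need[1]) g %*% t(bv) else NULL,
         if (need[2]) t(av) %*% g else NULL)
  })
}

ag_t <- function(a) ag_op(t(a$value), list(a), function(g, need) list(t(g)))

# y = W x + b with x a [in, n] matrix, W [out, in], b [out, 1]
ag_linear <- function(x, W, b = NULL) {
  y <- ag_matmul(W, x)
  if (is.null(b)) y else ag_add_bias(y, b)
}

ag_rows <- function(x, idx) {
  nr <- nrow(x$value); nc <- ncol(x$value)
  ag_op(x$value[idx, , drop = FALSE], list(x), function(g, need) {
    dx <- matrix(0, nr, nc)
    dx[idx, ] <- g
    list(dx)
  })
}

ag_rbind <- function(xs) {
  vals <- lapply(xs, function(x) x$value)
  nr <- vapply(vals, nrow, integer(1))
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  ag_op(do.call(rbind, vals), xs, function(g, need) {
    lapply(seq_along(xs), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

# multiply each column of x [C, V] by gate vector v [C, 1]
ag_mul_colvec <- function(x, v) {
  xv <- x$value; vv <- v$value[, 1L]
  ag_op(xv * vv, list(x, v), function(g, need) {
    list(g * vv, matrix(rowSums(g * xv), ncol = 1L))
  })
}

ag_pick <- function(x, i) {
  nr <- nrow(x$value); nc <- ncol(x$value)
  ag_op(matrix(x$value[i], 1, 1), list(x), function(g, need) {
    dx <- matrix(0, nr, nc)
    dx[i] <- g[1L]
    list(dx)
  })
}

ag_sum <- function(x) {
  dims <- dim(x$value)
  ag_op(matrix(sum(x$value), 1, 1), list(x),
        function(g, need) list(matrix(g[1L], dims[1], dims[2])))
}

ag_mean <- function(x) ag_smul(ag_sum(x), 1 / length(x$value))

ag_rowmeans <- function(x) {
  nc <- ncol(x$value)
  ag_op(matrix(rowMeans(x$value), ncol = 1L), list(x),
        function(g, need) list(matrix(g[, 1L] / nc, nrow(x$value), nc)))
}

# ---- nonlinearities ---------------------------------------------------------

ag_leaky_relu <- function(x, slope = 0.01) {
  xv <- x$value
  m <- ifelse(xv > 0, 1, slope)
  ag_op(xv * m, list(x), function(g, need) list(g * m))
}

ag_relu <- function(x) ag_leaky_relu(x, 0)

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ag_op(s, list(x), function(g, need) list(g * s * (1 - s)))
}

ag_gelu <- function(x) {
  xv <- x$value
  ph <- stats::pnorm(xv)
  ag_op(xv * ph, list(x),
        function(g, need) list(g * (ph + xv * stats::dnorm(xv))))
}

ag_log <- function(x) {
  xv <- x$value
  ag_op(log(xv), list(x), function(g, need) list(g / xv))
}

ag_exp <- function(x) {
  ev <- exp(x$value)
  ag_op(ev, list(x), function(g, need) list(g * ev))
}

# softmax along each row
ag_softmax_rows <- function(x) {
  xv <- x$value
  m <- apply(xv, 1L, max)
  e <- exp(xv - m)
  s <- e / rowSums(e)
  ag_op(s, list(x), function(g, need) {
    list((g - rowSums(g * s)) * s)
  })
}

ag_dropout <- function(x, p, training, rng = NULL) {
  if (!training || p <= 0) return(x)
  mask <- matrix(stats::runif(length(x$value)) >= p,
                 nrow(x$value), ncol(x$value)) / (1 - p)
  ag_op(x$value * mask, list(x), function(g, need) list(g * mask))
}

# ---- normalization ----------------------------------------------------------

# layer norm over channels (rows), independently per token (column)
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  mu <- colMeans(xv)
  xc <- sweep(xv, 2L, mu)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, `*`)
  gv <- gamma$value[, 1L]
  yv <- xhat * gv + beta$value[, 1L]
  ag_op(yv, list(x, gamma, beta), function(g, need) {
    # dx = (dxhat - mean(dxhat) - xhat * mean(dxhat*xhat)) * inv, per column
    dxhat <- g * gv
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- sweep(dxhat - xhat * rep(m2, each = nrow(g)), 2L, m1)
    dx <- sweep(dx, 2L, inv, `*`)
    list(dx,
         matrix(rowSums(g * xhat), ncol = 1L),
         matrix(rowSums(g), ncol = 1L))
  })
}

# batch norm over voxels (columns), per channel (row). Statistics are always
# the current sample's spatial moments (instance-norm semantics): training
# runs sample-by-sample here, and using EMA moments at eval creates a
# train/eval activation mismatch that wrecks held-out predictions. Running
# moments are still tracked for inspection/checkpoints.
ag_batchnorm <- function(x, gamma, beta, state, training, momentum = 0.1,
                         eps = 1e-5) {
  xv <- x$value
  gv <- gamma$value[, 1L]
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  if (training) {
    if (is.null(state$mean)) {
      state$mean <- mu
      state$var <- v
    } else {
      state$mean <- (1 - momentum) * state$mean + momentum * mu
      state$var <- (1 - momentum) * state$var + momentum * v
    }
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  yv <- xhat * gv + beta$value[, 1L]
  ag_op(yv, list(x, gamma, beta), function(g, need) {
    dxhat <- g * gv
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- (dxhat - m1 - xhat * m2) * inv
    list(dx,
         matrix(rowSums(g * xhat), ncol = 1L),
         matrix(rowSums(g), ncol = 1L))
  })
}

# ---- bilinear ---------------------------------------------------------------

# z = W vec(a b^T) + bias, a [ha,1], b [hb,1], W [out, ha*hb]
ag_bilinear <- function(a, b, W, bias = NULL) {
  av <- a$value; bv <- b$value
  ha <- nrow(av); hb <- nrow(bv)
  m <- as.vector(av[, 1L] %o% bv[, 1L])
  z <- W$value %*% m
  if (!is.null(bias)) z <- z + bias$value[, 1L]
  parents <- c(list(a, b, W), if (!is.null(bias)) list(bias))
  Wv <- W$value
  ag_op(z, parents, function(g, need) {
    dm <- t(Wv) %*% g
    M <- matrix(dm[, 1L], ha, hb)
    out <- list(M %*% bv,
                t(M) %*% av,
                if (need[3]) g %*% matrix(m, nrow = 1L) else NULL)
    if (length(parents) == 4L) out <- c(out, list(g))
    out
  })
}

# ---- convolutions -----------------------------------------------------------

conv_out_dim <- function(d, k, stride = 1L, pad = 0L, dilation = 1L) {
  (d + 2L * pad - ((k - 1L) * dilation + 1L)) %/% stride + 1L
}

# x [Cin, V]; W [Cout, (Cin/groups)*k^3]; b [Cout, 1] or NULL.
# Direct (no-im2col) C++ kernels keep memory flat for large kernels.
ag_conv3d <- function(x, W, b, dims, k, stride = 1L, pad = 0L, dilation = 1L,
                      groups = 1L) {
  xv <- x$value
  Cin <- nrow(xv)
  stopifnot(Cin %% groups == 0L, nrow(W$value) %% groups == 0L)
  dims <- as.integer(dims)
  k <- as.integer(k); stride <- as.integer(stride); pad <- as.integer(pad)
  dilation <- as.integer(dilation); groups <- as.integer(groups)
  Wv <- W$value
  yv <- conv3d_fwd_cpp(xv, Wv, dims, k, stride, pad, dilation, groups)
  if (!is.null(b)) yv <- yv + b$value[, 1L]
  parents <- c(list(x, W), if (!is.null(b)) list(b))
  ag_op(yv, parents, function(gr, need) {
    dx <- if (need[1]) {
      conv3d_bwd_x_cpp(gr, Wv, Cin, dims, k, stride, pad, dilation, groups)
    }
    dW <- if (need[2]) {
      conv3d_bwd_w_cpp(xv, gr, dims, k, stride, pad, dilation, groups)
    }
    out <- list(dx, dW)
    if (length(parents) == 3L) out <- c(out, list(matrix(rowSums(gr), ncol = 1L)))
    out
  })
}

# transposed convolution, stride s, kernel k, no padding
# u [Cin, Vin]; Wt [Cout*k^3, Cin]; output dims (d-1)*s + k
ag_conv_transpose3d <- function(u, Wt, b, dims_in, k, stride) {
  dims_out <- (as.integer(dims_in) - 1L) * as.integer(stride) + as.integer(k)
  uv <- u$value
  Wv <- Wt$value
  Cout <- nrow(Wv) %/% (k^3)
  cols <- Wv %*% uv
  yv <- col2im3d_cpp(cols, Cout, dims_out, as.integer(k), as.integer(stride),
                     0L, 1L)
  if (!is.null(b)) yv <- yv + b$value[, 1L]
  parents <- c(list(u, Wt), if (!is.null(b)) list(b))
  ag_op(yv, parents, function(gr, need) {
    dcols <- im2col3d_cpp(gr, dims_out, as.integer(k), as.integer(stride),
                          0L, 1L)
    out <- list(if (need[1]) t(Wv) %*% dcols else NULL,
                if (need[2]) dcols %*% t(uv) else NULL)
    if (length(parents) == 3L) out <- c(out, list(matrix(rowSums(gr), ncol = 1L)))
    out
  })
}

# ---- pooling (window 2, stride 2) -------------------------------------------

ag_avgpool2 <- function(x, dims) {
  xv <- x$value
  C <- nrow(xv)
  cols <- im2col3d_cpp(xv, as.integer(dims), 2L, 2L, 0L, 1L)
  Vo <- ncol(cols)
  arr <- matrix(cols, nrow = 8L)           # taps fastest (channel-major rows)
  yv <- matrix(colMeans(arr), nrow = C)    # [C, Vo]
  ag_op(yv, list(x), function(g, need) {
    dcols <- matrix(rep(as.vector(g) / 8, each = 8L), nrow = 8L * C)
    list(col2im3d_cpp(dcols, C, as.integer(dims), 2L, 2L, 0L, 1L))
  })
}

ag_maxpool2 <- function(x, dims) {
  xv <- x$value
  C <- nrow(xv)
  cols <- im2col3d_cpp(xv, as.integer(dims), 2L, 2L, 0L, 1L)
  Vo <- ncol(cols)
  arr <- matrix(cols, nrow = 8L)           # [8, C*Vo]
  m <- arr[1L, ]
  for (t in 2:8) m <- pmax(m, arr[t, ])
  yv <- matrix(m, nrow = C)
  ag_op(yv, list(x), function(g, need) {
    gv <- as.vector(g)
    darr <- matrix(0, 8L, C * Vo)
    taken <- rep(FALSE, C * Vo)
    for (t in 1:8) {
      hit <- (arr[t, ] == m) & !taken
      darr[t, hit] <- gv[hit]
      taken <- taken | hit
    }
    list(col2im3d_cpp(matrix(darr, nrow = 8L * C), C, as.integer(dims),
                      2L, 2L, 0L, 1L))
  })
}
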