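#' @useDynLib mmnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# A compact reverse-mode automatic-differentiation engine.
#
# Values are dense numeric arrays; feature maps use layout (C, H, W, N)
# (channel fastest, column-major) so that channel-wise layer norm, channel
# gating and the compiled convolution kernels all touch contiguous memory.
# Each op node keeps references to its parents and a closure that maps the
# node's upstream gradient to gradients for each parent; backward() walks the
# graph in reverse creation order, accumulating into leaf parameters.
# ---------------------------------------------------------------------------

.mm <- new.env(parent = emptyenv())
.mm$id <- 0L

next_id <- function() {
  .mm$id <- .mm$id + 1L
  .mm$id
}

new_tensor <- function(value, requires_grad = FALSE, parents = list(), backward = NULL) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$requires_grad <- requires_grad ||
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  t$parents <- parents
  t$backward_fn <- backward
  t$id <- next_id()
  class(t) <- "mm_tensor"
  t
}

is_tensor <- function(x) inherits(x, "mm_tensor")

#' Wrap a numeric array as a constant (no-gradient) tensor
#' @param x numeric array
#' @keywords internal
as_tensor <- function(x) {
  if (is_tensor(x)) x else new_tensor(x)
}

tensor_value <- function(x) if (is_tensor(x)) x$value else x

#' Run reverse-mode backpropagation from a scalar tensor
#'
#' Accumulates gradients into every reachable tensor with
#' `requires_grad = TRUE` (its `$grad` field).
#' @param loss a tensor holding a single number
#' @keywords internal
backward <- function(loss) {
  stopifnot(is_tensor(loss), length(loss$value) == 1L)
  # collect reachable grad-requiring nodes
  nodes <- new.env(parent = emptyenv())
  stack <- list(loss)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(nodes[[key]])) next
    if (!nd$requires_grad) next
    nodes[[key]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- ls(nodes)
  ord <- ord[order(-as.numeric(ord))]
  loss$grad <- array(1, dim = dim(loss$value) %||% 1L)
  for (key in ord) {
    nd <- nodes[[key]]
    if (is.null(nd$backward_fn) || is.null(nd$grad)) next
    grads <- nd$backward_fn(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      g <- grads[[k]]
      if (is.null(g) || !p$requires_grad) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- elementwise ------------------------------------------------------------

op_add <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  new_tensor(a$value + b$value, parents = list(a, b),
             backward = function(g) list(g, g))
}

op_sub <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  new_tensor(a$value - b$value, parents = list(a, b),
             backward = function(g) list(g, -g))
}

op_scale <- function(a, s) {
  a <- as_tensor(a)
  new_tensor(a$value * s, parents = list(a),
             backward = function(g) list(g * s))
}

op_relu <- function(a) {
  a <- as_tensor(a)
  keep <- a$value > 0
  new_tensor(a$value * keep, parents = list(a),
             backward = function(g) list(g * keep))
}

op_gelu <- function(a) {
  a <- as_tensor(a)
  x <- a$value
  cdf <- stats::pnorm(x)
  new_tensor(x * cdf, parents = list(a),
             backward = function(g) list(g * (cdf + x * stats::dnorm(x))))
}

op_sigmoid <- function(a) {
  a <- as_tensor(a)
  s <- 1 / (1 + exp(-a$value))
  new_tensor(s, parents = list(a),
             backward = function(g) list(g * s * (1 - s)))
}

# --- convolution and resampling --------------------------------------------

#' 2D convolution op (cross-correlation, PyTorch convention)
#'
#' @param x tensor (C,H,W,N); @param w weight tensor (Cin/groups, kh, kw, Cout)
#' @param b optional bias tensor (Cout)
#' @param stride,dilation length-2 integer (h, w)
#' @param pad length-4 integer (top, bottom, left, right), zeros
#' @param groups channel groups; `groups = C` with `Cin/groups = 1` is a
#'   depth-wise convolution
#' @keywords internal
op_conv2d <- function(x, w, b = NULL, stride = c(1L, 1L), pad = c(0L, 0L, 0L, 0L),
                      dilation = c(1L, 1L), groups = 1L) {
  x <- as_tensor(x); w <- as_tensor(w)
  xd <- dim(x$value); wd <- dim(w$value)
  if (xd[1] != wd[1] * groups) {
    stop(sprintf("conv2d: input has %d channels, weights expect %d",
                 xd[1], wd[1] * groups), call. = FALSE)
  }
  has_b <- !is.null(b)
  if (has_b) b <- as_tensor(b)
  y <- .conv2d_fw(x$value, xd, w$value, wd,
                  if (has_b) b$value else numeric(0), has_b,
                  stride[1], stride[2], pad[1], pad[2], pad[3], pad[4],
                  dilation[1], dilation[2], groups)
  yd <- dim(y)
  parents <- if (has_b) list(x, w, b) else list(x, w)
  xv <- x$value; wv <- w$value
  new_tensor(y, parents = parents, backward = function(g) {
    dx <- if (x$requires_grad)
      .conv2d_bw_input(g, yd, wv, wd, xd, stride[1], stride[2],
                       pad[1], pad[3], dilation[1], dilation[2], groups)
    dw <- if (w$requires_grad)
      .conv2d_bw_weight(g, yd, xv, xd, wd, stride[1], stride[2],
                        pad[1], pad[3], dilation[1], dilation[2], groups)
    out <- list(dx, dw)
    if (has_b) out[[3]] <- rowSums(matrix(g, nrow = yd[1]))
    out
  })
}

op_upsample_bilinear <- function(x, out_hw) {
  x <- as_tensor(x)
  xd <- dim(x$value)
  y <- .bilinear_fw(x$value, xd, as.integer(out_hw[1]), as.integer(out_hw[2]))
  yd <- dim(y)
  new_tensor(y, parents = list(x),
             backward = function(g) list(.bilinear_bw(g, yd, xd)))
}

# Reflective spatial padding (no edge repeat, PyTorch ReflectionPad2d)
op_pad_reflect <- function(x, pad) {  # (top, bottom, left, right)
  x <- as_tensor(x)
  d <- dim(x$value)
  H <- d[2]; W <- d[3]
  ridx <- function(n, p0, p1) {
    i <- seq_len(n + p0 + p1) - 1L - p0     # positions relative to source
    i <- ifelse(i < 0, -i, i)
    i <- ifelse(i > n - 1L, 2L * (n - 1L) - i, i)
    i + 1L
  }
  hi <- ridx(H, pad[1], pad[2]); wi <- ridx(W, pad[3], pad[4])
  y <- x$value[, hi, wi, , drop = FALSE]
  new_tensor(y, parents = list(x), backward = function(g) {
    dx <- array(0, dim = d)
    # scatter-add: accumulate duplicated rows/cols
    for (a in seq_along(hi)) for (b in seq_along(wi)) {
      dx[, hi[a], wi[b], ] <- dx[, hi[a], wi[b], ] + g[, a, b, ]
    }
    list(dx)
  })
}

# --- normalization ----------------------------------------------------------

# Layer norm across channels at every spatial position (per (h, w, n)).
op_layernorm_ch <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_tensor(x); gamma <- as_tensor(gamma); beta <- as_tensor(beta)
  d <- dim(x$value)
  C <- d[1]
  m <- matrix(x$value, nrow = C)           # columns are positions
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  y <- array(xhat * gamma$value + beta$value, dim = d)
  new_tensor(y, parents = list(x, gamma, beta), backward = function(g) {
    gm <- matrix(g, nrow = C)
    dxhat <- gm * gamma$value
    mh <- colMeans(dxhat)
    mhx <- colMeans(dxhat * xhat)
    dx <- sweep(dxhat, 2, mh) - sweep(xhat, 2, mhx, `*`)
    dx <- array(sweep(dx, 2, inv, `*`), dim = d)
    list(dx, rowSums(gm * xhat), rowSums(gm))
  })
}

# Batch norm over (H, W, N) per channel. `state` is an environment carrying
# running_mean / running_var, updated in training mode.
op_batchnorm2d <- function(x, gamma, beta, state, training = FALSE,
                           momentum = 0.1, eps = 1e-5) {
  x <- as_tensor(x); gamma <- as_tensor(gamma); beta <- as_tensor(beta)
  d <- dim(x$value)
  C <- d[1]
  m <- matrix(x$value, nrow = C)
  if (training) {
    mu <- rowMeans(m)
    xc <- m - mu
    va <- rowMeans(xc * xc)
    nn <- ncol(m)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * va * nn / max(nn - 1, 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
    xc <- m - mu
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  y <- array(xhat * gamma$value + beta$value, dim = d)
  new_tensor(y, parents = list(x, gamma, beta), backward = function(g) {
    gm <- matrix(g, nrow = C)
    if (training) {
      dxhat <- gm * gamma$value
      dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    } else {
      dx <- gm * (gamma$value * inv)
    }
    list(array(dx, dim = d), rowSums(gm * xhat), rowSums(gm))
  })
}

# --- shape & combination ----------------------------------------------------

op_concat_ch <- function(xs) {
  xs <- lapply(xs, as_tensor)
  ds <- lapply(xs, function(t) dim(t$value))
  C <- vapply(ds, `[`, integer(1), 1L)
  y <- array(0, dim = c(sum(C), ds[[1]][2], ds[[1]][3], ds[[1]][4]))
  off <- 0L
  for (k in seq_along(xs)) {
    y[off + seq_len(C[k]), , , ] <- xs[[k]]$value
    off <- off + C[k]
  }
  new_tensor(y, parents = xs, backward = function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (k in seq_along(xs)) {
      out[[k]] <- g[off + seq_len(C[k]), , , , drop = FALSE]
      off <- off + C[k]
    }
    out
  })
}

op_mul <- function(a, b) {   # elementwise, same shape
  a <- as_tensor(a); b <- as_tensor(b)
  av <- a$value; bv <- b$value
  new_tensor(av * bv, parents = list(a, b),
             backward = function(g) list(g * bv, g * av))
}

# Multiply each channel of x (C,H,W,N) by gate (C,N)
op_mul_channel <- function(x, gate) {
  x <- as_tensor(x); gate <- as_tensor(gate)
  d <- dim(x$value)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  gx <- array(rep(gate$value, each = 1), dim = c(C, N))
  expand <- function(gv) array(apply(gv, 2, function(col) rep(col, HW)), dim = d)
  y <- x$value * expand(gx)
  xv <- x$value
  new_tensor(y, parents = list(x, gate), backward = function(g) {
    dgate <- matrix(0, C, N)
    for (n in seq_len(N)) {
      dgate[, n] <- rowSums(matrix(g[, , , n] * xv[, , , n], nrow = C))
    }
    list(g * expand(gx), dgate)
  })
}

# Parameter-free channel resampling (nearest): used when an enhanced-features
# block is ablated and a level must still be brought to the shared width.
op_channel_resample <- function(x, c_out) {
  x <- as_tensor(x)
  d <- dim(x$value)
  C <- d[1]
  map <- pmin(C, floor((seq_len(c_out) - 1) * C / c_out) + 1L)
  y <- x$value[map, , , , drop = FALSE]
  new_tensor(y, parents = list(x), backward = function(g) {
    dx <- array(0, dim = d)
    for (k in seq_len(c_out)) {
      dx[map[k], , , ] <- dx[map[k], , , ] + g[k, , , ]
    }
    list(dx)
  })
}

# Global average pool over space: (C,H,W,N) -> (C,N)
op_gap <- function(x) {
  x <- as_tensor(x)
  d <- dim(x$value)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  a <- array(x$value, dim = c(C, HW, N))
  y <- matrix(0, C, N)
  for (n in seq_len(N)) y[, n] <- rowMeans(a[, , n, drop = TRUE])
  if (N == 1L) dim(y) <- c(C, 1L)
  new_tensor(y, parents = list(x), backward = function(g) {
    dx <- array(0, dim = d)
    for (n in seq_len(N)) dx[, , , n] <- array(rep(g[, n] / HW, HW), dim = d[1:3])
    list(dx)
  })
}

op_sigmoid_mat <- function(a) op_sigmoid(a)   # alias; works on any shape

# --- token-space ops (transformer backbone) ---------------------------------

# (C,H,W,N) -> (T,C,N) with T = H*W, tokens in column-major spatial order
op_tokens <- function(x) {
  x <- as_tensor(x)
  d <- dim(x$value)
  y <- aperm(array(x$value, dim = c(d[1], d[2] * d[3], d[4])), c(2, 1, 3))
  new_tensor(y, parents = list(x), backward = function(g) {
    list(array(aperm(g, c(2, 1, 3)), dim = d))
  })
}

# (T,C,N) -> (C,H,W,N)
op_chw <- function(x, H, W) {
  x <- as_tensor(x)
  d <- dim(x$value)
  y <- array(aperm(x$value, c(2, 1, 3)), dim = c(d[2], H, W, d[3]))
  new_tensor(y, parents = list(x), backward = function(g) {
    gd <- dim(g)
    list(aperm(array(g, dim = c(gd[1], H * W, gd[4])), c(2, 1, 3)))
  })
}

# x (T,Cin,N) %*% W (Cin,Cout) + b
op_linear <- function(x, w, b = NULL) {
  x <- as_tensor(x); w <- as_tensor(w)
  has_b <- !is.null(b)
  if (has_b) b <- as_tensor(b)
  d <- dim(x$value)
  Cout <- ncol(w$value)
  y <- array(0, dim = c(d[1], Cout, d[3]))
  for (n in seq_len(d[3])) {
    yn <- x$value[, , n, drop = TRUE] %*% w$value
    if (has_b) yn <- sweep(yn, 2, b$value, `+`)
    y[, , n] <- yn
  }
  xv <- x$value
  parents <- if (has_b) list(x, w, b) else list(x, w)
  new_tensor(y, parents = parents, backward = function(g) {
    dx <- array(0, dim = d)
    dw <- matrix(0, nrow(w$value), Cout)
    db <- numeric(Cout)
    for (n in seq_len(d[3])) {
      gn <- matrix(g[, , n], ncol = Cout)
      dx[, , n] <- gn %*% t(w$value)
      dw <- dw + t(matrix(xv[, , n], nrow = d[1])) %*% gn
      if (has_b) db <- db + colSums(gn)
    }
    out <- list(dx, dw)
    if (has_b) out[[3]] <- db
    out
  })
}

# layer norm across dim 2 of a (T,C,N) array
op_layernorm_tokens <- function(x, gamma, beta, eps = 1e-6) {
  x <- as_tensor(x); gamma <- as_tensor(gamma); beta <- as_tensor(beta)
  d <- dim(x$value)
  m <- aperm(x$value, c(2, 1, 3))          # (C, T, N)
  m <- matrix(m, nrow = d[2])
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  y <- aperm(array(xhat * gamma$value + beta$value, dim = c(d[2], d[1], d[3])),
             c(2, 1, 3))
  new_tensor(y, parents = list(x, gamma, beta), backward = function(g) {
    gm <- matrix(aperm(g, c(2, 1, 3)), nrow = d[2]) * gamma$value
    mh <- colMeans(gm)
    mhx <- colMeans(gm * xhat)
    dx <- sweep(gm, 2, mh) - sweep(xhat, 2, mhx, `*`)
    dx <- sweep(dx, 2, inv, `*`)
    gmraw <- matrix(aperm(g, c(2, 1, 3)), nrow = d[2])
    list(aperm(array(dx, dim = c(d[2], d[1], d[3])), c(2, 1, 3)),
         rowSums(gmraw * xhat), rowSums(gmraw))
  })
}

# batched matrix multiply: a (m,k,B) x b (k,n,B) -> (m,n,B)
op_bmm <- function(a, b) {
  a <- as_tensor(a); b <- as_tensor(b)
  da <- dim(a$value); db_ <- dim(b$value)
  B <- da[3]
  y <- array(0, dim = c(da[1], db_[2], B))
  for (i in seq_len(B)) y[, , i] <- matrix(a$value[, , i], da[1]) %*% matrix(b$value[, , i], db_[1])
  av <- a$value; bv <- b$value
  new_tensor(y, parents = list(a, b), backward = function(g) {
    dA <- array(0, dim = da); dB <- array(0, dim = db_)
    for (i in seq_len(B)) {
      gi <- matrix(g[, , i], da[1])
      dA[, , i] <- gi %*% t(matrix(bv[, , i], db_[1]))
      dB[, , i] <- t(matrix(av[, , i], da[1])) %*% gi
    }
    list(dA, dB)
  })
}

op_transpose12 <- function(x) {
  x <- as_tensor(x)
  y <- aperm(x$value, c(2, 1, 3))
  new_tensor(y, parents = list(x), backward = function(g) list(aperm(g, c(2, 1, 3))))
}

op_reshape <- function(x, dims) {
  x <- as_tensor(x)
  d <- dim(x$value)
  y <- x$value
  dim(y) <- dims
  new_tensor(y, parents = list(x), backward = function(g) { dim(g) <- d; list(g) })
}

# softmax over dim 2 of (m,n,B)
op_softmax2 <- function(x) {
  x <- as_tensor(x)
  d <- dim(x$value)
  y <- array(0, dim = d)
  for (i in seq_len(d[3])) {
    m <- matrix(x$value[, , i], d[1])
    m <- exp(m - apply(m, 1, max))
    y[, , i] <- m / rowSums(m)
  }
  yv <- y
  new_tensor(y, parents = list(x), backward = function(g) {
    dx <- array(0, dim = d)
    for (i in seq_len(d[3])) {
      gi <- matrix(g[, , i], d[1]); yi <- matrix(yv[, , i], d[1])
      dx[, , i] <- yi * (gi - rowSums(gi * yi))
    }
    list(dx)
  })
}
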