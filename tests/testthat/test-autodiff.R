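# The autodiff engine under the network: compiled kernels against naive
# loop oracles, and analytic gradients against central finite differences.

ad <- asNamespace("mmnet")

naive_conv <- function(x, w, b, stride, pad, dil, groups) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]; N <- dim(x)[4]
  Cpg <- dim(w)[1]; kh <- dim(w)[2]; kw <- dim(w)[3]; Cout <- dim(w)[4]
  Ho <- (H + pad[1] + pad[2] - dil[1] * (kh - 1) - 1) %/% stride[1] + 1
  Wo <- (W + pad[3] + pad[4] - dil[2] * (kw - 1) - 1) %/% stride[2] + 1
  Copg <- Cout %/% groups
  y <- array(0, c(Cout, Ho, Wo, N))
  for (n in 1:N) for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    g <- (co - 1) %/% Copg
    acc <- if (length(b)) b[co] else 0
    for (i in 1:kh) for (j in 1:kw) {
      hi <- (ho - 1) * stride[1] - pad[1] + (i - 1) * dil[1] + 1
      wi <- (wo - 1) * stride[2] - pad[3] + (j - 1) * dil[2] + 1
      if (hi < 1 || hi > H || wi < 1 || wi > W) next
      for (c in 1:Cpg) acc <- acc + x[g * Cpg + c, hi, wi, n] * w[c, i, j, co]
    }
    y[co, ho, wo, n] <- acc
  }
  y
}

test_that("compiled convolution matches a loop oracle across configurations", {
  set.seed(42)
  cases <- list(
    list(ci = 5L, co = 4L, k = c(3L, 3L), s = c(2L, 1L), p = c(1L, 2L, 0L, 1L),
         d = c(1L, 2L), g = 1L),
    list(ci = 6L, co = 6L, k = c(3L, 3L), s = c(1L, 1L), p = c(1L, 1L, 1L, 1L),
         d = c(1L, 1L), g = 6L),                      # depth-wise
    list(ci = 4L, co = 8L, k = c(1L, 7L), s = c(1L, 1L), p = c(0L, 0L, 3L, 3L),
         d = c(1L, 1L), g = 1L),                      # separable row kernel
    list(ci = 4L, co = 4L, k = c(4L, 4L), s = c(4L, 4L), p = c(0L, 0L, 0L, 0L),
         d = c(1L, 1L), g = 1L),                      # patch embedding
    list(ci = 4L, co = 6L, k = c(2L, 2L), s = c(1L, 1L), p = c(0L, 1L, 1L, 0L),
         d = c(1L, 1L), g = 2L)                       # even kernel, asym pad
  )
  for (cs in cases) {
    x <- array(rnorm(cs$ci * 8 * 9 * 2), c(cs$ci, 8L, 9L, 2L))
    w <- array(rnorm(cs$ci %/% cs$g * prod(cs$k) * cs$co),
               c(cs$ci %/% cs$g, cs$k, cs$co))
    b <- rnorm(cs$co)
    got <- ad$.conv2d_fw(x, dim(x), w, dim(w), b, TRUE, cs$s[1], cs$s[2],
                         cs$p[1], cs$p[2], cs$p[3], cs$p[4],
                         cs$d[1], cs$d[2], cs$g)
    want <- naive_conv(x, w, b, cs$s, cs$p, cs$d, cs$g)
    expect_equal(dim(got), dim(want))
    expect_tensor_close(got, want, 1e-10)
  }
})

fd_grad_check <- function(f, params, n_probe = 3L, eps = 1e-5, tol = 1e-4) {
  for (p in params) p$grad <- NULL
  loss <- f()
  ad$backward(loss)
  for (nm in names(params)) {
    t <- params[[nm]]
    expect_false(is.null(t$grad), info = paste("no gradient for", nm))
    idx <- sample(length(t$value), min(n_probe, length(t$value)))
    for (i in idx) {
      v0 <- t$value[i]
      t$value[i] <- v0 + eps
      lp <- as.numeric(f()$value)
      t$value[i] <- v0 - eps
      lm <- as.numeric(f()$value)
      t$value[i] <- v0
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - t$grad[i]), tol * max(1, abs(num)))
    }
  }
}

test_that("gradients of a conv/norm/gate graph match finite differences", {
  set.seed(7)
  ps <- ad$new_param_set()
  conv1 <- ad$conv_layer(ps, "c1", 3L, 4L, k = 3L, stride = 2L,
                         norm = "bn", act = "relu")
  convd <- ad$conv_layer(ps, "c2", 4L, 4L, k = 3L, groups = 4L,
                         bias = TRUE, act = "gelu")
  lnl <- ad$ln_layer(ps, "l1", 4L)
  xin <- array(runif(3 * 8 * 8 * 2), c(3L, 8L, 8L, 2L))
  gt <- array(rbinom(8 * 8 * 2, 1, 0.5), c(1L, 8L, 8L, 2L))
  f <- function() {
    y <- lnl(convd(conv1(ad$new_tensor(xin), training = TRUE), training = TRUE))
    y <- ad$op_upsample_bilinear(y, c(8L, 8L))
    y <- ad$op_mul_channel(y, ad$op_sigmoid(ad$op_gap(y)))
    y <- ad$op_channel_resample(ad$op_concat_ch(list(y, y)), 1L)
    ad$op_total_loss(ad$op_sigmoid(y), gt, reduction = "mean")
  }
  fd_grad_check(f, ps$params)
})

test_that("token-space ops (linear, tokens LN, attention pieces) match finite differences", {
  set.seed(8)
  ps <- ad$new_param_set()
  lin <- ad$linear_layer(ps, "q", 4L, 4L)
  lnt <- ad$ln_tokens_layer(ps, "ln", 4L)
  xin <- array(rnorm(6 * 4 * 2), c(6L, 4L, 2L))
  f <- function() {
    z <- lnt(lin(ad$new_tensor(xin)))
    zh <- ad$op_reshape(z, c(6L, 2L, 4L))          # 2 heads
    att <- ad$op_softmax2(ad$op_scale(ad$op_bmm(zh, ad$op_transpose12(zh)), 0.7))
    o <- ad$op_reshape(ad$op_bmm(att, zh), c(6L, 4L, 2L))
    v <- ad$op_sigmoid(o)
    s <- sum(v$value)
    ad$new_tensor(array(s, 1L), parents = list(v),
                  backward = function(g) list(array(as.numeric(g), dim(v$value))))
  }
  fd_grad_check(f, ps$params)
})

test_that("reflect padding mirrors without repeating the edge and backpropagates", {
  x <- array(seq_len(1 * 4 * 4), c(1L, 4L, 4L, 1L))
  t <- ad$new_tensor(x, requires_grad = TRUE)
  y <- ad$op_pad_reflect(t, c(2L, 1L, 0L, 0L))
  expect_equal(dim(y$value), c(1L, 7L, 4L, 1L))
  expect_equal(y$value[1, , 1, 1], c(3, 2, 1, 2, 3, 4, 3))
  loss <- ad$new_tensor(array(sum(y$value), 1L), parents = list(y),
                        backward = function(g) list(array(1, dim(y$value))))
  ad$backward(loss)
  # each source row receives one gradient unit per time it was replicated
  expect_equal(t$grad[1, , 1, 1], c(1, 2, 3, 1))
})

test_that("bilinear resize agrees with an independent half-pixel-center computation", {
  set.seed(3)
  x <- array(rnorm(2 * 5 * 4), c(2L, 5L, 4L, 1L))
  Ho <- 9L; Wo <- 7L
  got <- ad$.bilinear_fw(x, dim(x), Ho, Wo)
  for (pick in list(c(1L, 1L, 1L), c(2L, 5L, 3L), c(1L, 9L, 7L))) {
    c0 <- pick[1]; ho <- pick[2]; wo <- pick[3]
    hs <- min(max((ho - 0.5) * 5 / Ho - 0.5, 0), 4)
    ws <- min(max((wo - 0.5) * 4 / Wo - 0.5, 0), 3)
    h0 <- floor(hs); w0 <- floor(ws)
    fh <- hs - h0; fw <- ws - w0
    h1 <- min(h0 + 1, 4); w1 <- min(w0 + 1, 3)
    want <- (1 - fh) * (1 - fw) * x[c0, h0 + 1, w0 + 1, 1] +
      fh * (1 - fw) * x[c0, h1 + 1, w0 + 1, 1] +
      (1 - fh) * fw * x[c0, h0 + 1, w1 + 1, 1] +
      fh * fw * x[c0, h1 + 1, w1 + 1, 1]
    expect_equal(got[c0, ho, wo, 1], want, tolerance = 1e-12)
  }
})
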