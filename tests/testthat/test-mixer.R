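# Mixing module: patch embedding, residual block structure, channel gate.

ad <- asNamespace("mmnet")

make_mixer <- function(cg, cfg, seed = 1L) {
  set.seed(seed)
  ps <- ad$new_param_set()
  list(mx = ad$build_mixer(ps, "mixer", cg, cfg), ps = ps)
}

test_that("patch embedding pads and tokenizes to the expected grid", {
  m <- make_mixer(64L, mixer_config(depth = 0L, dim = 64L, patch_size = 9L))
  z <- patch_embed(m$mx, array(rnorm(64 * 352 * 352), c(64L, 352L, 352L)))
  expect_equal(dim(z), c(64L, 40L, 40L))   # 352 -> reflect-pad 360 -> 40 tokens

  m2 <- make_mixer(16L, mixer_config(depth = 0L, dim = 16L, patch_size = 4L))
  z2 <- patch_embed(m2$mx, array(rnorm(16 * 12 * 12), c(16L, 12L, 12L)))
  expect_equal(dim(z2), c(16L, 3L, 3L))
})

test_that("p = 1 with identity embedding and no LN is the identity", {
  m <- make_mixer(4L, mixer_config(depth = 0L, dim = 4L, patch_size = 1L,
                                   kernel_size = 3L, ln = FALSE))
  w <- m$ps$params[["mixer.embed.w"]]
  w$value <- array(0, dim(w$value))
  for (c in 1:4) w$value[c, 1, 1, c] <- 1
  m$ps$params[["mixer.embed.b"]]$value[] <- 0
  x <- array(abs(rnorm(4 * 6 * 6)) + 3, c(4L, 6L, 6L))  # >0: GELU(x) ~ x for large x
  z <- patch_embed(m$mx, x)
  expect_equal(dim(z), dim(x))
  expect_tensor_close(z, x * pnorm(x), 1e-8)   # exact-GELU identity path
})

test_that("a zero-initialized mixing block reduces to LN(LN(z))", {
  m <- make_mixer(16L, mixer_config(depth = 1L, dim = 16L, kernel_size = 7L,
                                    patch_size = 4L))
  for (nm in c("mixer.block1.dw.w", "mixer.block1.dw.b",
               "mixer.block1.pw.w", "mixer.block1.pw.b")) {
    m$ps$params[[nm]]$value[] <- 0
  }
  set.seed(2)
  z <- array(rnorm(16 * 5 * 5), c(16L, 5L, 5L))
  got <- mix_block(m$mx, z, block = 1L)
  # independent double layer-norm over channels at each position
  ln_ref <- function(a, eps = 1e-5) {
    out <- a
    for (i in seq_len(dim(a)[2])) for (j in seq_len(dim(a)[3])) {
      v <- a[, i, j]
      mu <- mean(v)
      va <- mean((v - mu)^2)
      out[, i, j] <- (v - mu) / sqrt(va + eps)
    }
    out
  }
  expect_tensor_close(got, ln_ref(ln_ref(z)), 1e-8)
})

test_that("stacked blocks keep the token grid shape at the published depth", {
  m <- make_mixer(16L, mixer_config(depth = 20L, dim = 16L, kernel_size = 7L,
                                    patch_size = 4L))
  expect_length(m$mx$blocks, 20L)
  z <- array(rnorm(16 * 8 * 8), c(16L, 8L, 8L))
  for (b in seq_len(20L)) z <- mix_block(m$mx, z, block = b)
  expect_equal(dim(z), c(16L, 8L, 8L))
  expect_true(all(is.finite(z)))
})

test_that("the channel gate is sigmoid-pooled: closed-form spot checks", {
  z0 <- array(0, c(8L, 5L, 5L))
  expect_equal(as.vector(channel_gate(z0)), rep(0.5, 8L))
  z1 <- z0
  z1[3, , ] <- 10
  g <- as.vector(channel_gate(z1))
  expect_equal(g[3], 1 / (1 + exp(-10)), tolerance = 1e-10)
  expect_equal(g[-3], rep(0.5, 7L))
  set.seed(4)
  for (k in 1:20) {
    zr <- array(rnorm(8 * 5 * 5, sd = 5), c(8L, 5L, 5L))
    gr <- channel_gate(zr)
    expect_true(all(gr > 0 & gr < 1))
  }
})

test_that("gating multiplies each channel by its weight, exactly", {
  set.seed(5)
  G <- array(rnorm(6 * 4 * 4), c(6L, 4L, 4L))
  gate <- runif(6L)
  got <- apply_gate(G, gate)
  for (c in 1:6) expect_tensor_close(got[c, , ], gate[c] * G[c, , ], 1e-12)
  expect_identical(apply_gate(G, rep(1, 6L)), G)
  expect_tensor_close(apply_gate(G, rep(0.5, 6L)), 0.5 * G, 1e-12)
  expect_error(apply_gate(G, runif(5L)), "channels")
})

test_that("the mask head maps a gated map to bounded probabilities of the right size", {
  set.seed(6)
  ps <- ad$new_param_set()
  head <- ad$conv_layer(ps, "head", 64L, 1L, k = 1L, pad = c(0L, 0L, 0L, 0L),
                        bias = TRUE)
  gated <- array(rnorm(64 * 44 * 44), c(64L, 44L, 44L))
  p <- mask_head(head, gated, c(352L, 352L))
  expect_equal(dim(p), c(352L, 352L))
  expect_true(all(p >= 0 & p <= 1))
  # constant-zero logits give 0.5 everywhere
  ps$params[["head.w"]]$value[] <- 0
  ps$params[["head.b"]]$value[] <- 0
  expect_equal(unique(as.vector(mask_head(head, gated, c(88L, 88L)))), 0.5)
  # raising a logit never lowers the corresponding probability
  ps$params[["head.b"]]$value[] <- 0.3
  p1 <- mask_head(head, gated * 0, c(44L, 44L))
  ps$params[["head.b"]]$value[] <- 0.6
  p2 <- mask_head(head, gated * 0, c(44L, 44L))
  expect_true(all(p2 >= p1))
})

test_that("depth zero still yields a valid gate and LN (not BN) is used throughout", {
  cfg <- mmnet_tiny_config(mixer = list(depth = 0L))
  m0 <- build_mmnet(cfg, seed = 2L)
  x <- array(runif(96 * 96 * 3), c(96L, 96L, 3L))
  p <- mmnet_forward(m0, x)
  expect_equal(dim(p), c(96L, 96L))
  expect_true(all(p > 0 & p < 1))
  m <- build_mmnet(mmnet_tiny_config(), seed = 2L)
  expect_true(assert_mixer_layernorm(m))
})
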