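# Parameter store, layer constructors and the Adam optimizer.
#
# A model owns one param-set environment; every layer registers its tensors
# under a hierarchical dotted name ("feb2.branch1.conv0.w"), which is what
# parameter counting and the ablation-lattice bookkeeping key on.

new_param_set <- function() {
  ps <- new.env(parent = emptyenv())
  ps$params <- list()
  ps$buffers <- list()
  ps
}

add_param <- function(ps, name, value) {
  t <- new_tensor(value, requires_grad = TRUE)
  t$name <- name
  ps$params[[name]] <- t
  t
}

add_buffer <- function(ps, name, env) {
  ps$buffers[[name]] <- env
  env
}

#' Number of trainable parameters, optionally restricted to a name prefix
#' @param model an `mmnet_model` (or a raw param set)
#' @param prefix optional character; count only parameters whose dotted name
#'   starts with this prefix
#' @return integer count
#' @export
n_parameters <- function(model, prefix = NULL) {
  ps <- if (inherits(model, "mmnet_model")) model$ps else model
  nm <- names(ps$params)
  if (!is.null(prefix)) nm <- nm[startsWith(nm, prefix)]
  sum(vapply(ps$params[nm], function(p) length(p$value), numeric(1)))
}

# Kaiming-uniform fan-in init (PyTorch Conv2d/Linear default scheme)
init_uniform <- function(dims, fan_in) {
  b <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -b, b), dim = dims)
}

# A conv layer closure. norm: "bn", "none". act: "relu", "gelu", "none".
conv_layer <- function(ps, name, cin, cout, k = c(3L, 3L), stride = c(1L, 1L),
                       pad = NULL, dilation = c(1L, 1L), groups = 1L,
                       norm = "none", act = "none", bias = NULL) {
  if (length(k) == 1L) k <- c(k, k)
  if (length(stride) == 1L) stride <- c(stride, stride)
  if (length(dilation) == 1L) dilation <- c(dilation, dilation)
  if (is.null(pad)) {  # "same" for odd kernels at stride 1
    ph <- dilation[1] * (k[1] - 1L)
    pw <- dilation[2] * (k[2] - 1L)
    pad <- c(floor(ph / 2), ceiling(ph / 2), floor(pw / 2), ceiling(pw / 2))
  }
  if (is.null(bias)) bias <- (norm == "none")
  cpg <- cin %/% groups
  fan_in <- cpg * k[1] * k[2]
  w <- add_param(ps, paste0(name, ".w"), init_uniform(c(cpg, k[1], k[2], cout), fan_in))
  b <- if (bias) add_param(ps, paste0(name, ".b"), init_uniform(cout, fan_in)) else NULL
  gamma <- beta <- state <- NULL
  if (norm == "bn") {
    gamma <- add_param(ps, paste0(name, ".bn.gamma"), rep(1, cout))
    beta <- add_param(ps, paste0(name, ".bn.beta"), numeric(cout))
    state <- new.env(parent = emptyenv())
    state$running_mean <- numeric(cout)
    state$running_var <- rep(1, cout)
    add_buffer(ps, paste0(name, ".bn"), state)
  }
  structure(function(x, training = FALSE) {
    y <- op_conv2d(x, w, b, stride = stride, pad = pad,
                   dilation = dilation, groups = groups)
    if (norm == "bn") y <- op_batchnorm2d(y, gamma, beta, state, training = training)
    switch(act, relu = op_relu(y), gelu = op_gelu(y), y)
  }, norm = norm, kernel = k, dilation = dilation)
}

ln_layer <- function(ps, name, C) {
  gamma <- add_param(ps, paste0(name, ".ln.gamma"), rep(1, C))
  beta <- add_param(ps, paste0(name, ".ln.beta"), numeric(C))
  function(x) op_layernorm_ch(x, gamma, beta)
}

ln_tokens_layer <- function(ps, name, C) {
  gamma <- add_param(ps, paste0(name, ".ln.gamma"), rep(1, C))
  beta <- add_param(ps, paste0(name, ".ln.beta"), numeric(C))
  function(x) op_layernorm_tokens(x, gamma, beta)
}

linear_layer <- function(ps, name, cin, cout, bias = TRUE) {
  w <- add_param(ps, paste0(name, ".w"), init_uniform(c(cin, cout), cin))
  b <- if (bias) add_param(ps, paste0(name, ".b"), init_uniform(cout, cin)) else NULL
  function(x) op_linear(x, w, b)
}

# --- Adam -------------------------------------------------------------------

#' Create an Adam optimizer state for a list of parameter tensors
#' @param params named list of parameter tensors
#' @param beta1,beta2,eps Adam moment coefficients
#' @keywords internal
adam_new <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) {
    if (is.null(dim(p$value))) numeric(length(p$value))
    else array(0, dim = dim(p$value))
  })
  st$v <- st$m
  st$t <- 0L
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_step <- function(st, params, lr) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[nm]] <- st$beta1 * st$m[[nm]] + (1 - st$beta1) * g
    st$v[[nm]] <- st$beta2 * st$v[[nm]] + (1 - st$beta2) * g * g
    p$value <- p$value - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + st$eps)
  }
  invisible(st)
}
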