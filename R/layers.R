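# Differentiable layer primitives.  All feature maps are (channel, time,
# batch) arrays.  Learnable tensors live in `net$params` (a flat named
# list keyed by dotted paths); batch-norm running statistics live in the
# environment `net$buffers`.  Each *_f returns list(y, cache); each *_b
# consumes the cache, accumulates parameter gradients into the environment
# `G` and returns the input gradient.

add_grad <- function(G, name, g) {
  cur <- G[[name]]
  G[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

conv_f <- function(net, p, spec, x, keep = TRUE) {
  W <- net$params[[paste0(p, ".W")]]
  has_bias <- spec$bias
  b <- if (has_bias) net$params[[paste0(p, ".b")]] else numeric(spec$out_channels)
  res <- cpp_selfonn_conv_fwd(x, flatten_kernel(W), b, spec$kernel_size,
                              spec$taylor_order, spec$stride, spec$padding,
                              has_bias, keep)
  list(y = res$y, cache = if (keep) list(x = x, cols = res$cols))
}

conv_b <- function(net, p, spec, cache, dy, G) {
  W <- net$params[[paste0(p, ".W")]]
  res <- cpp_selfonn_conv_bwd(cache$x, cache$cols, flatten_kernel(W), dy,
                              spec$kernel_size, spec$taylor_order,
                              spec$stride, spec$padding, spec$bias)
  O <- spec$out_channels
  dW <- aperm(array(res$dW, dim = c(O, spec$taylor_order, spec$kernel_size,
                                    spec$in_channels)), c(1L, 4L, 3L, 2L))
  add_grad(G, paste0(p, ".W"), dW)
  if (spec$bias) add_grad(G, paste0(p, ".b"), as.numeric(res$db))
  res$dx
}

bn_f <- function(net, p, x, training, eps = 1e-5, momentum = 0.1) {
  gamma <- net$params[[paste0(p, ".gamma")]]
  beta <- net$params[[paste0(p, ".beta")]]
  d <- dim(x)
  n <- d[2L] * d[3L]
  if (training) {
    xm <- matrix(x, nrow = d[1L])           # C x (L*B)
    mu <- rowMeans(xm)
    va <- rowMeans(xm * xm) - mu * mu       # biased batch variance
    rm_name <- paste0(p, ".running_mean"); rv_name <- paste0(p, ".running_var")
    net$buffers[[rm_name]] <- (1 - momentum) * net$buffers[[rm_name]] + momentum * mu
    unb <- if (n > 1L) va * n / (n - 1L) else va
    net$buffers[[rv_name]] <- (1 - momentum) * net$buffers[[rv_name]] + momentum * unb
  } else {
    mu <- net$buffers[[paste0(p, ".running_mean")]]
    va <- net$buffers[[paste0(p, ".running_var")]]
  }
  inv <- 1 / sqrt(va + eps)                 # length C, recycles over dim 1
  xhat <- (x - mu) * inv
  list(y = gamma * xhat + beta,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, n = n, training = training))
}

bn_b <- function(net, p, cache, dy, G) {
  d <- dim(dy)
  xhat <- cache$xhat
  dym <- matrix(dy, nrow = d[1L])
  dgamma <- rowSums(dym * matrix(xhat, nrow = d[1L]))
  dbeta <- rowSums(dym)
  add_grad(G, paste0(p, ".gamma"), dgamma)
  add_grad(G, paste0(p, ".beta"), dbeta)
  dxhat <- dy * cache$gamma
  if (cache$training) {
    n <- cache$n
    sum_dxhat <- rowSums(matrix(dxhat, nrow = d[1L]))
    sum_dxhat_xhat <- rowSums(matrix(dxhat * xhat, nrow = d[1L]))
    (dxhat - sum_dxhat / n - xhat * (sum_dxhat_xhat / n)) * cache$inv
  } else {
    dxhat * cache$inv
  }
}

tanh_f <- function(x) {
  y <- tanh(x)
  list(y = y, cache = y)
}

tanh_b <- function(cache, dy) dy * (1 - cache * cache)

# Global average pooling over time: (C, L, B) -> C x B feature matrix.
gap_f <- function(x) {
  d <- dim(x)
  y <- colSums(aperm(x, c(2L, 1L, 3L))) / d[2L]   # C x B
  list(y = matrix(y, nrow = d[1L]), cache = d)
}

gap_b <- function(cache, dy) {
  d <- cache
  aperm(array(dy / d[2L], dim = c(d[1L], d[3L], d[2L])), c(1L, 3L, 2L))
}

dense_f <- function(net, p, x) {   # x: features x batch
  W <- net$params[[paste0(p, ".W")]]
  b <- net$params[[paste0(p, ".b")]]
  list(y = W %*% x + b, cache = x)
}

dense_b <- function(net, p, cache, dy, G) {
  W <- net$params[[paste0(p, ".W")]]
  add_grad(G, paste0(p, ".W"), dy %*% t(cache))
  add_grad(G, paste0(p, ".b"), rowSums(dy))
  t(W) %*% dy
}

# Log-softmax over classes (rows), per column.
logsoftmax_f <- function(z) {
  mx <- apply(z, 2L, max)
  zs <- sweep(z, 2L, mx)
  lse <- log(colSums(exp(zs)))
  y <- sweep(zs, 2L, lse)
  list(y = y, cache = exp(y))
}

logsoftmax_b <- function(cache, dy) {
  dy - sweep(cache, 2L, colSums(dy), `*`)
}

mha_f <- function(net, p, xq, xk, xv, heads, keep = TRUE) {
  res <- cpp_mha_fwd(xq, xk, xv,
                     net$params[[paste0(p, ".Wq")]], net$params[[paste0(p, ".Wk")]],
                     net$params[[paste0(p, ".Wv")]], net$params[[paste0(p, ".Wo")]],
                     heads, keep)
  list(y = res$y,
       cache = if (keep) list(xq = xq, xk = xk, xv = xv, A = res$A, Qp = res$Qp,
                              Kp = res$Kp, Vp = res$Vp, O = res$O))
}

mha_b <- function(net, p, heads, cache, dy, G) {
  res <- cpp_mha_bwd(cache$xq, cache$xk, cache$xv,
                     net$params[[paste0(p, ".Wq")]], net$params[[paste0(p, ".Wk")]],
                     net$params[[paste0(p, ".Wv")]], net$params[[paste0(p, ".Wo")]],
                     heads, cache$A, cache$Qp, cache$Kp, cache$Vp, cache$O, dy)
  for (nm in c("Wq", "Wk", "Wv", "Wo"))
    add_grad(G, paste0(p, ".", nm), res[[paste0("d", nm)]])
  res[c("dxq", "dxk", "dxv")]
}

#' Scaled dot-product multi-head attention over time tokens
#'
#' Time positions are the tokens and channels the embedding.  Per head,
#' attention weights are `softmax(Q^T K / sqrt(d))` with `d =
#' channels/heads`; each query position's weights sum to 1.  Following the
#' attention-augmented residual design, the query and value are the block
#' input (identity features) and the key is the block output.
#'
#' @param identity (channel x time) matrix or (channel x time x batch)
#'   array: residual-block input, used as query and value.
#' @param block_output same shape: residual-block output, used as key.
#' @param heads positive integer; channels must be divisible by `heads`.
#' @param projections list with `Wq`, `Wk`, `Wv`, `Wo` (channel x channel
#'   matrices).  Defaults to identity matrices, under which the output is
#'   a pure convex re-mixing of the identity features.
#' @param return_weights if `TRUE`, also return the per-head attention
#'   weight matrices, stored key-major: entry `(j, m)` weights key/value
#'   token `j` for query token `m`, so each column sums to 1.
#' @return The attended feature map, same shape as `identity`; with
#'   `return_weights = TRUE` a list with elements `y` and `weights`.
#' @export
attention_block_forward <- function(identity, block_output, heads = 2L,
                                    projections = NULL,
                                    return_weights = FALSE) {
  fi <- as_feature_map(identity)
  fo <- as_feature_map(block_output)
  if (!identical(dim(fi$x), dim(fo$x)))
    stop("identity and block_output must have identical (channel, time) shape")
  C <- dim(fi$x)[1L]
  if (C %% heads != 0L) stop("channel count must be divisible by heads")
  if (is.null(projections)) {
    I <- diag(C)
    projections <- list(Wq = I, Wk = I, Wv = I, Wo = I)
  }
  res <- cpp_mha_fwd(fi$x, fo$x, fi$x, projections$Wq, projections$Wk,
                     projections$Wv, projections$Wo, as.integer(heads),
                     return_weights)
  y <- restore_rank(res$y, fi$rank)
  if (!return_weights) return(y)
  list(y = y, weights = res$A)
}
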