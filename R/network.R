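#' Architecture specification for the Self-ResNet18 family
#'
#' Fixes the structural hyperparameters of the 1D residual Self-ONN
#' networks: an 8-filter stem, four stages of two residual blocks whose
#' channel widths double per stage (8, 16, 32, 64 by default), a dense
#' classifier head with log-softmax output, and optionally one multi-head
#' attention layer on the second (non-strided) block of each stage.
#'
#' @param taylor_order Taylor order Q of every operational layer (1, 3 or 5
#'   in typical use; Q = 1 reduces every layer to a plain convolution).
#' @param stem_channels filters in the initial layer (default 8).
#' @param stage_channels channel width per stage; must double from
#'   `stem_channels` onward.
#' @param blocks_per_stage residual blocks per stage (default 2).
#' @param n_classes output classes (default 2: Healthy vs ICU).
#' @param attention_enabled add multi-head attention layers
#'   (Self-ResAttentioNet18) or not (Self-ResNet18).
#' @param attention_heads heads per attention layer (default 2); every
#'   stage width must be divisible by it when attention is enabled.
#' @param input_length expected input segment length (default 1024).
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(taylor_order = 3L, stem_channels = 8L,
                              stage_channels = c(8L, 16L, 32L, 64L),
                              blocks_per_stage = 2L, n_classes = 2L,
                              attention_enabled = FALSE,
                              attention_heads = 2L, input_length = 1024L) {
  spec <- list(taylor_order = as.integer(taylor_order),
               stem_channels = as.integer(stem_channels),
               stage_channels = as.integer(stage_channels),
               blocks_per_stage = as.integer(blocks_per_stage),
               n_classes = as.integer(n_classes),
               attention_enabled = isTRUE(attention_enabled),
               attention_heads = as.integer(attention_heads),
               input_length = as.integer(input_length))
  if (spec$taylor_order < 1L) stop("taylor_order must be >= 1")
  if (spec$stem_channels < 1L || spec$n_classes < 1L || spec$input_length < 1L)
    stop("channel, class and length counts must be positive")
  if (spec$stage_channels[1L] != spec$stem_channels ||
      any(diff(spec$stage_channels) != head(spec$stage_channels, -1L)))
    stop("stage_channels must double stage over stage starting at stem_channels")
  if (spec$attention_enabled && any(spec$stage_channels %% spec$attention_heads != 0L))
    stop("every stage channel count must be divisible by attention_heads")
  structure(spec, class = "architecture_spec")
}

stage_prefix <- function(s, b) sprintf("s%d.b%d", s, b)

conv_spec_for <- function(ich, och, K, Q, stride, pad, bias)
  selfonn_layer_spec(ich, och, K, Q, stride, pad, bias)

# Internal: register one operational layer's parameters.
add_conv <- function(net, p, spec, init_scale = NULL) {
  s <- if (is.null(init_scale)) kernel_init_scale(spec) else init_scale
  n <- spec$out_channels * spec$in_channels * spec$kernel_size * spec$taylor_order
  net$params[[paste0(p, ".W")]] <-
    array(runif(n, -s, s), dim = c(spec$out_channels, spec$in_channels,
                                   spec$kernel_size, spec$taylor_order))
  if (spec$bias) net$params[[paste0(p, ".b")]] <- numeric(spec$out_channels)
  net$specs[[p]] <- spec
  net
}

add_bn <- function(net, p, channels) {
  net$params[[paste0(p, ".gamma")]] <- rep(1, channels)
  net$params[[paste0(p, ".beta")]] <- rep(0, channels)
  net$buffers[[paste0(p, ".running_mean")]] <- rep(0, channels)
  net$buffers[[paste0(p, ".running_var")]] <- rep(1, channels)
  net
}

add_mha <- function(net, p, channels) {
  s <- 1 / sqrt(channels)
  for (nm in c("Wq", "Wk", "Wv", "Wo"))
    net$params[[paste0(p, ".", nm)]] <-
      matrix(runif(channels * channels, -s, s), channels, channels)
  net
}

build_network <- function(spec, seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  net <- list(arch = spec, params = list(), specs = list(),
              buffers = new.env(parent = emptyenv()))
  Q <- spec$taylor_order
  # Stem: 7-tap operational layer, stride 2, "same"-style padding, no bias
  # (batch norm follows), then BN + tanh.
  net <- add_conv(net, "stem.conv",
                  conv_spec_for(1L, spec$stem_channels, 7L, Q, 2L, 3L, FALSE))
  net <- add_bn(net, "stem.bn", spec$stem_channels)
  ich <- spec$stem_channels
  for (s in seq_along(spec$stage_channels)) {
    och <- spec$stage_channels[s]
    for (b in seq_len(spec$blocks_per_stage)) {
      p <- stage_prefix(s, b)
      stride <- if (s > 1L && b == 1L) 2L else 1L
      bin <- if (b == 1L) ich else och
      net <- add_conv(net, paste0(p, ".conv1"),
                      conv_spec_for(bin, och, 3L, Q, stride, 1L, FALSE))
      net <- add_bn(net, paste0(p, ".bn1"), och)
      net <- add_conv(net, paste0(p, ".conv2"),
                      conv_spec_for(och, och, 3L, Q, 1L, 1L, FALSE))
      net <- add_bn(net, paste0(p, ".bn2"), och)
      if (stride == 2L) {
        # Learned 1-tap projection shortcut; batch normalization is avoided
        # on the down-sampling path, so the projection keeps its bias.
        net <- add_conv(net, paste0(p, ".shortcut"),
                        conv_spec_for(bin, och, 1L, Q, 2L, 0L, TRUE))
      }
      if (spec$attention_enabled && b == spec$blocks_per_stage)
        net <- add_mha(net, paste0(p, ".attn"), och)
    }
    ich <- och
  }
  fdim <- spec$stage_channels[length(spec$stage_channels)]
  sd_ <- 1 / sqrt(fdim)
  net$params[["head.W"]] <- matrix(runif(spec$n_classes * fdim, -sd_, sd_),
                                   spec$n_classes, fdim)
  net$params[["head.b"]] <- numeric(spec$n_classes)
  class(net) <- "selfonn_net"
  net
}

#' Build the Self-ResNet18 network
#'
#' A 1D residual network whose every convolution is a Self-ONN operational
#' layer: a strided 8-filter stem, four stages of two residual blocks
#' (operational layer -> batch norm -> tanh -> operational layer -> batch
#' norm -> shortcut add -> tanh) with channel widths 8/16/32/64, learned
#' 1-tap projection shortcuts (no batch norm) on the strided blocks of
#' stages 2-4, then global average pooling, a dense linear layer with one
#' output per class, and a log-softmax head.  The main path carries 18
#' weighted layers: 17 operational layers plus the dense classifier.
#'
#' @param spec an [architecture_spec()] with `attention_enabled = FALSE`.
#' @param seed integer seed for weight initialization.
#' @return An object of class `selfonn_net`.
#' @export
build_self_resnet18 <- function(spec = architecture_spec(), seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  if (spec$attention_enabled)
    stop("Self-ResNet18 has no attention layers; use build_self_resattentionet18")
  build_network(spec, seed)
}

#' Build the Self-ResAttentioNet18 network
#'
#' Identical to [build_self_resnet18()] plus one multi-head attention layer
#' on the second (non-strided) residual block of each stage — four in total.
#' The block input (identity features) serves as query and value, the block
#' output as key; the attended feature is added to the block output before
#' propagating to the next stage.
#'
#' @param spec an [architecture_spec()]; `attention_enabled` is forced on.
#' @param seed integer seed for weight initialization.
#' @return An object of class `selfonn_net`.
#' @export
build_self_resattentionet18 <- function(spec = architecture_spec(attention_enabled = TRUE),
                                        seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  spec$attention_enabled <- TRUE
  if (any(spec$stage_channels %% spec$attention_heads != 0L))
    stop("every stage channel count must be divisible by attention_heads")
  build_network(spec, seed)
}

block_f <- function(net, p, x, has_shortcut, has_attn, heads, training, keep) {
  cc <- list()
  c1 <- conv_f(net, paste0(p, ".conv1"), net$specs[[paste0(p, ".conv1")]], x, keep)
  b1 <- bn_f(net, paste0(p, ".bn1"), c1$y, training)
  t1 <- tanh_f(b1$y)
  c2 <- conv_f(net, paste0(p, ".conv2"), net$specs[[paste0(p, ".conv2")]], t1$y, keep)
  b2 <- bn_f(net, paste0(p, ".bn2"), c2$y, training)
  if (has_shortcut) {
    sc <- conv_f(net, paste0(p, ".shortcut"), net$specs[[paste0(p, ".shortcut")]], x, keep)
    short <- sc$y
    cc$sc <- sc$cache
  } else short <- x
  t2 <- tanh_f(b2$y + short)
  out <- t2$y
  if (has_attn) {
    at <- mha_f(net, paste0(p, ".attn"), x, out, x, heads, keep)
    out <- out + at$y
    cc$at <- at$cache
  }
  cc$c1 <- c1$cache; cc$b1 <- b1$cache; cc$t1 <- t1$cache
  cc$c2 <- c2$cache; cc$b2 <- b2$cache; cc$t2 <- t2$cache
  list(y = out, cache = cc)
}

block_b <- function(net, p, cache, dy, has_shortcut, has_attn, heads, G) {
  dx_extra <- NULL
  if (has_attn) {
    da <- mha_b(net, paste0(p, ".attn"), heads, cache$at, dy, G)
    dout <- dy + da$dxk          # key was the block output
    dx_extra <- da$dxq + da$dxv  # query and value were the block input
  } else dout <- dy
  dadd <- tanh_b(cache$t2, dout)
  db2 <- bn_b(net, paste0(p, ".bn2"), cache$b2, dadd, G)
  dt1 <- conv_b(net, paste0(p, ".conv2"), net$specs[[paste0(p, ".conv2")]],
                cache$c2, db2, G)
  db1 <- tanh_b(cache$t1, dt1)
  dc1 <- bn_b(net, paste0(p, ".bn1"), cache$b1, db1, G)
  dx <- conv_b(net, paste0(p, ".conv1"), net$specs[[paste0(p, ".conv1")]],
               cache$c1, dc1, G)
  if (has_shortcut) {
    dx <- dx + conv_b(net, paste0(p, ".shortcut"),
                      net$specs[[paste0(p, ".shortcut")]], cache$sc, dadd, G)
  } else dx <- dx + dadd
  if (!is.null(dx_extra)) dx <- dx + dx_extra
  dx
}

net_forward <- function(net, x, training = FALSE, keep = FALSE) {
  arch <- net$arch
  caches <- list()
  st <- conv_f(net, "stem.conv", net$specs[["stem.conv"]], x, keep)
  sb <- bn_f(net, "stem.bn", st$y, training)
  stt <- tanh_f(sb$y)
  caches$stem <- list(conv = st$cache, bn = sb$cache, tanh = stt$cache)
  h <- stt$y
  for (s in seq_along(arch$stage_channels)) {
    for (b in seq_len(arch$blocks_per_stage)) {
      p <- stage_prefix(s, b)
      has_short <- s > 1L && b == 1L
      has_attn <- arch$attention_enabled && b == arch$blocks_per_stage
      bl <- block_f(net, p, h, has_short, has_attn, arch$attention_heads,
                    training, keep)
      caches[[p]] <- bl$cache
      h <- bl$y
    }
  }
  gp <- gap_f(h)
  dn <- dense_f(net, "head", gp$y)
  ls <- logsoftmax_f(dn$y)
  caches$head <- list(gap = gp$cache, dense = dn$cache, lsm = ls$cache)
  list(logp = ls$y, caches = if (keep) caches)
}

net_backward <- function(net, caches, dlogp) {
  arch <- net$arch
  G <- new.env(parent = emptyenv())
  dz <- logsoftmax_b(caches$head$lsm, dlogp)
  dg <- dense_b(net, "head", caches$head$dense, dz, G)
  dh <- gap_b(caches$head$gap, dg)
  for (s in rev(seq_along(arch$stage_channels))) {
    for (b in rev(seq_len(arch$blocks_per_stage))) {
      p <- stage_prefix(s, b)
      has_short <- s > 1L && b == 1L
      has_attn <- arch$attention_enabled && b == arch$blocks_per_stage
      dh <- block_b(net, p, caches[[p]], dh, has_short, has_attn,
                    arch$attention_heads, G)
    }
  }
  dst <- tanh_b(caches$stem$tanh, dh)
  dsb <- bn_b(net, "stem.bn", caches$stem$bn, dst, G)
  conv_b(net, "stem.conv", net$specs[["stem.conv"]], caches$stem$conv, dsb, G)
  as.list(G)
}

#' Structural summary of a built network
#'
#' Counts are obtained by walking the parameter graph: operational layers on
#' the main path (stem + residual convolutions), shortcut projections,
#' attention layers, weighted layers on the main path (operational layers
#' plus the final dense classifier) and total learnable parameters.
#'
#' @param network a `selfonn_net`.
#' @return An object of class `network_summary`.
#' @export
summarize_network <- function(network) {
  stopifnot(inherits(network, "selfonn_net"))
  nm <- names(network$specs)
  main <- nm[!grepl("\\.shortcut$", nm)]
  n_short <- sum(grepl("\\.shortcut$", nm))
  n_attn <- sum(grepl("\\.attn\\.Wq$", names(network$params)))
  total <- sum(vapply(network$params, length, integer(1)))
  structure(list(n_selfonn_layers_main_path = length(main),
                 n_shortcut_projections = n_short,
                 n_attention_layers = n_attn,
                 n_weighted_layers_main_path = length(main) + 1L,
                 total_parameters = total),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("Network summary\n")
  cat(sprintf("  operational layers (main path): %d\n", x$n_selfonn_layers_main_path))
  cat(sprintf("  weighted layers (main path):    %d\n", x$n_weighted_layers_main_path))
  cat(sprintf("  shortcut projections:           %d\n", x$n_shortcut_projections))
  cat(sprintf("  attention layers:               %d\n", x$n_attention_layers))
  cat(sprintf("  learnable parameters:           %d\n", x$total_parameters))
  invisible(x)
}

#' @export
print.selfonn_net <- function(x, ...) {
  a <- x$arch
  cat(sprintf("%s (Q = %d)\n",
              if (a$attention_enabled) "Self-ResAttentioNet18" else "Self-ResNet18",
              a$taylor_order))
  cat(sprintf("  stages: %s channels, %d blocks each, input length %d, %d classes\n",
              paste(a$stage_channels, collapse = "/"), a$blocks_per_stage,
              a$input_length, a$n_classes))
  print(summarize_network(x))
  invisible(x)
}

#' @export
summary.selfonn_net <- function(object, ...) summarize_network(object)

#' @export
coef.selfonn_net <- function(object, ...) object$params

#' Forward pass of a Self-ONN network
#'
#' @param object a `selfonn_net`.
#' @param x input segments: numeric vector (one segment), matrix
#'   (segments in rows), or (1, length, batch) array.
#' @param type `"log_prob"` (log-softmax outputs), `"prob"`, or `"class"`
#'   (argmax class index, 0-based to match the Healthy = 0 / ICU = 1
#'   labelling convention).
#' @param batch_size evaluation mini-batch size.
#' @param ... unused.
#' @return A matrix (samples x classes) of log-probabilities or
#'   probabilities, or an integer vector of class indices.
#' @export
predict.selfonn_net <- function(object, x, type = c("log_prob", "prob", "class"),
                                batch_size = 64L, ...) {
  type <- match.arg(type)
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (is.matrix(x)) x <- array(t(x), dim = c(1L, ncol(x), nrow(x)))
  B <- dim(x)[3L]
  out <- matrix(NA_real_, B, object$arch$n_classes)
  handle <- cpp_net_create(unclass(object$arch))
  for (start in seq(1L, B, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, B)
    lp <- cpp_net_forward_h(handle, object$params, object$buffers,
                            x[, , idx, drop = FALSE], FALSE)
    out[idx, ] <- t(lp)
  }
  switch(type,
         log_prob = out,
         prob = exp(out),
         class = max.col(out, ties.method = "first") - 1L)
}
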