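test_that("architecture spec validates its invariants", {
  expect_s3_class(architecture_spec(), "architecture_spec")
  expect_error(architecture_spec(stage_channels = c(8, 12, 24, 48)), "double")
  expect_error(architecture_spec(stem_channels = 4), "double")
  expect_error(architecture_spec(taylor_order = 0), "taylor_order")
  expect_error(architecture_spec(attention_enabled = TRUE, attention_heads = 3),
               "divisible")
  expect_error(build_self_resnet18(architecture_spec(attention_enabled = TRUE)),
               "attention")
})

test_that("Self-ResNet18 carries 18 weighted layers on the main path", {
  net <- build_self_resnet18(architecture_spec(), seed = 1)
  s <- summarize_network(net)
  expect_equal(s$n_selfonn_layers_main_path, 17L)
  expect_equal(s$n_weighted_layers_main_path, 18L)
  expect_equal(s$n_shortcut_projections, 3L)
  expect_equal(s$n_attention_layers, 0L)
})

test_that("Self-ResAttentioNet18 adds exactly four attention layers of two heads", {
  net <- build_self_resattentionet18(seed = 1)
  s <- summarize_network(net)
  expect_equal(s$n_attention_layers, 4L)
  expect_equal(s$n_weighted_layers_main_path, 18L)
  expect_equal(s$n_shortcut_projections, 3L)
  expect_equal(net$arch$attention_heads, 2L)
  # layer counts are invariant to the Taylor order
  s5 <- summarize_network(build_self_resattentionet18(
    architecture_spec(taylor_order = 5, attention_enabled = TRUE), seed = 1))
  expect_equal(s5[c(1, 2, 3, 4)], s[c(1, 2, 3, 4)])
})

test_that("stage channel widths double from 8 to 64 in the default build", {
  net <- build_self_resnet18(seed = 1)
  och <- vapply(net$specs, function(s) s$out_channels, integer(1))
  expect_equal(och[["stem.conv"]], 8L)
  expect_equal(unname(och[paste0("s", 1:4, ".b2.conv2")]), c(8L, 16L, 32L, 64L))
  expect_equal(nrow(net$params$head.W), 2L)
  expect_equal(ncol(net$params$head.W), 64L)
})

test_that("outputs are normalized log-probabilities", {
  net <- build_self_resattentionet18(seed = 2)
  x <- matrix(rnorm(2 * 1024, sd = 0.5), nrow = 2)
  lp <- predict(net, x, type = "log_prob")
  expect_equal(dim(lp), c(2L, 2L))
  expect_equal(rowSums(exp(lp)), c(1, 1), tolerance = 1e-6)
  # deterministic forward
  expect_identical(lp, predict(net, x, type = "log_prob"))
  cls <- predict(net, x, type = "class")
  expect_true(all(cls %in% 0:1))
})

test_that("kernel-weight count grows linearly in Q across the whole network", {
  n_kernel_weights <- function(net)
    sum(vapply(names(net$params)[grepl("\\.W$", names(net$params)) &
                                 !grepl("head", names(net$params))],
               function(nm) length(net$params[[nm]]), integer(1)))
  net1 <- build_self_resnet18(architecture_spec(taylor_order = 1), seed = 1)
  net3 <- build_self_resnet18(architecture_spec(taylor_order = 3), seed = 1)
  s1 <- summarize_network(net1)$total_parameters
  s3 <- summarize_network(net3)$total_parameters
  expect_equal(s3 - s1, 2L * n_kernel_weights(net1))
})

test_that("zeroed attention projections recover the plain residual network", {
  arch <- architecture_spec(taylor_order = 1)
  base <- build_self_resnet18(arch, seed = 9)
  archA <- arch; archA$attention_enabled <- TRUE
  attn <- build_self_resattentionet18(archA, seed = 9)
  for (nm in names(base$params)) attn$params[[nm]] <- base$params[[nm]]
  for (nm in grep("\\.attn\\.", names(attn$params), value = TRUE))
    attn$params[[nm]][] <- 0
  x <- matrix(rnorm(3 * 1024, sd = 0.5), nrow = 3)
  expect_lt(max(abs(predict(base, x) - predict(attn, x))), 1e-5)
})

test_that("attention block computes convex combinations of the value tokens", {
  set.seed(4)
  ident <- matrix(rnorm(8 * 16), 8, 16)
  blk <- matrix(rnorm(8 * 16), 8, 16)
  res <- attention_block_forward(ident, blk, heads = 2, return_weights = TRUE)
  expect_equal(dim(res$y), dim(ident))
  # each query position's weights sum to 1 (weights are key x query)
  expect_equal(dim(res$weights), c(16L, 16L, 2L))
  expect_equal(as.numeric(apply(res$weights, c(2, 3), sum)),
               rep(1, 32), tolerance = 1e-6)
  # zero key: uniform weights 1/T
  resz <- attention_block_forward(ident, blk * 0, heads = 2,
                                  return_weights = TRUE)
  expect_equal(as.numeric(resz$weights), rep(1 / 16, 16 * 16 * 2),
               tolerance = 1e-6)
  # identity projections + constant value vector v: output v at every position
  v <- rnorm(8)
  resv <- attention_block_forward(matrix(v, 8, 16), blk, heads = 2)
  expect_equal(resv, matrix(v, 8, 16), tolerance = 1e-8)
  expect_error(attention_block_forward(ident, blk[, 1:8]), "shape")
  expect_error(attention_block_forward(ident, blk, heads = 3), "divisible")
})

test_that("head splitting gives channels/heads dimensions per head", {
  ident <- matrix(rnorm(8 * 12), 8, 12)
  ns <- selfonn_ns
  res <- ns$cpp_mha_fwd(array(ident, c(8, 12, 1)), array(ident, c(8, 12, 1)),
                        array(ident, c(8, 12, 1)), diag(8), diag(8), diag(8),
                        diag(8), 2L, TRUE)
  expect_equal(dim(res$A), c(12L, 12L, 2L))     # one weight matrix per head
  expect_equal(dim(res$Qp), c(8L, 12L, 1L))     # 2 heads x 4 channels each
})
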