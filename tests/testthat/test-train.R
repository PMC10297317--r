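test_that("SoftM_MSE loss matches hand arithmetic and its contract", {
  expect_equal(softm_mse_loss(log(c(1 - 1e-12, 1e-12)), 0), 0, tolerance = 1e-9)
  expect_equal(softm_mse_loss(log(c(0.5, 0.5)), 0), 0.25)
  expect_equal(softm_mse_loss(log(c(1e-12, 1 - 1e-12)), 0), 1, tolerance = 1e-9)
  lp <- log(matrix(c(0.5, 0.5, 0.2, 0.8), 2))
  expect_equal(softm_mse_loss(lp, c(0, 1)), (0.25 + mean(c(0.2^2, 0.2^2))) / 2)
  expect_error(softm_mse_loss(log(c(0.5, 0.4)), 0), "normalized")
  expect_error(softm_mse_loss(log(c(0.5, 0.5)), 2), "range")
  # bounded in [0, 1] for two classes, zero only at perfect one-hot
  set.seed(60)
  for (i in 1:50) {
    p <- runif(1, 1e-6, 1 - 1e-6)
    l <- softm_mse_loss(log(c(p, 1 - p)), sample(0:1, 1))
    expect_gte(l, 0); expect_lte(l, 1)
    if (l == 0) expect_true(p %in% c(0, 1))
  }
})

test_that("train config mirrors the study hyperparameters and validates", {
  cfg <- train_config()
  expect_equal(cfg$n_folds, 5L)
  expect_equal(cfg$batch_size, 4L)
  expect_equal(cfg$n_epochs, 100L)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$epoch_patience, 7L)
  expect_equal(cfg$learning_factor, 0.2)
  expect_equal(cfg$loss, "SoftM_MSE")
  expect_equal(cfg$optimizer, "Adam")
  expect_error(train_config(learning_factor = 1.2), "learning_factor")
  expect_error(train_config(loss = "crossentropy"), "unsupported")
})

# A small separable training problem shared by the tests below.
small_problem <- function(seed = 70) {
  set.seed(seed)
  n <- 60
  t <- seq(0, 1023) / 217
  segs <- t(vapply(seq_len(n), function(i) {
    cls <- i %% 2L
    base <- if (cls == 0) 60 + 25 * sin(2 * pi * 1.2 * t) else
      35 + 45 * abs(sin(pi * 1.8 * t))
    base + rnorm(1024, sd = 2)
  }, numeric(1024)))
  list(x = segs, y = seq_len(n) %% 2L,
       sessions = sprintf("s%d", rep(1:6, length.out = n)))
}

test_that("training learns a separable problem deterministically", {
  prob <- small_problem()
  arch <- architecture_spec(taylor_order = 1, input_length = 1024)
  cfg <- train_config(n_epochs = 4, seed = 5)
  fit1 <- train_fold(build_self_resnet18(arch, seed = 5), prob$x, prob$y,
                     prob$sessions, cfg)
  expect_s3_class(fit1, "selfonn_fit")
  h <- fit1$history
  expect_equal(nrow(h), 4)
  expect_lt(h$train_loss[4], h$train_loss[1])
  # identical seed, identical everything
  fit2 <- train_fold(build_self_resnet18(arch, seed = 5), prob$x, prob$y,
                     prob$sessions, cfg)
  expect_equal(fit1$history, fit2$history)
  expect_equal(fit1$network$params, fit2$network$params)
  # standardization recorded from the training split
  expect_true(is.finite(fit1$standardize$mean) && fit1$standardize$sd > 0)
})

test_that("the plateau schedule multiplies the learning rate by 0.2", {
  prob <- small_problem(71)
  arch <- architecture_spec(taylor_order = 1)
  cfg <- train_config(n_epochs = 8, epoch_patience = 2, seed = 6)
  fit <- train_fold(build_self_resnet18(arch, seed = 6), prob$x, prob$y,
                    prob$sessions, cfg)
  lr <- fit$history$lr
  expect_true(all(diff(lr) <= 0))
  drops <- lr[-1][diff(lr) < 0] / lr[-length(lr)][diff(lr) < 0]
  if (length(drops) > 0) expect_equal(drops, rep(0.2, length(drops)))
})

test_that("training rejects degenerate inputs", {
  prob <- small_problem(72)
  arch <- architecture_spec(taylor_order = 1)
  net <- build_self_resnet18(arch, seed = 1)
  bad <- prob$x; bad[1, 1] <- NaN
  expect_error(train_fold(net, bad, prob$y, config = train_config()),
               "NaN-free")
  expect_error(train_fold(net, prob$x[1, , drop = FALSE], 0L), "two rows")
  expect_error(train_fold(net, prob$x, prob$y[-1]), "label")
})

test_that("fold evaluation assembles a conserving report", {
  prob <- small_problem(73)
  arch <- architecture_spec(taylor_order = 1)
  fit <- train_fold(build_self_resnet18(arch, seed = 7), prob$x, prob$y,
                    prob$sessions, train_config(n_epochs = 3, seed = 7))
  test_prob <- small_problem(99)
  rep_ <- evaluate_fold(fit, test_prob$x, test_prob$y)
  expect_s3_class(rep_, "classification_report")
  cc <- rep_$counts[["1"]]
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, nrow(test_prob$x))
  expect_equal(rep_$weighted_recall, rep_$overall_accuracy)
  expect_error(evaluate_fold(fit, prob$x[0, , drop = FALSE], integer(0)),
               "non-empty")
})
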