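test_that("parameter count matches layer-shape enumeration, incl. the reference shape", {
  cfg <- model_config()
  # single linear 2 -> 3 with bias, no hidden layers' batch norm involved
  tiny <- build_network(model_config(hidden_sizes = integer(0), batch_norm = FALSE),
                        2, 3)
  expect_identical(parameter_count(tiny), 9L)

  net <- build_network(cfg, 576L, 1820L)
  oracle <- enumerate_parameters(576, c(512, 512, 1024, 1024), 1820, batch_norm = TRUE)
  expect_identical(parameter_count(net), as.integer(oracle))
  expect_equal(round(parameter_count(net) / 1e6, 1), 4.0)

  # d_genes = 1 gives a single output node
  one <- build_network(model_config(hidden_sizes = c(8L), seed = 1), 4, 1)
  expect_equal(ncol(one$out$W), 1)
})

test_that("class weights follow the expressed/silent rule", {
  expect_equal(regression_weights(rep(0, 4)), rep(1, 4))
  expect_equal(regression_weights(c(0, 2, 0.1)), c(1, 5, 5))
  expect_equal(regression_weights(c(0, 1), w_pos = 2, w_neg = 2), c(2, 2))
  expect_error(regression_weights(c(-1, 0)), "non-negative")
})

test_that("loss identities hold", {
  y <- c(0, 1, 2); w <- regression_weights(y)
  # perfect fit
  expect_equal(loss_regression(y, y, w), 0)
  # single positive gene, y = 1, prediction 0, default weights: 5 * (0 - 1)^2
  expect_equal(loss_regression(0, 1, regression_weights(1)), 5)
  # unweighted limit equals d x mean squared error
  withr::with_seed(30, {
    yh <- matrix(runif(40), 8, 5); yy <- matrix(runif(40), 8, 5)
    w1 <- matrix(1, 8, 5)
    expect_equal(loss_regression(yh, yy, w1), 5 * mean((yh - yy)^2))
  })
  # maximum-entropy point of the unweighted binary loss
  expect_equal(loss_binary(rep(0, 6), rep(c(TRUE, FALSE), 3), rep(1, 6)), log(2))
  # separable limit: large correct logits drive the loss to 0
  b <- c(TRUE, FALSE, TRUE)
  big <- c(50, -50, 50)
  expect_lt(loss_binary(big, b, regression_weights(b * 1)), 1e-20)
  expect_gt(loss_binary(big / 10, b, regression_weights(b * 1)),
            loss_binary(big, b, regression_weights(b * 1)))
  # hand-computed 2-gene case
  lg <- c(0.5, -1); bb <- c(TRUE, FALSE); ww <- c(5, 1)
  manual <- mean(ww * c(log(1 + exp(-0.5)), log(1 + exp(-1))) * c(1, 1))
  expect_equal(loss_binary(lg, bb, ww), manual)
})

test_that("total loss is linear in the lambdas and reduces under ablation", {
  withr::with_seed(31, {
    yh <- matrix(rnorm(30), 6, 5)
    y <- matrix(rpois(30, 1) * runif(30), 6, 5)
    cfg0 <- model_config(lambda_bin = 0)
    w <- regression_weights(y)
    expect_equal(loss_total(yh, y, cfg = cfg0), 1 * loss_regression(yh, y, w))
    c12 <- model_config(lambda_reg = 2, lambda_bin = 3)
    expect_equal(loss_total(yh, y, cfg = c12),
                 2 * loss_regression(yh, y, w) +
                   3 * loss_binary(yh, y > 0, w))
  })
})

test_that("backpropagation matches finite-difference gradients", {
  withr::with_seed(32, {
    cfg <- model_config(hidden_sizes = c(4L, 3L), dropout = 0, seed = 5)
    net <- build_network(cfg, 5, 2)
    X <- matrix(rnorm(30), 6, 5)
    y <- matrix(rpois(12, 1) * runif(12), 6, 2)
    b <- (y > 0) * 1
    w <- regression_weights(y, cfg$w_pos, cfg$w_neg)
    loss_of <- function(nn) {
      fw <- staincast:::mlp_forward(nn, X, training = TRUE)
      cfg$lambda_reg * loss_regression(fw$out, y, w) +
        cfg$lambda_bin * loss_binary(fw$out, b, w)
    }
    fw <- staincast:::mlp_forward(net, X, training = TRUE)
    G <- staincast:::loss_gradient(fw$out, y, b, w, cfg)
    grads <- staincast:::mlp_backward(net, fw, G)
    eps <- 1e-5
    check <- function(path_get, path_set, g, label) {
      for (i in sample(length(g), min(5, length(g)))) {
        plus <- path_set(net, `[<-`(path_get(net), i, path_get(net)[i] + eps))
        minus <- path_set(net, `[<-`(path_get(net), i, path_get(net)[i] - eps))
        num <- (loss_of(plus) - loss_of(minus)) / (2 * eps)
        expect_lt(abs(g[i] - num), 1e-6 + 1e-4 * abs(num))
      }
    }
    check(function(n) n$out$W, function(n, p) {n$out$W <- p; n},
          grads$out$W, "out W")
    check(function(n) n$hidden[[1]]$W, function(n, p) {n$hidden[[1]]$W <- p; n},
          grads$hidden[[1]]$W, "h1 W")
    check(function(n) n$hidden[[2]]$gamma, function(n, p) {n$hidden[[2]]$gamma <- p; n},
          grads$hidden[[2]]$gamma, "h2 gamma")
    check(function(n) n$hidden[[2]]$b, function(n, p) {n$hidden[[2]]$b <- p; n},
          grads$hidden[[2]]$b, "h2 b")
  })
})

fit_fixture <- function(seed = 40, n = 150, d = 6, in_dim = 12) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * in_dim), n, in_dim)
    W <- matrix(rnorm(in_dim * d), in_dim, d)
    y <- pmax(X %*% W * 0.4 + rnorm(n * d, 0, 0.2), 0)
    list(X = X, y = y)
  })
}

test_that("training learns, logs, and is deterministic under a fixed seed", {
  fx <- fit_fixture()
  cfg <- model_config(hidden_sizes = c(16L, 16L), batch_size = 64L,
                      max_epochs = 25L, seed = 2)
  m <- fit(fx$X, fx$y, cfg = cfg)
  expect_lt(m$log$train_loss[nrow(m$log)], m$log$train_loss[1])
  m2 <- fit(fx$X, fx$y, cfg = cfg)
  expect_identical(m$log, m2$log)
  expect_identical(m$net, m2$net)
  # early stopping contract: returned validation loss is the log minimum
  expect_equal(m$best_val_loss, min(m$log$val_loss))
  expect_equal(m$log$val_loss[m$best_epoch], min(m$log$val_loss))
})

test_that("a cell count below two batches trains full-batch with a warning", {
  fx <- fit_fixture(n = 40)
  cfg <- model_config(hidden_sizes = c(8L), batch_size = 256L,
                      max_epochs = 3L, seed = 1)
  expect_warning(fit(fx$X, fx$y, cfg = cfg), "full-batch")
})

test_that("unweighted, regression-only training loss is plain summed squared error", {
  fx <- fit_fixture(n = 60, d = 3)
  cfg <- model_config(hidden_sizes = c(8L), batch_size = 1000L, max_epochs = 2L,
                      w_pos = 1, w_neg = 1, lambda_bin = 0, dropout = 0, seed = 9)
  suppressWarnings(m <- fit(fx$X, fx$y, cfg = cfg))
  expect_true(all(is.finite(m$log$train_loss)))
  # in this limit the total loss equals the per-cell summed squared error
  yh <- matrix(rnorm(12), 4, 3); yy <- matrix(abs(rnorm(12)), 4, 3)
  expect_equal(loss_total(yh, yy, cfg = cfg),
               mean(rowSums((yh - yy)^2)))
})

test_that("prediction clips at zero, is batch-invariant and validates dims", {
  fx <- fit_fixture(n = 80, d = 4)
  cfg <- model_config(hidden_sizes = c(8L), batch_size = 32L, max_epochs = 5L, seed = 3)
  m <- fit(fx$X, fx$y, cfg = cfg)
  pred <- predict_cells(m, fx$X)
  expect_true(all(pred$y_hat >= 0))
  expect_true(all(pred$p_expressed > 0 & pred$p_expressed < 1))
  # batch-of-1 equals the corresponding row of the full batch
  p1 <- predict_cells(m, fx$X[3, , drop = FALSE])
  expect_equal(unname(p1$y_hat[1, ]), unname(pred$y_hat[3, ]), tolerance = 1e-5)
  # identical feature rows map to identical outputs (constant map)
  z2 <- predict_cells(m, matrix(0, 2, ncol(fx$X)))
  expect_equal(z2$y_hat[1, ], z2$y_hat[2, ])
  expect_error(predict_cells(m, fx$X[, 1:5]), "input_dim")
})
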