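#' Configuration of the dual-loss weighted regressor
#'
#' Defaults are the tuned training regime of the method: four hidden layers
#' (512, 512, 1024, 1024), leaky-ReLU (slope 0.01) followed by batch
#' normalization and dropout 0.1 per hidden block, a single linear output
#' with one node per panel gene read by both losses (regression directly,
#' classification through a sigmoid), class weights `w_pos = 5` / `w_neg = 1`
#' on expressed/silent entries, loss mix `lambda_reg = 1`, `lambda_bin = 20`,
#' AdamW with learning rate 0.01 and weight decay 0.05, batch size 256, up
#' to 100 epochs with early stopping after 10 non-improving validation
#' epochs on a seeded 10% validation split.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param leaky_slope Negative-side slope of the leaky rectifier.
#' @param batch_norm Whether hidden blocks carry batch normalization.
#' @param w_pos,w_neg Class weights for expressed (`y > 0`) and silent
#'   entries; must satisfy `w_pos > w_neg > 0`... except in the deliberate
#'   unweighted limit `w_pos == w_neg`, which is allowed for ablations.
#' @param lambda_reg,lambda_bin Mixing weights of the regression and
#'   binary-classification losses.
#' @param lr,weight_decay AdamW learning rate and decoupled weight decay.
#' @param batch_size,max_epochs,early_stop_patience,val_fraction Training
#'   loop controls.
#' @param seed Integer seed governing initialization, the validation split,
#'   shuffling and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(hidden_sizes = c(512L, 512L, 1024L, 1024L),
                         dropout = 0.1, leaky_slope = 0.01, batch_norm = TRUE,
                         w_pos = 5, w_neg = 1,
                         lambda_reg = 1, lambda_bin = 20,
                         lr = 0.01, weight_decay = 0.05,
                         batch_size = 256L, max_epochs = 100L,
                         early_stop_patience = 10L, val_fraction = 0.1,
                         seed = 1L) {
  cfg <- list(hidden_sizes = as.integer(hidden_sizes), dropout = dropout,
              leaky_slope = leaky_slope, batch_norm = isTRUE(batch_norm),
              w_pos = w_pos, w_neg = w_neg,
              lambda_reg = lambda_reg, lambda_bin = lambda_bin,
              lr = lr, weight_decay = weight_decay,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              early_stop_patience = as.integer(early_stop_patience),
              val_fraction = val_fraction, seed = as.integer(seed))
  if (!(cfg$w_pos >= cfg$w_neg && cfg$w_neg > 0))
    abort("class weights must satisfy w_pos >= w_neg > 0")
  if (cfg$dropout < 0 || cfg$dropout >= 1) abort("dropout must be in [0, 1)")
  if (cfg$lr <= 0 || cfg$batch_size < 1 || cfg$max_epochs < 1)
    abort("rates and sizes must be positive")
  if (cfg$val_fraction <= 0 || cfg$val_fraction >= 1)
    abort("val_fraction must be in (0, 1)")
  structure(cfg, class = "model_config")
}

#' Build the feed-forward network
#'
#' Layers: for each hidden width `h`, `linear -> leaky-ReLU -> batch-norm ->
#' dropout`; then a final linear layer with `d_genes` output nodes and no
#' activation. Weights and biases are initialized uniformly in
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]` from the config seed; batch-norm
#' scale/shift start at 1/0.
#'
#' @param cfg A [model_config()].
#' @param input_dim Feature dimension (e.g. 576).
#' @param d_genes Number of output genes.
#' @return An `sc_network` list of layer parameter sets.
#' @export
build_network <- function(cfg, input_dim, d_genes) {
  stopifnot(inherits(cfg, "model_config"), input_dim >= 1, d_genes >= 1)
  widths <- c(input_dim, cfg$hidden_sizes)
  withr::with_seed(cfg$seed, {
    layers <- purrr::map(seq_along(cfg$hidden_sizes), function(l) {
      fan_in <- widths[l]; fan_out <- widths[l + 1]
      k <- 1 / sqrt(fan_in)
      lay <- list(W = matrix(runif(fan_in * fan_out, -k, k), fan_in, fan_out),
                  b = runif(fan_out, -k, k))
      if (cfg$batch_norm) {
        lay$gamma <- rep(1, fan_out); lay$beta <- rep(0, fan_out)
        lay$run_mean <- rep(0, fan_out); lay$run_var <- rep(1, fan_out)
      }
      lay
    })
    k <- 1 / sqrt(tail(widths, 1))
    out <- list(W = matrix(runif(tail(widths, 1) * d_genes, -k, k),
                           tail(widths, 1), d_genes),
                b = runif(d_genes, -k, k))
    structure(list(hidden = layers, out = out, input_dim = as.integer(input_dim),
                   d_genes = as.integer(d_genes), leaky_slope = cfg$leaky_slope,
                   dropout = cfg$dropout, batch_norm = cfg$batch_norm),
              class = "sc_network")
  })
}

#' Count trainable parameters
#'
#' Sums element counts of all trainable tensors: linear weights and biases
#' plus batch-norm scale and shift (running statistics are buffers, not
#' parameters). Accepts a network or a fitted model.
#'
#' @param model An `sc_network` or `trained_model`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(model) {
  net <- if (inherits(model, "trained_model")) model$net else model
  stopifnot(inherits(net, "sc_network"))
  n <- sum(purrr::map_int(net$hidden, function(l)
    length(l$W) + length(l$b) +
      (if (!is.null(l$gamma)) length(l$gamma) + length(l$beta) else 0L)))
  n + length(net$out$W) + length(net$out$b)
}

leaky <- function(x, slope) ifelse(x > 0, x, slope * x)

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# forward pass; training = TRUE uses batch statistics, updates running stats
# and applies inverted dropout with the masks provided in `masks`
mlp_forward <- function(net, X, training = FALSE, masks = NULL) {
  cache <- list()
  H <- X
  for (l in seq_along(net$hidden)) {
    lay <- net$hidden[[l]]
    lin <- sweep(H %*% lay$W, 2, lay$b, "+")
    act <- leaky(lin, net$leaky_slope)
    if (net$batch_norm) {
      if (training) {
        mu <- colMeans(act)
        v <- colMeans(sweep(act, 2, mu)^2)            # biased batch variance
        net$hidden[[l]]$run_mean <- (1 - BN_MOMENTUM) * lay$run_mean + BN_MOMENTUM * mu
        net$hidden[[l]]$run_var <- (1 - BN_MOMENTUM) * lay$run_var + BN_MOMENTUM * v
      } else {
        mu <- lay$run_mean; v <- lay$run_var
      }
      xhat <- sweep(sweep(act, 2, mu), 2, sqrt(v + BN_EPS), "/")
      bn <- sweep(sweep(xhat, 2, lay$gamma, "*"), 2, lay$beta, "+")
    } else {
      xhat <- NULL; mu <- NULL; v <- NULL; bn <- act
    }
    if (training && net$dropout > 0) {
      drop <- bn * masks[[l]] / (1 - net$dropout)
    } else {
      drop <- bn
    }
    cache[[l]] <- list(input = H, lin = lin, act = act, xhat = xhat,
                       mu = mu, v = v, bn = bn)
    H <- drop
  }
  out <- sweep(H %*% net$out$W, 2, net$out$b, "+")
  list(net = net, out = out, top = H, cache = cache)
}

# backward pass from dL/d(logits); returns gradients in the layer structure
mlp_backward <- function(net, fw, G, masks = NULL) {
  B <- nrow(G)
  grads <- list(out = list(W = crossprod(fw$top, G), b = colSums(G)),
                hidden = vector("list", length(net$hidden)))
  dH <- G %*% t(net$out$W)
  for (l in rev(seq_along(net$hidden))) {
    lay <- net$hidden[[l]]
    cc <- fw$cache[[l]]
    if (net$dropout > 0 && !is.null(masks))
      dH <- dH * masks[[l]] / (1 - net$dropout)
    if (net$batch_norm) {
      dgamma <- colSums(dH * cc$xhat)
      dbeta <- colSums(dH)
      inv_sd <- 1 / sqrt(cc$v + BN_EPS)
      dxhat <- sweep(dH, 2, lay$gamma, "*")
      da <- sweep(dxhat -
                    matrix(colMeans(dxhat), B, ncol(dxhat), byrow = TRUE) -
                    cc$xhat * matrix(colMeans(dxhat * cc$xhat), B, ncol(dxhat), byrow = TRUE),
                  2, inv_sd, "*")
    } else {
      dgamma <- NULL; dbeta <- NULL
      da <- dH
    }
    dlin <- da * ifelse(cc$lin > 0, 1, net$leaky_slope)
    grads$hidden[[l]] <- list(W = crossprod(cc$input, dlin), b = colSums(dlin),
                              gamma = dgamma, beta = dbeta)
    dH <- dlin %*% t(lay$W)
  }
  grads
}

#' Per-entry class weights for the dual loss
#'
#' `w_i = w_pos` where the target is expressed (`y_i > 0`), `w_neg` where it
#' is silent. Works elementwise on vectors or matrices.
#'
#' @param y Non-negative targets.
#' @param w_pos,w_neg Class weights (defaults 5 and 1).
#' @return Numeric weights, same shape as `y`.
#' @export
regression_weights <- function(y, w_pos = 5, w_neg = 1) {
  if (any(y < 0)) abort("targets must be non-negative")
  w <- ifelse(y > 0, w_pos, w_neg)
  if (is.matrix(y)) w <- matrix(w, nrow(y), ncol(y))
  w
}

as_row <- function(x) if (is.matrix(x)) x else matrix(x, 1)

#' Weighted regression loss
#'
#' Per cell, the class-weighted summed squared error over genes,
#' `sum_i w_i (yhat_i - y_i)^2`, averaged over the batch.
#'
#' @param y_hat,y Predicted and observed expression (vectors or cells x
#'   genes matrices of equal shape).
#' @param w Per-entry weights from [regression_weights()].
#' @return Scalar loss.
#' @export
loss_regression <- function(y_hat, y, w) {
  y_hat <- as_row(y_hat); y <- as_row(y); w <- as_row(w)
  stopifnot(identical(dim(y_hat), dim(y)), identical(dim(y), dim(w)))
  mean(rowSums(w * (y_hat - y)^2))
}

#' Weighted binary classification loss
#'
#' Sigmoid cross-entropy on the shared output read as logits, weighted by
#' the same per-entry class weights as the regression loss, averaged over
#' genes and then over the batch. Computed in the numerically stable
#' logits form.
#'
#' @param logits Raw network outputs.
#' @param b Logical (or 0/1) expressed labels, same shape.
#' @param w Per-entry weights.
#' @return Scalar loss.
#' @export
loss_binary <- function(logits, b, w) {
  logits <- as_row(logits); b <- as_row(b * 1); w <- as_row(w)
  stopifnot(identical(dim(logits), dim(b)), identical(dim(b), dim(w)))
  bce <- pmax(logits, 0) - logits * b + log1p(exp(-abs(logits)))
  mean(rowMeans(w * bce))
}

#' Total training loss
#'
#' `lambda_reg * L_reg + lambda_bin * L_bin`, both losses reading the same
#' shared output vector: the regression loss directly, the classification
#' loss through a sigmoid.
#'
#' @param y_hat Raw network outputs (also the regression predictions).
#' @param y Observed normalized expression.
#' @param b Expressed labels (defaults to `y > 0`).
#' @param cfg A [model_config()] supplying weights and lambdas.
#' @return Scalar loss.
#' @export
loss_total <- function(y_hat, y, b = y > 0, cfg = model_config()) {
  w <- regression_weights(y, cfg$w_pos, cfg$w_neg)
  cfg$lambda_reg * loss_regression(y_hat, y, w) +
    cfg$lambda_bin * loss_binary(y_hat, b, w)
}

# dL/d(logits) matching loss_total under mean-over-batch reductions
loss_gradient <- function(out, y, b, w, cfg) {
  B <- nrow(out); d <- ncol(out)
  cfg$lambda_reg * 2 * w * (out - y) / B +
    cfg$lambda_bin * w * (sigmoid(out) - b) / (d * B)
}

adamw_state <- function(net) {
  list(m = rapply(list(hidden = lapply(net$hidden, function(l)
         l[intersect(names(l), c("W", "b", "gamma", "beta"))]),
         out = net$out), function(x) x * 0, how = "replace"),
       v = rapply(list(hidden = lapply(net$hidden, function(l)
         l[intersect(names(l), c("W", "b", "gamma", "beta"))]),
         out = net$out), function(x) x * 0, how = "replace"),
       t = 0)
}

adamw_step <- function(net, grads, state, cfg, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - cfg$lr * (m / bc1 / (sqrt(v / bc2) + eps) + cfg$weight_decay * p)
    list(p = p, m = m, v = v)
  }
  for (l in seq_along(net$hidden)) {
    for (nm in intersect(names(net$hidden[[l]]), c("W", "b", "gamma", "beta"))) {
      u <- upd(net$hidden[[l]][[nm]], grads$hidden[[l]][[nm]],
               state$m$hidden[[l]][[nm]], state$v$hidden[[l]][[nm]])
      net$hidden[[l]][[nm]] <- u$p
      state$m$hidden[[l]][[nm]] <- u$m; state$v$hidden[[l]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(net$out[[nm]], grads$out[[nm]], state$m$out[[nm]], state$v$out[[nm]])
    net$out[[nm]] <- u$p
    state$m$out[[nm]] <- u$m; state$v$out[[nm]] <- u$v
  }
  list(net = net, state = state)
}

#' Train the dual-loss regressor
#'
#' Standardizes features (center/scale, recorded in the model), holds out a
#' seeded random validation fraction, then runs AdamW over shuffled
#' mini-batches. Each epoch logs the training loss and the evaluation-mode
#' validation loss; training stops at `max_epochs` or when the validation
#' loss has not improved for `early_stop_patience` consecutive epochs, and
#' the weights of the best validation epoch are returned.
#'
#' @param features A [embed_cells()] result or a cells x dim numeric matrix.
#' @param y Cells x genes matrix of normalized expression (the training
#'   labels, from [normalize_log1p()] restricted to the panel genes).
#' @param b Logical expressed labels (default `y > 0`).
#' @param cfg A [model_config()].
#' @param panel Optional [build_panel()] result stored with the model.
#' @return A `trained_model`: network weights, config, panel, feature and
#'   label normalization metadata, and a per-epoch `log` tibble.
#' @export
fit <- function(features, y, b = NULL, cfg = model_config(), panel = NULL) {
  X <- if (inherits(features, "histology_features")) features$z else as.matrix(features)
  stopifnot(is.matrix(X), nrow(X) == nrow(y))
  if (is.null(b)) b <- y > 0
  storage.mode(y) <- "double"
  b <- b * 1
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  n <- nrow(Xs)

  withr::with_seed(cfg$seed, {
    n_val <- max(1L, round(cfg$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) < 2 * cfg$batch_size)
      warn("fewer training cells than two batches; training full-batch")
    net <- build_network(cfg, ncol(Xs), ncol(y))
    state <- adamw_state(net)
    w_all <- regression_weights(y, cfg$w_pos, cfg$w_neg)

    best <- list(val = Inf, net = net, epoch = 0L)
    log <- vector("list", cfg$max_epochs)
    stall <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_idx)
      starts <- seq(1, length(ord), by = cfg$batch_size)
      # fold a trailing singleton into the previous batch (batch-norm needs >= 2)
      if (length(starts) > 1 && length(ord) - starts[length(starts)] == 0)
        starts <- starts[-length(starts)]
      tl <- 0
      for (s in seq_along(starts)) {
        idx <- ord[starts[s]:(if (s < length(starts)) starts[s + 1] - 1 else length(ord))]
        masks <- if (net$dropout > 0)
          purrr::map(net$hidden, function(l)
            matrix(runif(length(idx) * length(l$b)) >= net$dropout,
                   length(idx), length(l$b)))
        else NULL
        fw <- mlp_forward(net, Xs[idx, , drop = FALSE], training = TRUE, masks = masks)
        net <- fw$net
        yb <- y[idx, , drop = FALSE]; bb <- b[idx, , drop = FALSE]
        wb <- w_all[idx, , drop = FALSE]
        l_batch <- cfg$lambda_reg * loss_regression(fw$out, yb, wb) +
          cfg$lambda_bin * loss_binary(fw$out, bb, wb)
        tl <- tl + l_batch * length(idx)
        G <- loss_gradient(fw$out, yb, bb, wb, cfg)
        grads <- mlp_backward(net, fw, G, masks)
        st <- adamw_step(net, grads, state, cfg)
        net <- st$net; state <- st$state
      }
      fw_val <- mlp_forward(net, Xs[val_idx, , drop = FALSE], training = FALSE)
      vl <- cfg$lambda_reg * loss_regression(fw_val$out, y[val_idx, , drop = FALSE],
                                             w_all[val_idx, , drop = FALSE]) +
        cfg$lambda_bin * loss_binary(fw_val$out, b[val_idx, , drop = FALSE],
                                     w_all[val_idx, , drop = FALSE])
      log[[epoch]] <- tibble(epoch = epoch, train_loss = tl / length(ord),
                             val_loss = vl)
      if (vl < best$val) {
        best <- list(val = vl, net = net, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$early_stop_patience) break
      }
    }
  })

  structure(list(net = best$net, config = cfg, input_dim = ncol(Xs),
                 d_genes = ncol(y), panel = panel,
                 feature_center = ctr, feature_scale = scl,
                 normalization = if (!is.null(panel)) panel$normalization
                 else list(target_sum = attr(y, "target_sum") %||% NA_real_,
                           log1p = TRUE),
                 log = dplyr::bind_rows(log), best_epoch = best$epoch,
                 best_val_loss = best$val),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %d -> [%s] -> %d genes, %s params; best epoch %d (val loss %.4f)\n",
              x$input_dim, paste(x$config$hidden_sizes, collapse = ", "),
              x$d_genes, format(parameter_count(x), big.mark = ","),
              x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict expression for new cells
#'
#' Runs the network in inference mode (dropout off, batch-norm running
#' statistics). The shared output is read twice: clipped below at zero as
#' the expression prediction, and through a sigmoid as the per-gene
#' probability of being expressed.
#'
#' @param model A [fit()] result.
#' @param features A [embed_cells()] result or cells x dim matrix; the
#'   dimension must match `model$input_dim`.
#' @return List with `y_hat` (non-negative normalized predictions) and
#'   `p_expressed` (probabilities), both cells x genes.
#' @export
predict_cells <- function(model, features) {
  stopifnot(inherits(model, "trained_model"))
  X <- if (inherits(features, "histology_features")) features$z else as.matrix(features)
  if (ncol(X) != model$input_dim)
    abort(sprintf("feature dimension %d does not match model input_dim %d",
                  ncol(X), model$input_dim))
  Xs <- sweep(sweep(X, 2, model$feature_center), 2, model$feature_scale, "/")
  out <- mlp_forward(model$net, Xs, training = FALSE)$out
  genes <- if (!is.null(model$panel)) model$panel$genes else NULL
  dimnames(out) <- list(rownames(X), genes)
  list(y_hat = pmax(out, 0), p_expressed = sigmoid(out))
}
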