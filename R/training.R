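# Optimization of GOAE and GONN: seeded mini-batch training with Adam or
# plain SGD, paper-preset hyperparameters, and embedding extraction.

#' Training configuration
#'
#' @param batch_size Mini-batch size, default 64.
#' @param epochs Number of passes over the data, default 100.
#' @param learning_rate Positive step size.
#' @param lambda L2 regularization coefficient (used by GONN), default 1e-4.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param shuffle Reshuffle samples every epoch (seeded), default `TRUE`.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 64, epochs = 100, learning_rate = 1e-3,
                         lambda = 1e-4, seed = 0, optimizer = c("adam", "sgd"),
                         shuffle = TRUE) {
  structure(
    list(
      batch_size = check_count(batch_size, "batch_size"),
      epochs = check_count(epochs, "epochs"),
      learning_rate = check_scalar_number(learning_rate, "learning_rate", min = .Machine$double.xmin),
      lambda = check_scalar_number(lambda, "lambda", min = 0),
      seed = check_count(seed, "seed", min = 0L),
      optimizer = match.arg(optimizer),
      shuffle = isTRUE(shuffle)
    ),
    class = "train_config"
  )
}

#' Named training presets
#'
#' `"goae-paper"`: batch 64, 100 epochs, learning rate 1e-3 (Adam) — the
#' published setting for the autoencoder after term selection.
#' `"goae-unselected"`: batch 64, 300 epochs, learning rate 1e-4 — the
#' published setting for the no-selection autoencoder variant.
#' `"gonn-paper"`: batch 64, 200 epochs, learning rate 0.2 (plain SGD; a
#' rate of 0.2 is a stochastic-gradient idiom, not an adaptive-method one).
#'
#' @param name Preset name.
#' @param seed Seed to embed in the configuration.
#' @return A [train_config()].
#' @export
train_preset <- function(name = c("goae-paper", "gonn-paper", "goae-unselected"),
                         seed = 0) {
  name <- match.arg(name)
  switch(name,
    "goae-paper" = train_config(64, 100, 1e-3, seed = seed, optimizer = "adam"),
    "goae-unselected" = train_config(64, 300, 1e-4, seed = seed, optimizer = "adam"),
    "gonn-paper" = train_config(64, 200, 0.2, lambda = 1e-4, seed = seed,
                                optimizer = "sgd")
  )
}

make_optimizer <- function(layers, cfg) {
  if (cfg$optimizer == "sgd") {
    list(
      step = function(layers, grads, state) {
        for (l in seq_along(layers)) {
          layers[[l]]$W <- layers[[l]]$W - cfg$learning_rate * grads[[l]]$dW
          if (!is.null(layers[[l]]$mask)) {
            layers[[l]]$W <- layers[[l]]$W * layers[[l]]$mask
          }
          layers[[l]]$b <- layers[[l]]$b - cfg$learning_rate * grads[[l]]$db
        }
        list(layers = layers, state = state)
      },
      state = NULL
    )
  } else {
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    zero_like <- function(layer) list(
      mW = layer$W * 0, vW = layer$W * 0,
      mb = layer$b * 0, vb = layer$b * 0
    )
    list(
      step = function(layers, grads, state) {
        state$t <- state$t + 1
        corr1 <- 1 - beta1^state$t
        corr2 <- 1 - beta2^state$t
        for (l in seq_along(layers)) {
          s <- state$m[[l]]
          s$mW <- beta1 * s$mW + (1 - beta1) * grads[[l]]$dW
          s$vW <- beta2 * s$vW + (1 - beta2) * grads[[l]]$dW^2
          s$mb <- beta1 * s$mb + (1 - beta1) * grads[[l]]$db
          s$vb <- beta2 * s$vb + (1 - beta2) * grads[[l]]$db^2
          layers[[l]]$W <- layers[[l]]$W -
            cfg$learning_rate * (s$mW / corr1) / (sqrt(s$vW / corr2) + eps)
          if (!is.null(layers[[l]]$mask)) {
            layers[[l]]$W <- layers[[l]]$W * layers[[l]]$mask
          }
          layers[[l]]$b <- layers[[l]]$b -
            cfg$learning_rate * (s$mb / corr1) / (sqrt(s$vb / corr2) + eps)
          state$m[[l]] <- s
        }
        list(layers = layers, state = state)
      },
      state = list(t = 0, m = lapply(layers, zero_like))
    )
  }
}

run_training <- function(layers, X, cfg, grad_fn, label = "model") {
  n <- nrow(X)
  opt <- make_optimizer(layers, cfg)
  state <- opt$state
  trace <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    idx <- if (cfg$shuffle) sample.int(n) else seq_len(n)
    starts <- seq(1, n, by = cfg$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      batch <- idx[s:min(s + cfg$batch_size - 1, n)]
      g <- grad_fn(layers, batch)
      if (!is.finite(g$loss)) {
        abort(sprintf(
          "Non-finite %s loss at epoch %d (learning rate %g); lower the learning rate.",
          label, epoch, cfg$learning_rate
        ), class = "scgonet_training_error")
      }
      epoch_loss <- epoch_loss + g$loss * length(batch)
      upd <- opt$step(layers, g$grads, state)
      layers <- upd$layers
      state <- upd$state
    }
    trace[epoch] <- epoch_loss / n
  }
  list(layers = layers, trace = trace)
}

check_training_input <- function(data, mask) {
  if (!inherits(data, "expr_matrix")) {
    abort_config("`data` must be an expr_matrix.")
  }
  if (data$normalization != "log_zscore") {
    abort_config("Training input must be normalized with scheme 'log_zscore'.")
  }
  if (!identical(gene_ids(data), rownames(mask$matrix))) {
    abort_config("Gene order of the expression matrix and mask differ.")
  }
}

#' Train the GOAE autoencoder
#'
#' Seeded mini-batch training of the masked autoencoder under the mean
#' squared reconstruction error. Two runs with the same configuration are
#' bitwise identical; masked weight positions are exactly zero throughout.
#'
#' @param data A `log_zscore`-normalized `expr_matrix`.
#' @param mask A `go_mask` whose gene order matches `data`.
#' @param cfg A [train_config()]; default is the `"goae-paper"` preset.
#' @param latent_dim Latent width (hidden layer 2). Default 10.
#' @return A `goae_fit`: list with `model` (`goae_model`), `trace` (tibble
#'   `epoch`, `loss`) and `config`.
#' @export
train_goae <- function(data, mask, cfg = train_preset("goae-paper"),
                       latent_dim = 10) {
  check_training_input(data, mask)
  X <- data$values
  withr::with_seed(cfg$seed, {
    model <- goae_model(mask, latent_dim = latent_dim)
    out <- run_training(
      model$layers, X, cfg,
      grad_fn = function(layers, batch) {
        m <- model; m$layers <- layers
        goae_gradients(m, X[batch, , drop = FALSE])
      },
      label = "GOAE"
    )
  })
  model$layers <- out$layers
  structure(
    list(
      model = model,
      trace = tibble(epoch = seq_len(cfg$epochs), loss = out$trace),
      config = cfg
    ),
    class = "goae_fit"
  )
}

#' Train the GONN classifier
#'
#' Seeded mini-batch training of the masked supervised network under
#' component-wise cross entropy with L2 regularization. Class order is fixed
#' lexicographically.
#'
#' @param data A labelled, `log_zscore`-normalized `expr_matrix`.
#' @param mask A `go_mask` whose gene order matches `data`.
#' @param cfg A [train_config()]; default is the `"gonn-paper"` preset.
#' @param hidden_dim Width of the fully connected hidden (embedding) layer.
#' @return A `gonn_fit`: list with `model` (`gonn_model`), `trace` and
#'   `config`.
#' @export
train_gonn <- function(data, mask, cfg = train_preset("gonn-paper"),
                       hidden_dim = 100) {
  check_training_input(data, mask)
  if (is.null(data$labels)) {
    abort_config("GONN training needs cell-type labels on the expression matrix.")
  }
  labels <- data$labels[cell_ids(data)]
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    abort_config("GONN training needs at least 2 cell-type classes.")
  }
  small <- table(labels)
  if (any(small < 2)) {
    warn(sprintf(
      "Classes with fewer than 2 cells: %s",
      paste(names(small)[small < 2], collapse = ", ")
    ))
  }
  X <- data$values
  Y <- outer(labels, classes, `==`) * 1
  withr::with_seed(cfg$seed, {
    model <- gonn_model(mask, classes, hidden_dim = hidden_dim)
    out <- run_training(
      model$layers, X, cfg,
      grad_fn = function(layers, batch) {
        m <- model; m$layers <- layers
        gonn_gradients(m, X[batch, , drop = FALSE],
                       Y[batch, , drop = FALSE], cfg$lambda)
      },
      label = "GONN"
    )
  })
  model$layers <- out$layers
  structure(
    list(
      model = model,
      trace = tibble(epoch = seq_len(cfg$epochs), loss = out$trace),
      config = cfg
    ),
    class = "gonn_fit"
  )
}

#' Extract the low-dimensional embedding of cells
#'
#' Hidden-layer-2 activations of a trained model: the latent layer for the
#' autoencoder, the fully connected hidden layer for the classifier.
#'
#' @param fit A `goae_fit`/`gonn_fit` (or bare model).
#' @param data An `expr_matrix` normalized as for training, with the same
#'   gene order as the model.
#' @return Matrix (cells x latent) with cell rownames.
#' @export
extract_embedding <- function(fit, data) {
  model <- as_model(fit)
  if (!identical(gene_ids(data), model$gene_ids)) {
    abort_config("Gene order of the expression matrix and model differ.")
  }
  acts <- net_forward(model$layers[1:2], data$values)
  emb <- acts[[3]]
  rownames(emb) <- cell_ids(data)
  emb
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles weights, biases, mask, term order and the full
#' training configuration.
#'
#' @param fit A `goae_fit` or `gonn_fit`.
#' @param path Checkpoint file path.
#' @return `path` (for `save_checkpoint`), the fit (for `load_checkpoint`).
#' @export
save_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("Checkpoint not found: %s", path))
  fit <- readRDS(path)
  if (!inherits(fit, c("goae_fit", "gonn_fit"))) {
    abort_config("File is not a scgonet checkpoint.")
  }
  fit
}
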