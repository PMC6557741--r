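# Hand-built layers keep the expectations fully transparent.
layer_of <- function(W, b, mask = NULL, activation = "tanh") {
  list(W = W, b = b, mask = mask, activation = activation)
}

test_that("masked forward propagation matches the closed form", {
  l <- layer_of(matrix(1), 0, activation = "tanh")
  expect_equal(masked_forward(0.5, l), tanh(0.5))
  expect_equal(masked_forward(0.5, l), 0.46211716, tolerance = 1e-8)
  expect_equal(masked_forward(0, l), 0)

  # an all-zero mask makes the weights inert: output is f(b)
  W <- matrix(rnorm(6), 2, 3)
  msk <- matrix(0, 2, 3)
  l0 <- layer_of(W * msk, b = c(0.1, -0.2, 0.3), mask = msk)
  expect_equal(masked_forward(c(5, -7), l0), tanh(c(0.1, -0.2, 0.3)))

  expect_error(masked_forward(c(1, 2, 3), l), class = "scgonet_domain_error")
})

test_that("GOAE forward pass honors shapes, zeros and mask locality", {
  msk <- manual_mask(c("g1", "g2", "g3"), list(T1 = c("g1", "g2"), T2 = "g3"),
                     n_dense = 0)
  model <- withr::with_seed(1, goae_model(msk, latent_dim = 2))
  out <- goae_forward(model, c(0.3, -0.1, 0.5))
  expect_length(out$embedding, 2)
  expect_length(out$reconstruction, 3)

  zero <- model
  for (i in seq_along(zero$layers)) {
    zero$layers[[i]]$W[] <- 0
    zero$layers[[i]]$b[] <- 0
  }
  z <- goae_forward(zero, c(1, 2, 3))
  expect_equal(unname(z$embedding), c(0, 0))
  expect_equal(unname(z$reconstruction), c(0, 0, 0))

  # changing a gene outside T1's gene set leaves unit T1's activation alone
  a1 <- masked_forward(c(0.3, -0.1, 0.5), model$layers[[1]])
  a2 <- masked_forward(c(0.3, -0.1, 99), model$layers[[1]])
  expect_equal(a1[["T1"]], a2[["T1"]])
  expect_false(a1[["T2"]] == a2[["T2"]])
})

test_that("reconstruction loss is the mean squared Euclidean error", {
  expect_equal(goae_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(goae_loss(c(0, 0), c(1, 1)), 2)
  batch <- matrix(rnorm(10), 5, 2)
  noisy <- batch + 0.1
  expect_equal(goae_loss(rbind(batch, batch), rbind(noisy, noisy)),
               goae_loss(batch, noisy))
  expect_error(goae_loss(matrix(1, 1, 2), matrix(1, 1, 3)),
               class = "scgonet_domain_error")
})

test_that("softmax is a shift-invariant probability simplex map", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(1000, 1000)), c(0.5, 0.5))     # no overflow
  withr::with_seed(2, {
    for (i in 1:10) {
      x <- rnorm(5, sd = 10)
      p <- softmax(x)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p > 0 & p < 1))
      expect_equal(softmax(x + 123.4), p, tolerance = 1e-12)
    }
  })
})

test_that("classification loss reproduces hand-computed values", {
  expect_equal(gonn_loss(matrix(c(1, 0), 1), matrix(c(1, 0), 1), lambda = 0), 0,
               tolerance = 1e-10)
  expect_equal(gonn_loss(matrix(1), matrix(0.5), lambda = 0), 0.69314718,
               tolerance = 1e-7)
  with_l2 <- gonn_loss(matrix(1), matrix(0.5), weights = c(1, 1), lambda = 1)
  expect_equal(with_l2, 0.69314718 + 1.0, tolerance = 1e-7)
  expect_error(gonn_loss(matrix(1), matrix(0.5), lambda = -1),
               class = "scgonet_config_error")
})

test_that("prediction takes the arg-max with first-index tie-breaking", {
  msk <- manual_mask(c("g1", "g2"), list(T1 = c("g1", "g2")), n_dense = 1)
  model <- withr::with_seed(3, gonn_model(msk, classes = c("a", "b", "c")))
  # force a deterministic output: zero logits -> uniform probabilities -> tie
  model$layers[[3]]$W[] <- 0
  model$layers[[3]]$b[] <- 0
  pred <- gonn_predict(model, c(0.2, 0.4))
  expect_equal(pred$class, "a")
  expect_equal(dim(pred$prob), c(1L, 3L))
  expect_length(pred$embedding, 100)
  model$layers[[3]]$b <- c(0, 1, 0)
  expect_equal(gonn_predict(model, c(0.2, 0.4))$class, "b")
})

# central-difference gradient check on a 5-gene / 3-term toy network
numeric_grad <- function(loss_fn, layers, eps = 1e-6) {
  lapply(seq_along(layers), function(l) {
    W <- layers[[l]]$W
    dW <- W * 0
    for (i in seq_len(nrow(W))) {
      for (j in seq_len(ncol(W))) {
        if (!is.null(layers[[l]]$mask) && layers[[l]]$mask[i, j] == 0) next
        up <- layers; up[[l]]$W[i, j] <- W[i, j] + eps
        dn <- layers; dn[[l]]$W[i, j] <- W[i, j] - eps
        dW[i, j] <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
      }
    }
    b <- layers[[l]]$b
    db <- b * 0
    for (j in seq_along(b)) {
      up <- layers; up[[l]]$b[j] <- b[j] + eps
      dn <- layers; dn[[l]]$b[j] <- b[j] - eps
      db[j] <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
    }
    list(dW = dW, db = db)
  })
}

expect_grads_match <- function(analytic, numeric, tol = 1e-5) {
  for (l in seq_along(analytic)) {
    for (part in c("dW", "db")) {
      a <- as.numeric(analytic[[l]][[part]])
      n <- as.numeric(numeric[[l]][[part]])
      rel <- abs(a - n) / pmax(abs(a) + abs(n), 1e-8)
      expect_lt(max(rel), tol)
    }
  }
}

toy_models <- function() {
  msk <- manual_mask(sprintf("g%d", 1:5),
                     list(TA = c("g1", "g2"), TB = c("g2", "g3", "g4"), TC = "g5"),
                     n_dense = 1)
  withr::with_seed(42, {
    goae <- goae_model(msk, latent_dim = 3)
    gonn <- gonn_model(msk, classes = c("x", "y"), hidden_dim = 4)
    X <- matrix(rnorm(20), 4, 5, dimnames = list(NULL, sprintf("g%d", 1:5)))
    Y <- matrix(0, 4, 2); Y[cbind(1:4, c(1, 2, 1, 2))] <- 1
    list(goae = goae, gonn = gonn, X = X, Y = Y)
  })
}

test_that("analytic reconstruction-loss gradients match central differences", {
  tm <- toy_models()
  g <- scgonet:::goae_gradients(tm$goae, tm$X)
  loss_fn <- function(layers) {
    m <- tm$goae; m$layers <- layers
    goae_loss(tm$X, goae_forward(m, tm$X)$reconstruction)
  }
  expect_grads_match(g$grads, numeric_grad(loss_fn, tm$goae$layers))
})

test_that("analytic classification-loss gradients match central differences", {
  tm <- toy_models()
  lambda <- 0.01
  g <- scgonet:::gonn_gradients(tm$gonn, tm$X, tm$Y, lambda)
  loss_fn <- function(layers) {
    m <- tm$gonn; m$layers <- layers
    p <- gonn_predict(m, tm$X)$prob
    gonn_loss(tm$Y, p, weights = lapply(layers, `[[`, "W"), lambda = lambda)
  }
  expect_grads_match(g$grads, numeric_grad(loss_fn, tm$gonn$layers))
})

test_that("losses are nonnegative on random batches", {
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- matrix(rnorm(12), 3, 4)
      b <- matrix(rnorm(12), 3, 4)
      expect_gte(goae_loss(a, b), 0)
      p <- softmax(matrix(rnorm(6), 2, 3))
      y <- matrix(0, 2, 3); y[cbind(1:2, sample(3, 2, TRUE))] <- 1
      expect_gte(gonn_loss(y, p, weights = rnorm(4), lambda = 0.5), 0)
    }
  })
})
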