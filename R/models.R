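# GOAE / GONN model definitions: masked layers, forward passes, losses and
# analytic gradients. The networks are small (a few hundred inputs, ~100
# hidden units), so everything is dense base-R matrix arithmetic.

PROB_EPS <- 1e-12

new_layer <- function(W, b, mask = NULL, activation = c("tanh", "linear", "softmax")) {
  activation <- match.arg(activation)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(W)))
    W <- W * mask
  }
  list(W = W, b = b, mask = mask, activation = activation)
}

# Fan-in-scaled uniform initialization; for masked layers the fan-in of each
# unit is its count of connected genes, so sparse units get a wider range.
init_layer <- function(n_in, n_out, activation, mask = NULL) {
  fan_in <- if (is.null(mask)) rep(n_in, n_out) else pmax(colSums(mask), 1)
  limit <- sqrt(3 / fan_in)
  W <- matrix(runif(n_in * n_out, -1, 1), n_in, n_out)
  W <- sweep(W, 2, limit, "*")
  new_layer(W, b = rep(0, n_out), mask = mask, activation = activation)
}

apply_activation <- function(z, activation) {
  switch(activation,
    tanh = tanh(z),
    linear = z,
    softmax = softmax(z)
  )
}

#' Forward propagation through one (optionally masked) layer
#'
#' Computes `f(x W + b)` where masked weight entries are identically zero,
#' so a gene not annotated by a unit's GO term contributes exactly nothing
#' to that unit.
#'
#' @param x Input: numeric vector or matrix (samples x inputs).
#' @param layer A layer as stored in a model: list with `W`, `b`, optional
#'   `mask`, and `activation` (`tanh`, `linear` or `softmax`).
#' @return Activation matrix (samples x units); a vector input returns a
#'   vector.
#' @export
masked_forward <- function(x, layer) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  if (ncol(x) != nrow(layer$W)) {
    abort_domain(sprintf(
      "Input has %d features but layer expects %d.", ncol(x), nrow(layer$W)
    ))
  }
  z <- sweep(x %*% layer$W, 2, layer$b, "+")
  a <- apply_activation(z, layer$activation)
  if (vec) a <- drop(a)
  a
}

net_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- x
  for (i in seq_along(layers)) {
    acts[[i + 1]] <- masked_forward(acts[[i]], layers[[i]])
  }
  acts
}

#' Construct an untrained GOAE model
#'
#' The Gene Ontology autoencoder: a masked encoder layer from genes to
#' GO-term (plus dense) units with tanh activation, a dense tanh layer to
#' the latent space, and a decoder mirroring those shapes — a dense tanh
#' layer back to the unit layer and a masked linear layer (transposed
#' connectivity pattern) back to gene space. Decoder weights are free
#' parameters sharing only the mask pattern, not tied to the encoder. The
#' output activation is linear because inputs are z-scored and unbounded.
#'
#' @param mask A `go_mask` from [build_mask()].
#' @param latent_dim Width of the latent (hidden layer 2) space. Default 10:
#'   a tight bottleneck on the order of the expected number of cell types.
#' @return A `goae_model`.
#' @export
goae_model <- function(mask, latent_dim = 10) {
  latent_dim <- check_count(latent_dim, "latent_dim")
  m <- mask$matrix
  layers <- list(
    init_layer(nrow(m), ncol(m), "tanh", mask = m),
    init_layer(ncol(m), latent_dim, "tanh"),
    init_layer(latent_dim, ncol(m), "tanh"),
    init_layer(ncol(m), nrow(m), "linear", mask = t(m))
  )
  structure(
    list(
      layers = layers, latent_dim = latent_dim,
      unit_terms = mask$unit_terms, n_dense = mask$n_dense,
      gene_ids = rownames(m)
    ),
    class = "goae_model"
  )
}

#' Construct an untrained GONN model
#'
#' The supervised Gene Ontology network: the same masked gene-to-unit tanh
#' layer, a dense tanh hidden layer (100 units by default, the embedding
#' layer), and a dense softmax output over cell types.
#'
#' @param mask A `go_mask`.
#' @param classes Ordered character vector of cell-type labels.
#' @param hidden_dim Width of the fully connected hidden layer. Default 100.
#' @return A `gonn_model`.
#' @export
gonn_model <- function(mask, classes, hidden_dim = 100) {
  hidden_dim <- check_count(hidden_dim, "hidden_dim")
  classes <- as.character(classes)
  if (length(classes) < 2) {
    abort_config("GONN needs at least 2 cell-type classes.")
  }
  m <- mask$matrix
  layers <- list(
    init_layer(nrow(m), ncol(m), "tanh", mask = m),
    init_layer(ncol(m), hidden_dim, "tanh"),
    init_layer(hidden_dim, length(classes), "softmax")
  )
  structure(
    list(
      layers = layers, classes = classes, hidden_dim = hidden_dim,
      unit_terms = mask$unit_terms, n_dense = mask$n_dense,
      gene_ids = rownames(m)
    ),
    class = "gonn_model"
  )
}

#' @export
print.goae_model <- function(x, ...) {
  cat(sprintf(
    "<goae_model> %d genes -> %d units (%d terms + %d dense) -> %d latent (mirrored decoder)\n",
    length(x$gene_ids), length(x$unit_terms) + x$n_dense,
    length(x$unit_terms), x$n_dense, x$latent_dim
  ))
  invisible(x)
}

#' @export
print.gonn_model <- function(x, ...) {
  cat(sprintf(
    "<gonn_model> %d genes -> %d units (%d terms + %d dense) -> %d hidden -> %d classes\n",
    length(x$gene_ids), length(x$unit_terms) + x$n_dense,
    length(x$unit_terms), x$n_dense, x$hidden_dim, length(x$classes)
  ))
  invisible(x)
}

#' Forward pass of a GOAE model
#'
#' @param model A `goae_model`.
#' @param x Input vector or matrix (cells x genes), z-scored log expression.
#' @return List with `embedding` (hidden-layer-2 activations) and
#'   `reconstruction` (output-layer values in gene space).
#' @export
goae_forward <- function(model, x) {
  acts <- net_forward(model$layers, if (is.null(dim(x))) matrix(x, nrow = 1) else x)
  emb <- acts[[3]]
  rec <- acts[[5]]
  if (is.null(dim(x))) {
    emb <- drop(emb)
    rec <- drop(rec)
  }
  list(embedding = emb, reconstruction = rec)
}

#' Reconstruction loss of the autoencoder
#'
#' Mean over samples of the squared Euclidean distance between input and
#' reconstruction.
#'
#' @param x_in,x_out Matrices (samples x genes) of equal shape; vectors are
#'   treated as single samples.
#' @return Nonnegative scalar.
#' @export
goae_loss <- function(x_in, x_out) {
  if (is.null(dim(x_in))) x_in <- matrix(x_in, nrow = 1)
  if (is.null(dim(x_out))) x_out <- matrix(x_out, nrow = 1)
  if (!all(dim(x_in) == dim(x_out))) {
    abort_domain("Input and reconstruction batches must have equal shape.")
  }
  if (nrow(x_in) == 0) {
    abort_domain("Empty batch.")
  }
  mean(rowSums((x_in - x_out)^2))
}

#' Numerically safe softmax
#'
#' Row-wise `exp(x_i) / sum(exp(x))` with max-subtraction, so the result is
#' invariant to adding a constant to all inputs and never overflows.
#'
#' @param x Score vector, or matrix with samples in rows.
#' @return Probabilities of the same shape; rows sum to 1.
#' @export
softmax <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  z <- x - apply(x, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  if (vec) p <- drop(p)
  p
}

#' Classification loss of the supervised model
#'
#' Component-wise binary cross entropy between the one-hot target and the
#' predicted probability vector, summed over output components and averaged
#' over samples, plus an L2 penalty `lambda/(2n) * sum(w^2)` over the weight
#' matrices (biases are not regularized). Probabilities are clipped into
#' `[1e-12, 1 - 1e-12]` before the logarithms.
#'
#' @param y_true One-hot matrix (samples x classes); a vector is one sample.
#' @param y_prob Predicted probability matrix of the same shape.
#' @param weights Numeric vector (or list of matrices) of trainable weights
#'   entering the L2 term.
#' @param lambda Nonnegative L2 coefficient.
#' @return Scalar loss.
#' @export
gonn_loss <- function(y_true, y_prob, weights = numeric(0), lambda = 0) {
  if (lambda < 0) abort_config("`lambda` must be nonnegative.")
  if (is.null(dim(y_true))) y_true <- matrix(y_true, nrow = 1)
  if (is.null(dim(y_prob))) y_prob <- matrix(y_prob, nrow = 1)
  if (!all(dim(y_true) == dim(y_prob))) {
    abort_domain("Target and prediction batches must have equal shape.")
  }
  n <- nrow(y_true)
  if (n == 0) abort_domain("Empty batch.")
  p <- pmin(pmax(y_prob, PROB_EPS), 1 - PROB_EPS)
  ce <- -sum(y_true * log(p) + (1 - y_true) * log(1 - p)) / n
  w2 <- sum(unlist(lapply(weights, function(w) sum(w^2))))
  ce + lambda / (2 * n) * w2
}

#' Predict cell types with a GONN model
#'
#' @param model A trained `gonn_model` (or `gonn_fit`).
#' @param x Input vector or matrix (cells x genes), z-scored log expression.
#' @return List with `class` (predicted labels; ties resolved to the lowest
#'   class index), `prob` (probability matrix) and `embedding` (hidden-layer-2
#'   activations).
#' @export
gonn_predict <- function(model, x) {
  model <- as_model(model)
  acts <- net_forward(model$layers, if (is.null(dim(x))) matrix(x, nrow = 1) else x)
  prob <- acts[[4]]
  idx <- apply(prob, 1, which.max) # first maximum on ties
  list(
    class = model$classes[idx],
    prob = prob,
    embedding = acts[[3]]
  )
}

as_model <- function(x) {
  if (inherits(x, c("goae_fit", "gonn_fit"))) x$model else x
}

# ---- gradients ------------------------------------------------------------

# Backpropagation through a layer stack given dL/dA at the top.
# `acts` comes from net_forward(); returns per-layer dW, db (mask applied).
backprop <- function(layers, acts, dtop, l2_lambda = 0, l2_n = 1) {
  L <- length(layers)
  grads <- vector("list", L)
  dA <- dtop
  for (l in rev(seq_len(L))) {
    a <- acts[[l + 1]]
    dZ <- switch(layers[[l]]$activation,
      linear = dA,
      tanh = dA * (1 - a^2),
      softmax = {
        # dA is dL/dp here; route through the softmax Jacobian row-wise
        a * (dA - rowSums(dA * a))
      }
    )
    dW <- crossprod(acts[[l]], dZ)
    if (l2_lambda > 0) dW <- dW + (l2_lambda / l2_n) * layers[[l]]$W
    if (!is.null(layers[[l]]$mask)) dW <- dW * layers[[l]]$mask
    grads[[l]] <- list(dW = dW, db = colSums(dZ))
    if (l > 1) dA <- dZ %*% t(layers[[l]]$W)
  }
  grads
}

# Loss and analytic gradients of the reconstruction objective for a batch.
goae_gradients <- function(model, x) {
  acts <- net_forward(model$layers, x)
  rec <- acts[[5]]
  loss <- goae_loss(x, rec)
  dtop <- 2 / nrow(x) * (rec - x)
  list(loss = loss, grads = backprop(model$layers, acts, dtop))
}

# Loss and analytic gradients of the classification objective for a batch.
gonn_gradients <- function(model, x, y_onehot, lambda) {
  acts <- net_forward(model$layers, x)
  p <- acts[[4]]
  n <- nrow(x)
  weights <- lapply(model$layers, `[[`, "W")
  loss <- gonn_loss(y_onehot, p, weights = weights, lambda = lambda)
  pc <- pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
  dP <- -(y_onehot / pc - (1 - y_onehot) / (1 - pc)) / n
  list(
    loss = loss,
    grads = backprop(model$layers, acts, dP, l2_lambda = lambda, l2_n = n)
  )
}
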