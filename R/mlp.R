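# Minimal softmax multi-layer perceptron trained by mini-batch stochastic
# gradient descent with momentum. Pure R matrix arithmetic; training is a
# deterministic function of (data, config, seed).

mlpInit <- function(layerSizes) {
  W <- list(); b <- list()
  for (l in seq_len(length(layerSizes) - 1)) {
    fanIn <- layerSizes[l]
    W[[l]] <- matrix(stats::rnorm(fanIn * layerSizes[l + 1], 0, sqrt(2 / fanIn)),
                     fanIn, layerSizes[l + 1])
    b[[l]] <- rep(0, layerSizes[l + 1])
  }
  list(W = W, b = b)
}

mlpForward <- function(W, b, X) {
  L <- length(W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% W[[l]]
    Z <- sweep(Z, 2, b[[l]], "+")
    A[[l + 1]] <- if (l < L) pmax(Z, 0) else Z   # ReLU hidden, linear output
  }
  A
}

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Train a softmax MLP by seeded SGD
#'
#' ReLU hidden layers, softmax cross-entropy output, mini-batch stochastic
#' gradient descent with momentum, He-normal weight initialization. Features
#' are standardized per dimension with training statistics (constant
#' dimensions get unit scale); the statistics are stored in the model and
#' reapplied at prediction.
#'
#' @param X n x p feature matrix.
#' @param y factor (or coercible) of class labels; levels become the output
#'   order.
#' @param layerSizes integer vector from input to output width; the first
#'   entry must equal \code{ncol(X)} and the last the number of classes.
#' @param learningRate,momentum,epochs,batchSize SGD hyperparameters
#'   (defaults 0.01, 0.9, 200, 32).
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @param featureMeta free-form descriptor metadata stored in the model.
#' @return An [MlpModel-class].
#' @export
mlpTrain <- function(X, y, layerSizes, learningRate = 0.01, momentum = 0.9,
                     epochs = 200L, batchSize = 32L, seed = 1L,
                     featureMeta = list()) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2)
    stopf("spineDSS_training_error", "training data contains a single class")
  if (ncol(X) != layerSizes[1])
    stopf("spineDSS_validation_error", "layerSizes[1] (%d) != feature dimension (%d)",
          layerSizes[1], ncol(X))
  if (utils::tail(layerSizes, 1) != nlevels(y))
    stopf("spineDSS_validation_error", "output width (%d) != number of classes (%d)",
          utils::tail(layerSizes, 1), nlevels(y))
  if (epochs < 1 || batchSize < 1)
    stopf("spineDSS_validation_error", "epochs and batchSize must be >= 1")

  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  Y <- diag(nlevels(y))[as.integer(y), , drop = FALSE]
  n <- nrow(Xs)

  fit <- withSeed(seed, {
    par <- mlpInit(layerSizes)
    vW <- lapply(par$W, function(w) w * 0)
    vb <- lapply(par$b, function(bb) bb * 0)
    L <- length(par$W)
    lossHist <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = batchSize)) {
        sel <- ord[start:min(start + batchSize - 1, n)]
        Xb <- Xs[sel, , drop = FALSE]; Yb <- Y[sel, , drop = FALSE]
        A <- mlpForward(par$W, par$b, Xb)
        P <- softmaxRows(A[[L + 1]])
        losses <- c(losses, -mean(log(pmax(rowSums(P * Yb), 1e-12))))
        dZ <- (P - Yb) / nrow(Xb)
        for (l in L:1) {
          gW <- crossprod(A[[l]], dZ)
          gb <- colSums(dZ)
          if (l > 1) {
            dA <- tcrossprod(dZ, par$W[[l]])
            dZ <- dA * (A[[l]] > 0)
          }
          vW[[l]] <- momentum * vW[[l]] - learningRate * gW
          vb[[l]] <- momentum * vb[[l]] - learningRate * gb
          par$W[[l]] <- par$W[[l]] + vW[[l]]
          par$b[[l]] <- par$b[[l]] + vb[[l]]
        }
      }
      lossHist[ep] <- mean(losses)
    }
    list(par = par, lossHist = lossHist)
  })

  new("MlpModel", weights = fit$par$W, biases = fit$par$b,
      norm = list(mean = mu, sd = sd), classes = levels(y),
      config = list(layerSizes = layerSizes, learningRate = learningRate,
                    momentum = momentum, epochs = as.integer(epochs),
                    batchSize = as.integer(batchSize), seed = as.integer(seed),
                    activation = "relu"),
      lossHistory = fit$lossHist, featureMeta = featureMeta)
}

#' Class probabilities from a trained MLP
#'
#' @param model an [MlpModel-class].
#' @param X feature matrix (or a single feature vector).
#' @return n x K matrix of class probabilities (columns in
#'   \code{model@classes} order); rows sum to 1.
#' @export
mlpPredict <- function(model, X) {
  if (!isTrained(model))
    stopf("spineDSS_state_error", "model has not been trained")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, model@norm$mean), 2, model@norm$sd, "/")
  A <- mlpForward(model@weights, model@biases, Xs)
  P <- softmaxRows(A[[length(model@weights) + 1]])
  colnames(P) <- model@classes
  P
}
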