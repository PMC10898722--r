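# Minimal one-hidden-layer neural network matching the study configuration:
# ReLU hidden layer, sigmoid output, binary cross-entropy loss, AdamW
# optimizer with decoupled weight decay, mini-batch training with per-epoch
# reshuffling. Small enough (24 inputs, <= 64 hidden units, <= ~100 training
# trials) that plain R matrix operations are fast.

fit_ann <- function(X, y01, hidden = 16, batch_size = 16, lr = 1e-2,
                    weight_decay = 1e-4, epochs = 50, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  with_seed(seed, {
    # He initialisation for the ReLU layer, Glorot-ish for the output
    W1 <- matrix(rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden)
    b1 <- rep(0, hidden)
    W2 <- matrix(rnorm(hidden, 0, sqrt(1 / hidden)), hidden, 1)
    b2 <- 0
    pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    m <- lapply(pars, function(p) p * 0)
    v <- lapply(pars, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- X[idx, , drop = FALSE]
        yb <- y01[idx]
        nb <- length(idx)
        # forward
        h_lin <- xb %*% pars$W1 + rep(pars$b1, each = nb)
        h <- pmax(h_lin, 0)
        z <- drop(h %*% pars$W2) + pars$b2
        prob <- 1 / (1 + exp(-z))
        # backward (mean BCE; d loss / d z = prob - y)
        dz <- (prob - yb) / nb
        gW2 <- crossprod(h, dz)
        gb2 <- sum(dz)
        dh <- (dz %*% t(pars$W2)) * (h_lin > 0)
        gW1 <- crossprod(xb, dh)
        gb1 <- colSums(dh)
        grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
        step <- step + 1L
        bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
        for (nm in names(pars)) {
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
          upd <- (m[[nm]] / bc1) / (sqrt(v[[nm]] / bc2) + eps)
          # AdamW: weight decay decoupled from the gradient, biases excluded
          decay <- if (nm %in% c("W1", "W2")) weight_decay * pars[[nm]] else 0
          pars[[nm]] <- pars[[nm]] - lr * (upd + decay)
        }
      }
    }
    structure(pars, class = "windeeg_ann")
  })
}

predict_ann <- function(model, X) {
  X <- as.matrix(X)
  h <- pmax(X %*% model$W1 + rep(model$b1, each = nrow(X)), 0)
  drop(1 / (1 + exp(-(h %*% model$W2 + model$b2))))
}
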