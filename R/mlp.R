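# Feed-forward network with softmax output, trained by full-batch Adam with
# cross-entropy loss, decoupled weight decay, and early stopping on a
# stratified validation split. Used both as the NN base learner and as the
# stacking meta-learner (where a pure-linear mode is also offered, since a
# "deep linear layer network" admits either reading). Full-batch training is
# deliberate: n is a few hundred to ~1,400 here, the BLAS matmuls dominate,
# and it keeps the optimisation trajectory exactly reproducible from the seed.

mlp_fit <- function(X, y, hidden = c(64, 32), activation = c("relu", "linear"),
                    max_epochs = 200, lr = 1e-2, weight_decay = 1e-4,
                    val_fraction = 0.1, patience = 20, seed = 0) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  if (anyNA(X) || !all(is.finite(X))) abort("non-finite features passed to the network")
  y <- factor(y)
  classes <- levels(y)
  if (length(classes) < 2) abort("need at least 2 classes, got 1")
  n <- nrow(X); p <- ncol(X); C <- length(classes)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  sizes <- c(p, hidden, C)
  L <- length(sizes) - 1

  withr::with_seed(seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
    use_val <- val_fraction > 0 && n >= 20 && all(table(y) >= 2 / val_fraction)
    if (use_val) {
      fold <- stratified_folds(y, round(1 / val_fraction), seed + 1L)
      val_idx <- which(fold == 1)
    } else {
      val_idx <- integer(0)
    }
  })
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  Xva <- X[val_idx, , drop = FALSE]; Yva <- Y[val_idx, , drop = FALSE]

  act <- if (activation == "relu") function(z) pmax(z, 0) else identity
  dact <- if (activation == "relu") function(z) (z > 0) * 1 else function(z) 1

  forward <- function(Xb) {
    A <- vector("list", L + 1); Z <- vector("list", L)
    A[[1]] <- Xb
    for (l in seq_len(L)) {
      Z[[l]] <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], `+`)
      A[[l + 1]] <- if (l < L) act(Z[[l]]) else Z[[l]]
    }
    zl <- A[[L + 1]]
    zl <- zl - apply(zl, 1, max)
    P <- exp(zl); P <- P / rowSums(P)
    list(A = A, Z = Z, P = P)
  }
  ce_loss <- function(P, Yb) -mean(rowSums(Yb * log(pmax(P, 1e-12))))

  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, W = W, b = b, epoch = 0)
  stall <- 0
  ntr <- nrow(Xtr)

  for (epoch in seq_len(max_epochs)) {
    fw <- forward(Xtr)
    dZ <- (fw$P - Ytr) / ntr
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in rev(seq_len(L))) {
      gW[[l]] <- crossprod(fw$A[[l]], dZ)
      gb[[l]] <- colSums(dZ)
      if (l > 1) dZ <- (dZ %*% t(W[[l]])) * dact(fw$Z[[l - 1]])
    }
    bc1 <- 1 - b1^epoch; bc2 <- 1 - b2^epoch
    for (l in seq_len(L)) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
      W[[l]] <- W[[l]] - lr * ((mW[[l]] / bc1) / (sqrt(vW[[l]] / bc2) + eps) +
                                 weight_decay * W[[l]])
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
      b[[l]] <- b[[l]] - lr * (mb[[l]] / bc1) / (sqrt(vb[[l]] / bc2) + eps)
    }
    if (length(val_idx)) {
      vl <- ce_loss(forward(Xva)$P, Yva)
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, W = W, b = b, epoch = epoch)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= patience) break
      }
    }
  }
  if (length(val_idx)) { W <- best$W; b <- best$b }

  structure(list(W = W, b = b, classes = classes, activation = activation,
                 sizes = sizes),
            class = "rpstack_mlp")
}

mlp_predict_proba <- function(model, X) {
  X <- as.matrix(X)
  A <- X
  L <- length(model$W)
  act <- if (model$activation == "relu") function(z) pmax(z, 0) else identity
  for (l in seq_len(L)) {
    Z <- sweep(A %*% model$W[[l]], 2, model$b[[l]], `+`)
    A <- if (l < L) act(Z) else Z
  }
  A <- A - apply(A, 1, max)
  P <- exp(A); P <- P / rowSums(P)
  colnames(P) <- model$classes
  P
}

# Pegasos-style linear SVM (hinge loss, L2), used only by the ANOVA+SVM
# comparator pipeline; probabilities are a logistic squash of the margin.
linear_svm_fit <- function(X, y, lambda = 1e-3, epochs = 40, seed = 0) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) abort("linear SVM comparator is binary only")
  yy <- ifelse(as.integer(y) == 2, 1, -1)
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p); b0 <- 0; t <- 0
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1
        eta <- 1 / (lambda * t)
        marg <- yy[i] * (sum(X[i, ] * w) + b0)
        w <- (1 - eta * lambda) * w
        if (marg < 1) {
          w <- w + eta * yy[i] * X[i, ]
          b0 <- b0 + eta * yy[i]
        }
      }
    }
  })
  structure(list(w = w, b = b0, classes = levels(y)), class = "rpstack_svm")
}

linear_svm_predict_proba <- function(model, X) {
  marg <- as.vector(as.matrix(X) %*% model$w + model$b)
  p2 <- stats::plogis(marg)
  P <- cbind(1 - p2, p2)
  colnames(P) <- model$classes
  P
}
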