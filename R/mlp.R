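# Minimal feed-forward network for per-base correctness probability.
# Dense layers with ReLU activations, sigmoid output, (optionally
# class-weighted) binary cross-entropy, Adam updates, early stopping on a
# held-out split.  Everything is plain matrix arithmetic so that training
# is exactly reproducible from the seed.

.mlp_init <- function(nin, hidden, seed) {
  set.seed(seed)
  dims <- c(nin, hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1L)) {
    # He initialisation, suited to ReLU units
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                  sd = sqrt(2 / dims[l])),
                     nrow = dims[l])
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b)
}

.mlp_forward <- function(params, X) {
  L <- length(params$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% params$W[[l]], 2, params$b[[l]], `+`)
    acts[[l + 1L]] <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  acts
}

.mlp_predict <- function(params, X) {
  p <- .mlp_forward(params, X)[[length(params$W) + 1L]]
  as.numeric(p)
}

.bce <- function(p, y, w) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
}

# One Adam step over a minibatch; returns updated params + moments.
.mlp_step <- function(state, X, y, w, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  params <- state$params
  L <- length(params$W)
  acts <- .mlp_forward(params, X)
  n <- nrow(X)
  p <- acts[[L + 1L]]
  # d(loss)/d(logit) for weighted BCE with sigmoid output
  delta <- matrix(w * (p - y) / n, ncol = 1L)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params$W[[l]])) * (acts[[l]] > 0)
    }
  }
  state$t <- state$t + 1L
  for (l in seq_len(L)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * gW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * gW[[l]]^2
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * gb[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * gb[[l]]^2
    mhW <- state$mW[[l]] / (1 - beta1^state$t)
    vhW <- state$vW[[l]] / (1 - beta2^state$t)
    mhb <- state$mb[[l]] / (1 - beta1^state$t)
    vhb <- state$vb[[l]] / (1 - beta2^state$t)
    params$W[[l]] <- params$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
    params$b[[l]] <- params$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
  }
  state$params <- params
  state
}

.mlp_train <- function(X, y, w, holdout, epochs, lr, batchSize, seed,
                       patience = 5L, verbose = FALSE) {
  params <- .mlp_init(ncol(X), attr(X, "hidden"), seed)
  zeros <- function(tmpl) lapply(tmpl, function(m) m * 0)
  state <- list(params = params, t = 0L,
                mW = zeros(params$W), vW = zeros(params$W),
                mb = zeros(params$b), vb = zeros(params$b))
  Xtr <- X[!holdout, , drop = FALSE]; ytr <- y[!holdout]; wtr <- w[!holdout]
  Xva <- X[holdout, , drop = FALSE]; yva <- y[holdout]; wva <- w[holdout]
  ntr <- nrow(Xtr)
  best <- list(loss = Inf, params = state$params, epoch = 0L)
  bad <- 0L
  for (ep in seq_len(epochs)) {
    ordr <- sample.int(ntr)          # seeded by the caller's set.seed chain
    for (start in seq(1L, ntr, by = batchSize)) {
      idx <- ordr[start:min(start + batchSize - 1L, ntr)]
      state <- .mlp_step(state, Xtr[idx, , drop = FALSE], ytr[idx],
                         wtr[idx], lr)
    }
    vloss <- .bce(.mlp_predict(state$params, Xva), yva, wva)
    if (verbose) message(sprintf("epoch %d: held-out loss %.6f", ep, vloss))
    if (vloss < best$loss - 1e-7) {
      best <- list(loss = vloss, params = state$params, epoch = ep)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  best
}
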