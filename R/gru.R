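# Minimal gated recurrent unit (GRU) regression head, full-batch training
# with analytic backpropagation through time and Adam updates. The avatar
# only ever needs tiny models (<= a few dozen hidden units, lookback of a
# week), so everything is dense base-R matrix algebra.
#
# Gate convention (update gate z moves the state toward the candidate):
#   z_t = sigmoid(X_t Wz' + H_{t-1} Uz' + bz)
#   r_t = sigmoid(X_t Wr' + H_{t-1} Ur' + br)
#   c_t = tanh(X_t Wh' + (r_t * H_{t-1}) Uh' + bh)
#   H_t = (1 - z_t) * H_{t-1} + z_t * c_t
#   yhat = H_L wo + bo

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_init <- function(n_in, n_h, seed) {
  with_seed_(seed, {
    glorot <- function(nr, nc) {
      lim <- sqrt(6 / (nr + nc))
      matrix(runif(nr * nc, -lim, lim), nr, nc)
    }
    list(Wz = glorot(n_h, n_in), Uz = glorot(n_h, n_h), bz = numeric(n_h),
         Wr = glorot(n_h, n_in), Ur = glorot(n_h, n_h), br = numeric(n_h),
         Wh = glorot(n_h, n_in), Uh = glorot(n_h, n_h), bh = numeric(n_h),
         wo = runif(n_h, -sqrt(6 / (n_h + 1)), sqrt(6 / (n_h + 1))),
         bo = 0)
  })
}

# X: list over L timesteps of (n x n_in) matrices.
gru_forward <- function(params, X, cache = FALSE) {
  n <- nrow(X[[1]]); n_h <- length(params$bz); L <- length(X)
  H <- matrix(0, n, n_h)
  steps <- if (cache) vector("list", L) else NULL
  bz <- matrix(params$bz, n, n_h, byrow = TRUE)
  br <- matrix(params$br, n, n_h, byrow = TRUE)
  bh <- matrix(params$bh, n, n_h, byrow = TRUE)
  tWz <- t(params$Wz); tUz <- t(params$Uz)
  tWr <- t(params$Wr); tUr <- t(params$Ur)
  tWh <- t(params$Wh); tUh <- t(params$Uh)
  for (t in seq_len(L)) {
    Xt <- X[[t]]
    z <- sigmoid(Xt %*% tWz + H %*% tUz + bz)
    r <- sigmoid(Xt %*% tWr + H %*% tUr + br)
    cc <- tanh(Xt %*% tWh + (r * H) %*% tUh + bh)
    Hnew <- (1 - z) * H + z * cc
    if (cache) steps[[t]] <- list(Hprev = H, z = z, r = r, c = cc)
    H <- Hnew
  }
  yhat <- drop(H %*% params$wo) + params$bo
  list(yhat = yhat, H = H, steps = steps)
}

# Mean-squared-error loss and its gradient in all parameters.
gru_loss_grad <- function(params, X, y) {
  fw <- gru_forward(params, X, cache = TRUE)
  n <- length(y); L <- length(X)
  resid <- fw$yhat - y
  loss <- mean(resid^2)
  dy <- 2 * resid / n
  g <- list(Wz = 0 * params$Wz, Uz = 0 * params$Uz, bz = 0 * params$bz,
            Wr = 0 * params$Wr, Ur = 0 * params$Ur, br = 0 * params$br,
            Wh = 0 * params$Wh, Uh = 0 * params$Uh, bh = 0 * params$bh,
            wo = crossprod(fw$H, dy)[, 1], bo = sum(dy))
  dH <- tcrossprod(dy, params$wo)
  for (t in rev(seq_len(L))) {
    st <- fw$steps[[t]]
    Xt <- X[[t]]
    dz <- dH * (st$c - st$Hprev)
    dc <- dH * st$z
    da_h <- dc * (1 - st$c^2)
    da_z <- dz * st$z * (1 - st$z)
    drH <- da_h %*% params$Uh
    dr <- drH * st$Hprev
    da_r <- dr * st$r * (1 - st$r)
    g$Wz <- g$Wz + crossprod(da_z, Xt); g$Uz <- g$Uz + crossprod(da_z, st$Hprev)
    g$bz <- g$bz + colSums(da_z)
    g$Wr <- g$Wr + crossprod(da_r, Xt); g$Ur <- g$Ur + crossprod(da_r, st$Hprev)
    g$br <- g$br + colSums(da_r)
    g$Wh <- g$Wh + crossprod(da_h, Xt)
    g$Uh <- g$Uh + crossprod(da_h, st$r * st$Hprev)
    g$bh <- g$bh + colSums(da_h)
    dH <- dH * (1 - st$z) + da_z %*% params$Uz + da_r %*% params$Ur + drH * st$r
  }
  list(loss = loss, grad = g)
}

# Full-batch Adam with optional early stopping on a validation subset.
# Deterministic: no shuffling, initialization seeded by the caller.
gru_train <- function(X, y, n_hidden, seed, lr = 0.01, max_epochs = 200L,
                      patience = 20L, val_idx = integer(0),
                      init_params = NULL, l2 = 0) {
  n_in <- ncol(X[[1]])
  params <- if (is.null(init_params)) gru_init(n_in, n_hidden, seed) else init_params
  train_idx <- setdiff(seq_along(y), val_idx)
  Xtr <- lapply(X, function(m) m[train_idx, , drop = FALSE])
  ytr <- y[train_idx]
  has_val <- length(val_idx) > 0
  if (has_val) {
    Xva <- lapply(X, function(m) m[val_idx, , drop = FALSE])
    yva <- y[val_idx]
  }
  m <- v <- lapply(params, function(p) 0 * p)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- params; best_loss <- Inf; wait <- 0L
  weight_mats <- c("Wz", "Uz", "Wr", "Ur", "Wh", "Uh", "wo")
  for (epoch in seq_len(max_epochs)) {
    lg <- gru_loss_grad(params, Xtr, ytr)
    if (l2 > 0) {
      for (k in weight_mats) lg$grad[[k]] <- lg$grad[[k]] + l2 * params[[k]]
    }
    for (k in names(params)) {
      m[[k]] <- b1 * m[[k]] + (1 - b1) * lg$grad[[k]]
      v[[k]] <- b2 * v[[k]] + (1 - b2) * lg$grad[[k]]^2
      mhat <- m[[k]] / (1 - b1^epoch)
      vhat <- v[[k]] / (1 - b2^epoch)
      params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
    monitor <- if (has_val) {
      mean((gru_forward(params, Xva)$yhat - yva)^2)
    } else {
      lg$loss
    }
    if (monitor < best_loss - 1e-12) {
      best <- params; best_loss <- monitor; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(params = best, monitor_loss = best_loss, epochs_run = epoch)
}

gru_predict <- function(params, X) {
  gru_forward(params, X)$yhat
}
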