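# Minimal neural-network engine: LSTM / GRU / 1-D convolution / dense layers
# with hand-derived backpropagation and Adam. Sequences are lists over time of
# [batch x dim] matrices. Internal; the classifier front-ends live in
# classify.R.

sigm <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

lstm_init <- function(D, H) {
  list(Wx = glorot(D, 4 * H), Wh = glorot(H, 4 * H), b = rep(0, 4 * H))
}

lstm_forward <- function(X, p, H) {
  T_ <- length(X); B <- nrow(X[[1]])
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hs <- vector("list", T_); cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    z <- X[[t]] %*% p$Wx + h %*% p$Wh + rep(p$b, each = B)
    i <- sigm(z[, 1:H, drop = FALSE])
    f <- sigm(z[, H + 1:H, drop = FALSE])
    o <- sigm(z[, 2 * H + 1:H, drop = FALSE])
    g <- tanh(z[, 3 * H + 1:H, drop = FALSE])
    c_new <- f * cc + i * g
    h_new <- o * tanh(c_new)
    cache[[t]] <- list(x = X[[t]], h_prev = h, c_prev = cc,
                       i = i, f = f, o = o, g = g, c = c_new)
    h <- h_new; cc <- c_new
    Hs[[t]] <- h
  }
  list(H = Hs, cache = cache)
}

lstm_backward <- function(dH, cache, p, H) {
  T_ <- length(cache); B <- nrow(cache[[1]]$x)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dX <- vector("list", T_)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    ca <- cache[[t]]
    dh <- dh_next + (dH[[t]] %||% 0)
    tc <- tanh(ca$c)
    do_ <- dh * tc
    dc <- dc_next + dh * ca$o * (1 - tc^2)
    df <- dc * ca$c_prev
    di <- dc * ca$g
    dg <- dc * ca$i
    dc_next <- dc * ca$f
    dz <- cbind(di * ca$i * (1 - ca$i), df * ca$f * (1 - ca$f),
                do_ * ca$o * (1 - ca$o), dg * (1 - ca$g^2))
    dWx <- dWx + crossprod(ca$x, dz)
    dWh <- dWh + crossprod(ca$h_prev, dz)
    db <- db + colSums(dz)
    dX[[t]] <- dz %*% t(p$Wx)
    dh_next <- dz %*% t(p$Wh)
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, b = db))
}

gru_init <- function(D, H) {
  list(Wx = glorot(D, 3 * H), Wh = glorot(H, 3 * H),
       bx = rep(0, 3 * H), bh = rep(0, 3 * H))
}

gru_forward <- function(X, p, H) {
  T_ <- length(X); B <- nrow(X[[1]])
  h <- matrix(0, B, H)
  Hs <- vector("list", T_); cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    zx <- X[[t]] %*% p$Wx + rep(p$bx, each = B)
    zh <- h %*% p$Wh + rep(p$bh, each = B)
    r <- sigm(zx[, 1:H, drop = FALSE] + zh[, 1:H, drop = FALSE])
    z <- sigm(zx[, H + 1:H, drop = FALSE] + zh[, H + 1:H, drop = FALSE])
    zh_n <- zh[, 2 * H + 1:H, drop = FALSE]
    n <- tanh(zx[, 2 * H + 1:H, drop = FALSE] + r * zh_n)
    h_new <- (1 - z) * n + z * h
    cache[[t]] <- list(x = X[[t]], h_prev = h, r = r, z = z, n = n, zh_n = zh_n)
    h <- h_new
    Hs[[t]] <- h
  }
  list(H = Hs, cache = cache)
}

gru_backward <- function(dH, cache, p, H) {
  T_ <- length(cache); B <- nrow(cache[[1]]$x)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; dbx <- p$bx * 0; dbh <- p$bh * 0
  dX <- vector("list", T_)
  dh_next <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    ca <- cache[[t]]
    dh <- dh_next + (dH[[t]] %||% 0)
    dn <- dh * (1 - ca$z)
    dz <- dh * (ca$h_prev - ca$n)
    dh_prev <- dh * ca$z
    dn_pre <- dn * (1 - ca$n^2)
    dr <- dn_pre * ca$zh_n
    dzh_n <- dn_pre * ca$r
    dz_pre <- dz * ca$z * (1 - ca$z)
    dr_pre <- dr * ca$r * (1 - ca$r)
    dzx <- cbind(dr_pre, dz_pre, dn_pre)
    dzh <- cbind(dr_pre, dz_pre, dzh_n)
    dWx <- dWx + crossprod(ca$x, dzx)
    dbx <- dbx + colSums(dzx)
    dWh <- dWh + crossprod(ca$h_prev, dzh)
    dbh <- dbh + colSums(dzh)
    dX[[t]] <- dzx %*% t(p$Wx)
    dh_next <- dh_prev + dzh %*% t(p$Wh)
  }
  list(dX = dX, grads = list(Wx = dWx, Wh = dWh, bx = dbx, bh = dbh))
}

conv1d_init <- function(k, Fin, Fout) {
  list(W = lapply(seq_len(k), function(j) glorot(Fin, Fout)), b = rep(0, Fout))
}

conv1d_forward <- function(X, p) {
  # same-length output with zero padding; kernel tap j sees x_{t + j - 1 - pad}
  T_ <- length(X); B <- nrow(X[[1]]); k <- length(p$W)
  pad <- (k - 1) %/% 2
  Y <- lapply(seq_len(T_), function(t) matrix(rep(p$b, each = B), B))
  for (j in seq_len(k)) {
    for (t in seq_len(T_)) {
      s <- t + j - 1 - pad
      if (s >= 1 && s <= T_) Y[[t]] <- Y[[t]] + X[[s]] %*% p$W[[j]]
    }
  }
  list(Y = Y, X = X)
}

conv1d_backward <- function(dY, cache, p) {
  X <- cache$X
  T_ <- length(X); k <- length(p$W)
  pad <- (k - 1) %/% 2
  dW <- lapply(p$W, function(w) w * 0)
  db <- p$b * 0
  dX <- lapply(X, function(x) x * 0)
  for (t in seq_len(T_)) db <- db + colSums(dY[[t]])
  for (j in seq_len(k)) {
    for (t in seq_len(T_)) {
      s <- t + j - 1 - pad
      if (s >= 1 && s <= T_) {
        dW[[j]] <- dW[[j]] + crossprod(X[[s]], dY[[t]])
        dX[[s]] <- dX[[s]] + dY[[t]] %*% t(p$W[[j]])
      }
    }
  }
  list(dX = dX, grads = list(W = dW, b = db))
}

maxpool_time_forward <- function(X) {
  T_ <- length(X)
  if (T_ == 1L) return(list(Y = X[[1]], which = NULL, T_ = 1L))
  Y <- X[[1]]; which_t <- matrix(1L, nrow(Y), ncol(Y))
  for (t in 2:T_) {
    upd <- X[[t]] > Y
    Y[upd] <- X[[t]][upd]
    which_t[upd] <- t
  }
  list(Y = Y, which = which_t, T_ = T_)
}

maxpool_time_backward <- function(dY, cache) {
  if (cache$T_ == 1L) return(list(dY))
  dX <- lapply(seq_len(cache$T_), function(t) dY * 0)
  for (t in seq_len(cache$T_)) {
    m <- cache$which == t
    dX[[t]][m] <- dY[m]
  }
  dX
}

dense_init <- function(Din, Dout) list(W = glorot(Din, Dout), b = rep(0, Dout))

dense_forward <- function(x, p) x %*% p$W + rep(p$b, each = nrow(x))

dense_backward <- function(dy, x, p) {
  list(dx = dy %*% t(p$W),
       grads = list(W = crossprod(x, dy), b = colSums(dy)))
}

relu <- function(x) pmax(x, 0)

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy loss + gradient wrt logits; y is 1-based class index
softmax_ce <- function(logits, y) {
  p <- softmax(logits)
  B <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(B), y)], 1e-12)))
  dp <- p
  dp[cbind(seq_len(B), y)] <- dp[cbind(seq_len(B), y)] - 1
  list(loss = loss, dlogits = dp / B)
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- matrix(stats::rbinom(length(x), 1, 1 - rate), nrow(x)) / (1 - rate)
  list(y = x * mask, mask = mask)
}

# ---- Adam over an arbitrarily nested parameter list -------------------------

adam_init <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(upd, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- mapply(upd, params, grads, state$m, state$v, SIMPLIFY = FALSE)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = state$t))
}

# ---- recurrent classifier (LSTM / Bi-LSTM stacks) ---------------------------

rnn_clf_init <- function(D, hidden, n_layers, bidirectional, n_classes = 2) {
  layers <- vector("list", n_layers)
  din <- D
  for (l in seq_len(n_layers)) {
    layers[[l]] <- if (bidirectional) {
      list(fwd = lstm_init(din, hidden), bwd = lstm_init(din, hidden))
    } else {
      list(fwd = lstm_init(din, hidden))
    }
    din <- hidden * (1 + bidirectional)
  }
  list(layers = layers, head = dense_init(din, n_classes))
}

rnn_clf_forward <- function(X, params, hidden, bidirectional, dropout = 0,
                            training = FALSE) {
  caches <- list()
  for (l in seq_along(params$layers)) {
    lf <- lstm_forward(X, params$layers[[l]]$fwd, hidden)
    if (bidirectional) {
      lb <- lstm_forward(rev(X), params$layers[[l]]$bwd, hidden)
      Hb <- rev(lb$H)
      X2 <- mapply(cbind, lf$H, Hb, SIMPLIFY = FALSE)
    } else {
      lb <- NULL
      X2 <- lf$H
    }
    dr <- lapply(X2, dropout_forward, rate = dropout, training = training)
    X <- lapply(dr, `[[`, "y")
    caches[[l]] <- list(fwd = lf, bwd = lb, drop = lapply(dr, `[[`, "mask"))
  }
  mp <- maxpool_time_forward(X)
  logits <- dense_forward(mp$Y, params$head)
  list(logits = logits, caches = caches, mp = mp)
}

rnn_clf_backward <- function(dlogits, fw, params, hidden, bidirectional) {
  n_layers <- length(params$layers)
  hd <- dense_backward(dlogits, fw$mp$Y, params$head)
  dX <- maxpool_time_backward(hd$dx, fw$mp)
  glayers <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    ca <- fw$caches[[l]]
    if (!is.null(ca$drop[[1]])) {
      dX <- mapply(function(d, m) d * m, dX, ca$drop, SIMPLIFY = FALSE)
    }
    if (bidirectional) {
      dF <- lapply(dX, function(d) d[, seq_len(hidden), drop = FALSE])
      dB <- lapply(dX, function(d) d[, hidden + seq_len(hidden), drop = FALSE])
      bf <- lstm_backward(dF, ca$fwd$cache, params$layers[[l]]$fwd, hidden)
      bb <- lstm_backward(rev(dB), ca$bwd$cache, params$layers[[l]]$bwd, hidden)
      dX <- mapply(`+`, bf$dX, rev(bb$dX), SIMPLIFY = FALSE)
      glayers[[l]] <- list(fwd = bf$grads, bwd = bb$grads)
    } else {
      bf <- lstm_backward(dX, ca$fwd$cache, params$layers[[l]]$fwd, hidden)
      dX <- bf$dX
      glayers[[l]] <- list(fwd = bf$grads)
    }
  }
  list(layers = glayers, head = hd$grads)
}

# split an array [B, T, D] into a list over time
seq_to_list <- function(arr) {
  T_ <- dim(arr)[2]
  lapply(seq_len(T_), function(t) arr[, t, , drop = TRUE] |>
           matrix(nrow = dim(arr)[1]))
}

train_rnn_classifier <- function(X, y, bidirectional, hidden = 32,
                                 n_layers = if (bidirectional) 3 else 5,
                                 dropout = 0.2, batch_size = 512, epochs = 100,
                                 lr = 1e-3, seed = 1) {
  B <- dim(X)[1]
  withr::with_seed(derive_seed(seed, "rnn-init"), {
    params <- rnn_clf_init(dim(X)[3], hidden, n_layers, bidirectional)
    state <- adam_init(params)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(B)
      for (start in seq(1, B, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, B)]
        Xb <- seq_to_list(X[idx, , , drop = FALSE])
        fw <- rnn_clf_forward(Xb, params, hidden, bidirectional,
                              dropout = dropout, training = TRUE)
        ce <- softmax_ce(fw$logits, y[idx])
        if (!is.finite(ce$loss)) abort("training diverged (non-finite loss)")
        grads <- rnn_clf_backward(ce$dlogits, fw, params, hidden, bidirectional)
        st <- adam_step(params, grads, state, lr = lr)
        params <- st$params; state <- st$state
      }
    }
  })
  list(params = params, hidden = hidden, bidirectional = bidirectional)
}

predict_rnn_classifier <- function(model, X) {
  fw <- rnn_clf_forward(seq_to_list(X), model$params, model$hidden,
                        model$bidirectional, training = FALSE)
  softmax(fw$logits)
}

# ---- GRU + CNN Q-network ----------------------------------------------------

gcql_net_init <- function(D, gru_units, conv_filters, kernel_size,
                          dense_units, n_actions = 2) {
  list(gru = gru_init(D, gru_units),
       conv = conv1d_init(kernel_size, gru_units, conv_filters),
       fc = dense_init(conv_filters, dense_units),
       head = dense_init(dense_units, n_actions))
}

gcql_net_forward <- function(X, params, gru_units) {
  gf <- gru_forward(X, params$gru, gru_units)
  cf <- conv1d_forward(gf$H, params$conv)
  A <- lapply(cf$Y, relu)
  mp <- maxpool_time_forward(A)
  z1 <- dense_forward(mp$Y, params$fc)
  a1 <- relu(z1)
  q <- dense_forward(a1, params$head)
  list(q = q, gf = gf, cf = cf, A = A, mp = mp, z1 = z1, a1 = a1)
}

gcql_net_backward <- function(dq, fw, params, gru_units) {
  hb <- dense_backward(dq, fw$a1, params$head)
  dz1 <- hb$dx * (fw$z1 > 0)
  fb <- dense_backward(dz1, fw$mp$Y, params$fc)
  dA <- maxpool_time_backward(fb$dx, fw$mp)
  dY <- mapply(function(d, y) d * (y > 0), dA, fw$cf$Y, SIMPLIFY = FALSE)
  cb <- conv1d_backward(dY, fw$cf, params$conv)
  gb <- gru_backward(cb$dX, fw$gf$cache, params$gru, gru_units)
  list(gru = gb$grads, conv = cb$grads, fc = fb$grads, head = hb$grads)
}
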