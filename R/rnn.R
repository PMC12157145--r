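# Recurrent hip-ROM predictors (simple RNN / GRU / LSTM), written directly in
# R with batch-vectorized forward passes and analytic backpropagation through
# time, trained with Adam. Input is the per-cycle 100 x 7 tensor (sagittal
# thigh angle waveform, 3D acceleration, 3D angular velocity).

#' Recurrent network specification
#'
#' Architecture: bidirectional recurrent layer (full sequence out), dropout,
#' recurrent layer (last state out), dropout, two dense hidden layers each
#' followed by dropout, then a linear output (regression) or a 3-class
#' softmax (classification). Recurrent candidate and hidden activations are
#' tanh for regression and rectified-linear for classification; losses are
#' mean squared error and sparse categorical cross-entropy.
#'
#' @param cell One of "simple", "gru", "lstm".
#' @param units Units per recurrent layer (>= 1).
#' @param hidden Units per dense hidden layer (default `units`).
#' @param dropout Dropout rate in `[0, 1)`.
#' @param learning_rate Adam learning rate (> 0).
#' @param task "regression" or "classification".
#' @param n_timesteps,n_channels Input shape (default 100 x 7).
#' @param n_classes Number of classes (classification only).
#' @return An `rnn_spec`.
#' @export
rnn_spec <- function(cell = c("gru", "simple", "lstm"), units = 16,
                     hidden = units, dropout = 0.2, learning_rate = 1e-3,
                     task = c("regression", "classification"),
                     n_timesteps = 100L, n_channels = 7L, n_classes = 3L) {
  cell <- match.arg(cell)
  task <- match.arg(task)
  if (units < 1) stop("`units` must be >= 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)", call. = FALSE)
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  structure(list(cell = cell, units = as.integer(units),
                 hidden = as.integer(hidden), dropout = dropout,
                 learning_rate = learning_rate, task = task,
                 n_timesteps = as.integer(n_timesteps),
                 n_channels = as.integer(n_channels),
                 n_classes = as.integer(n_classes)),
            class = "rnn_spec")
}

n_gates <- function(cell) switch(cell, simple = 1L, gru = 3L, lstm = 4L)

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
}

cell_init <- function(cell, input_dim, units) {
  g <- n_gates(cell)
  list(W = glorot(input_dim, g * units),
       U = glorot(units, g * units),
       b = numeric(g * units))
}

act_fun <- function(act, a) if (act == "tanh") tanh(a) else pmax(a, 0)
# derivative expressed via pre-activation a and output h
act_deriv <- function(act, a, h) if (act == "tanh") 1 - h^2 else (a > 0) * 1

sigm <- function(a) 1 / (1 + exp(-a))

# --- recurrent cell forward/backward (batch n, inputs X = list of T n x in) -

cell_forward <- function(cell, p, X, units, act) {
  T_ <- length(X)
  n <- nrow(X[[1L]])
  h <- matrix(0, n, units)
  cst <- matrix(0, n, units)
  H <- vector("list", T_)
  cache <- vector("list", T_)
  idx <- function(g) ((g - 1L) * units + 1L):(g * units)
  for (t in seq_len(T_)) {
    A <- X[[t]] %*% p$W + h %*% p$U + matrix(p$b, n, length(p$b), byrow = TRUE)
    if (cell == "simple") {
      hn <- act_fun(act, A)
      cache[[t]] <- list(a = A, h_prev = h)
    } else if (cell == "gru") {
      z <- sigm(A[, idx(1L), drop = FALSE])
      r <- sigm(A[, idx(2L), drop = FALSE])
      ac <- X[[t]] %*% p$W[, idx(3L), drop = FALSE] +
        (r * h) %*% p$U[, idx(3L), drop = FALSE] +
        matrix(p$b[idx(3L)], n, units, byrow = TRUE)
      cc <- act_fun(act, ac)
      hn <- (1 - z) * h + z * cc
      cache[[t]] <- list(z = z, r = r, ac = ac, cc = cc, h_prev = h)
    } else { # lstm
      i <- sigm(A[, idx(1L), drop = FALSE])
      f <- sigm(A[, idx(2L), drop = FALSE])
      o <- sigm(A[, idx(3L), drop = FALSE])
      ag <- A[, idx(4L), drop = FALSE]
      g <- act_fun(act, ag)
      cn <- f * cst + i * g
      hn <- o * tanh(cn)
      cache[[t]] <- list(i = i, f = f, o = o, ag = ag, g = g,
                         c_prev = cst, c = cn, h_prev = h)
      cst <- cn
    }
    h <- hn
    H[[t]] <- h
  }
  list(H = H, cache = cache)
}

cell_backward <- function(cell, p, X, fw, dH, units, act) {
  T_ <- length(X)
  n <- nrow(X[[1L]])
  idx <- function(g) ((g - 1L) * units + 1L):(g * units)
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dX <- vector("list", T_)
  dh_next <- matrix(0, n, units)
  dc_next <- matrix(0, n, units)
  for (t in rev(seq_len(T_))) {
    ch <- fw$cache[[t]]
    dh <- dh_next + (if (is.null(dH[[t]])) 0 else dH[[t]])
    if (cell == "simple") {
      h <- fw$H[[t]]
      da <- dh * act_deriv(act, ch$a, h)
      dW <- dW + crossprod(X[[t]], da)
      dU <- dU + crossprod(ch$h_prev, da)
      db <- db + colSums(da)
      dX[[t]] <- da %*% t(p$W)
      dh_next <- da %*% t(p$U)
    } else if (cell == "gru") {
      dz <- dh * (ch$cc - ch$h_prev)
      dcc <- dh * ch$z
      dh_prev <- dh * (1 - ch$z)
      dac <- dcc * act_deriv(act, ch$ac, ch$cc)
      daz <- dz * ch$z * (1 - ch$z)
      tmp <- dac %*% t(p$U[, idx(3L), drop = FALSE])
      dr <- tmp * ch$h_prev
      dh_prev <- dh_prev + tmp * ch$r
      dar <- dr * ch$r * (1 - ch$r)
      dA <- cbind(daz, dar, dac)
      dW <- dW + crossprod(X[[t]], dA)
      dU[, idx(1L)] <- dU[, idx(1L), drop = FALSE] + crossprod(ch$h_prev, daz)
      dU[, idx(2L)] <- dU[, idx(2L), drop = FALSE] + crossprod(ch$h_prev, dar)
      dU[, idx(3L)] <- dU[, idx(3L), drop = FALSE] +
        crossprod(ch$r * ch$h_prev, dac)
      db <- db + colSums(dA)
      dX[[t]] <- dA %*% t(p$W)
      dh_next <- dh_prev +
        daz %*% t(p$U[, idx(1L), drop = FALSE]) +
        dar %*% t(p$U[, idx(2L), drop = FALSE])
    } else { # lstm
      tc <- tanh(ch$c)
      do_ <- dh * tc
      dao <- do_ * ch$o * (1 - ch$o)
      dc <- dc_next + dh * ch$o * (1 - tc^2)
      di <- dc * ch$g
      df <- dc * ch$c_prev
      dg <- dc * ch$i
      dai <- di * ch$i * (1 - ch$i)
      daf <- df * ch$f * (1 - ch$f)
      dag <- dg * act_deriv(act, ch$ag, ch$g)
      dA <- cbind(dai, daf, dao, dag)
      dW <- dW + crossprod(X[[t]], dA)
      dU <- dU + crossprod(ch$h_prev, dA)
      db <- db + colSums(dA)
      dX[[t]] <- dA %*% t(p$W)
      dh_next <- dA %*% t(p$U)
      dc_next <- dc * ch$f
    }
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

#' Build a trainable recurrent network
#'
#' Initializes all weights (Glorot normal) for the architecture described in
#' [rnn_spec()].
#'
#' @param spec An [rnn_spec()].
#' @param seed Integer seed for the weight initialization.
#' @return An `rnn_model` (untrained until passed to [train_rnn()]).
#' @export
build_rnn <- function(spec, seed = 17) {
  stopifnot(inherits(spec, "rnn_spec"))
  u <- spec$units
  hdim <- spec$hidden
  nout <- if (spec$task == "classification") spec$n_classes else 1L
  params <- with_preserved_seed(as.integer(seed), list(
    fwd = cell_init(spec$cell, spec$n_channels, u),
    bwd = cell_init(spec$cell, spec$n_channels, u),
    rec2 = cell_init(spec$cell, 2L * u, u),
    dense1 = list(W = glorot(u, hdim), b = numeric(hdim)),
    dense2 = list(W = glorot(hdim, hdim), b = numeric(hdim)),
    out = list(W = glorot(hdim, nout), b = numeric(nout))
  ))
  structure(list(spec = spec, params = params, standardizer = NULL,
                 history = numeric(0)),
            class = "rnn_model")
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf(
    "<rnn_model> %s (%s), %d units, dropout %.2f%s\n",
    x$spec$cell, x$spec$task, x$spec$units, x$spec$dropout,
    if (length(x$history)) sprintf(", trained %d epochs (loss %.4g)",
                                   length(x$history), utils::tail(x$history, 1))
    else " (untrained)"
  ))
  invisible(x)
}

# forward pass; X is an n x T x C array. In training mode, dropout masks are
# drawn from the ambient RNG and the full cache is kept for backprop.
rnn_forward <- function(model, X, training = FALSE) {
  spec <- model$spec
  p <- model$params
  act <- if (spec$task == "regression") "tanh" else "relu"
  n <- dim(X)[1L]; T_ <- dim(X)[2L]
  Xl <- lapply(seq_len(T_), function(t) X[, t, , drop = FALSE][, 1L, , drop = TRUE])
  Xl <- lapply(Xl, function(m) if (is.null(dim(m))) matrix(m, nrow = n) else m)
  f1 <- cell_forward(spec$cell, p$fwd, Xl, spec$units, act)
  b1 <- cell_forward(spec$cell, p$bwd, rev(Xl), spec$units, act)
  H1 <- lapply(seq_len(T_), function(t) cbind(f1$H[[t]], b1$H[[T_ - t + 1L]]))
  drop_mask <- function(dims) {
    if (training && spec$dropout > 0) {
      matrix(stats::rbinom(prod(dims), 1L, 1 - spec$dropout), dims[1L], dims[2L]) /
        (1 - spec$dropout)
    } else {
      NULL
    }
  }
  m1 <- drop_mask(c(n, 2L * spec$units))  # same mask across time steps
  H1d <- if (is.null(m1)) H1 else lapply(H1, function(h) h * m1)
  f2 <- cell_forward(spec$cell, p$rec2, H1d, spec$units, act)
  h2 <- f2$H[[T_]]
  m2 <- drop_mask(dim(h2))
  h2d <- if (is.null(m2)) h2 else h2 * m2
  a3 <- h2d %*% p$dense1$W + matrix(p$dense1$b, n, length(p$dense1$b), byrow = TRUE)
  h3 <- act_fun(act, a3)
  m3 <- drop_mask(dim(h3))
  h3d <- if (is.null(m3)) h3 else h3 * m3
  a4 <- h3d %*% p$dense2$W + matrix(p$dense2$b, n, length(p$dense2$b), byrow = TRUE)
  h4 <- act_fun(act, a4)
  m4 <- drop_mask(dim(h4))
  h4d <- if (is.null(m4)) h4 else h4 * m4
  out <- h4d %*% p$out$W + matrix(p$out$b, n, ncol(p$out$W), byrow = TRUE)
  if (spec$task == "classification") {
    z <- out - apply(out, 1L, max)
    probs <- exp(z) / rowSums(exp(z))
  } else {
    probs <- NULL
  }
  list(out = out, probs = probs, Xl = Xl, f1 = f1, b1 = b1, H1 = H1,
       H1d = H1d, f2 = f2, h2 = h2, h2d = h2d, a3 = a3, h3 = h3, h3d = h3d,
       a4 = a4, h4 = h4, h4d = h4d,
       masks = list(m1 = m1, m2 = m2, m3 = m3, m4 = m4))
}

rnn_loss_grad <- function(model, fw, y) {
  spec <- model$spec
  n <- nrow(fw$out)
  if (spec$task == "regression") {
    r <- fw$out[, 1L] - y
    loss <- mean(r^2)
    dout <- matrix(2 * r / n, n, 1L)
  } else {
    onehot <- matrix(0, n, spec$n_classes)
    onehot[cbind(seq_len(n), as.integer(y))] <- 1
    loss <- -mean(log(pmax(fw$probs[cbind(seq_len(n), as.integer(y))], 1e-12)))
    dout <- (fw$probs - onehot) / n
  }
  list(loss = loss, dout = dout)
}

rnn_backward <- function(model, fw, dout) {
  spec <- model$spec
  p <- model$params
  act <- if (spec$task == "regression") "tanh" else "relu"
  T_ <- length(fw$Xl)
  g <- list()
  g$out <- list(W = crossprod(fw$h4d, dout), b = colSums(dout))
  dh4d <- dout %*% t(p$out$W)
  dh4 <- if (is.null(fw$masks$m4)) dh4d else dh4d * fw$masks$m4
  da4 <- dh4 * act_deriv(act, fw$a4, fw$h4)
  g$dense2 <- list(W = crossprod(fw$h3d, da4), b = colSums(da4))
  dh3d <- da4 %*% t(p$dense2$W)
  dh3 <- if (is.null(fw$masks$m3)) dh3d else dh3d * fw$masks$m3
  da3 <- dh3 * act_deriv(act, fw$a3, fw$h3)
  g$dense1 <- list(W = crossprod(fw$h2d, da3), b = colSums(da3))
  dh2d <- da3 %*% t(p$dense1$W)
  dh2 <- if (is.null(fw$masks$m2)) dh2d else dh2d * fw$masks$m2
  dH2 <- vector("list", T_)
  dH2[[T_]] <- dh2
  bk2 <- cell_backward(spec$cell, p$rec2, fw$H1d, fw$f2, dH2, spec$units, act)
  g$rec2 <- list(W = bk2$dW, U = bk2$dU, b = bk2$db)
  dH1 <- if (is.null(fw$masks$m1)) bk2$dX else
    lapply(bk2$dX, function(d) d * fw$masks$m1)
  u <- spec$units
  dHf <- lapply(dH1, function(d) d[, seq_len(u), drop = FALSE])
  dHb <- lapply(rev(dH1), function(d) d[, u + seq_len(u), drop = FALSE])
  Xl <- fw$Xl
  bkf <- cell_backward(spec$cell, p$fwd, Xl, fw$f1, dHf, u, act)
  bkb <- cell_backward(spec$cell, p$bwd, rev(Xl), fw$b1, dHb, u, act)
  g$fwd <- list(W = bkf$dW, U = bkf$dU, b = bkf$db)
  g$bwd <- list(W = bkb$dW, U = bkb$dU, b = bkb$db)
  # same order as model$params: the Adam walk pairs leaves positionally
  g[c("fwd", "bwd", "rec2", "dense1", "dense2", "out")]
}

# Adam over the nested parameter list
adam_init <- function(params) {
  zeros <- function(x) if (is.list(x)) lapply(x, zeros) else x * 0
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mh <- m / (1 - beta1^state$t)
      vh <- v / (1 - beta2^state$t)
      list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = state$t))
}

#' Train a recurrent network
#'
#' Mini-batch Adam on the specified loss; the per-epoch mean training loss
#' is appended to the model's `history`. Dropout is active during training
#' only. Deterministic for a fixed seed.
#'
#' @param model A [build_rnn()] model.
#' @param X Input tensor, `n x timesteps x channels` array (standardize with
#'   [tensor_standardizer_fit()] first; fold-local in cross-validation).
#' @param y Targets: degrees (regression) or classes 1..K (classification).
#' @param epochs Training epochs (default 30).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed for shuffling and dropout.
#' @return The trained `rnn_model`.
#' @export
train_rnn <- function(model, X, y, epochs = 30, batch_size = 32, seed = 17) {
  stopifnot(inherits(model, "rnn_model"))
  n <- dim(X)[1L]
  state <- adam_init(model$params)
  with_preserved_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- X[idx, , , drop = FALSE]
        fw <- rnn_forward(model, Xb, training = TRUE)
        lg <- rnn_loss_grad(model, fw, y[idx])
        grads <- rnn_backward(model, fw, lg$dout)
        upd <- adam_step(model$params, grads, state,
                         lr = model$spec$learning_rate)
        model$params <- upd$params
        state <- upd$state
        losses <- c(losses, lg$loss)
      }
      model$history <- c(model$history, mean(losses))
    }
  })
  model
}

#' @export
predict.rnn_model <- function(object, newdata, type = c("response", "prob"),
                              ...) {
  type <- match.arg(type)
  fw <- rnn_forward(object, newdata, training = FALSE)
  if (object$spec$task == "regression") {
    as.numeric(fw$out[, 1L])
  } else if (type == "prob") {
    fw$probs
  } else {
    max.col(fw$probs, ties.method = "first")
  }
}

#' Per-channel standardization for cycle tensors
#'
#' Means and SDs computed per channel over all cycles and time steps of the
#' training set; apply to training and test tensors alike (never fit on test
#' data).
#'
#' @param X `n x timesteps x channels` array.
#' @return A `tensor_standardizer`.
#' @export
tensor_standardizer_fit <- function(X) {
  C <- dim(X)[3L]
  mu <- vapply(seq_len(C), function(c) mean(X[, , c]), numeric(1))
  sd_ <- vapply(seq_len(C), function(c) {
    s <- stats::sd(as.numeric(X[, , c]))
    if (s < 1e-12) 1 else s
  }, numeric(1))
  structure(list(mean = mu, sd = sd_), class = "tensor_standardizer")
}

#' @rdname tensor_standardizer_fit
#' @param std A `tensor_standardizer`.
#' @export
tensor_standardizer_apply <- function(std, X) {
  for (c in seq_len(dim(X)[3L])) {
    X[, , c] <- (X[, , c] - std$mean[c]) / std$sd[c]
  }
  X
}
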