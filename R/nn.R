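# Minimal dense-tensor neural network primitives used by the risk network.
# All convolutions are 3x3, stride 1, zero-padded ("same"); pooling is 2x2
# max. Forward passes return caches sufficient for exact reverse-mode
# gradients; correctness is pinned against finite differences in the tests.
# Everything is vectorised through im2col + BLAS matrix products.

# block-mean pooling matrix mapping a length-`from` axis onto `to` bins;
# `from` must be a multiple of `to`
nn_pool_matrix <- function(from, to) {
  if (from %% to != 0)
    stop(sprintf("image side %d is not a multiple of the backbone input size %d",
                 from, to))
  f <- from / to
  P <- matrix(0, to, from)
  for (i in seq_len(to)) P[i, ((i - 1) * f + 1):(i * f)] <- 1 / f
  P
}

nn_downsample <- function(x, P) P %*% x %*% t(P)

# memoized linear-index maps from padded tensors to patch matrices, keyed by
# the input shape; makes im2col a single gather and col2im a single rowsum
.nn_idx_cache <- new.env(parent = emptyenv())

nn_im2col_idx <- function(H, W, C) {
  key <- paste(H, W, C, sep = "x")
  hit <- .nn_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  idx <- matrix(0L, H * W, 9L * C)
  k <- 1L
  for (ch in seq_len(C)) for (dx in 0:2) for (dy in 0:2) {
    rows <- dy + seq_len(H)
    cols <- dx + seq_len(W)
    idx[, k] <- as.integer(outer(rows, (cols - 1L) * Hp, "+") +
                             (ch - 1L) * Hp * Wp)
    k <- k + 1L
  }
  # interior (unpadded) positions of the padded tensor, for fast padding
  interior <- as.integer(outer(outer(1L + seq_len(H), seq_len(W) * Hp, "+"),
                               (seq_len(C) - 1L) * Hp * Wp, "+"))
  # sparse scatter-add operator for col2im: padded gradient = S %*% c(dcols)
  scatter <- Matrix::sparseMatrix(i = c(idx), j = seq_along(idx), x = 1,
                                  dims = c(Hp * Wp * C, length(idx)))
  out <- list(idx = idx, interior = interior, padded_len = Hp * Wp * C,
              scatter = scatter)
  .nn_idx_cache[[key]] <- out
  out
}

# unroll a zero-padded HxWxC tensor into an (H*W) x (9*C) patch matrix;
# column order (kernel y fastest, then kernel x, then channel) matches the
# conv weight layout produced in svn_init_params
nn_conv_forward <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]
  maps <- nn_im2col_idx(H, Wd, C)
  xp <- numeric(maps$padded_len)
  xp[maps$interior] <- x
  cols <- xp[maps$idx]
  dim(cols) <- c(H * Wd, 9L * C)
  y <- cols %*% W
  y <- y + rep(b, each = nrow(y))
  dim(y) <- c(H, Wd, length(b))
  list(out = y, cols = cols, in_dim = d)
}

nn_conv_backward <- function(cache, W, dout, need_dx = TRUE) {
  d <- cache$in_dim; H <- d[1]; Wd <- d[2]; C <- d[3]
  dY <- dout
  dim(dY) <- c(H * Wd, ncol(W))
  dW <- crossprod(cache$cols, dY)
  db <- colSums(dY)
  if (!need_dx) return(list(dx = NULL, dW = dW, db = db))
  maps <- nn_im2col_idx(H, Wd, C)
  dcols <- dY %*% t(W)
  dim(dcols) <- NULL
  dx <- as.numeric(maps$scatter %*% dcols)[maps$interior]
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

nn_maxpool_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  i1 <- seq.int(1L, H, 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, W, 2L); j2 <- j1 + 1L
  a <- x[i1, j1, , drop = FALSE]; b <- x[i2, j1, , drop = FALSE]
  cc <- x[i1, j2, , drop = FALSE]; dd <- x[i2, j2, , drop = FALSE]
  out <- pmax(pmax(a, b), pmax(cc, dd))
  # ties route the gradient to the first window position attaining the max
  m1 <- a >= out
  m2 <- !m1 & b >= out
  m3 <- !m1 & !m2 & cc >= out
  m4 <- !(m1 | m2 | m3)
  list(out = out, masks = list(m1, m2, m3, m4), in_dim = d)
}

nn_maxpool_backward <- function(cache, dout) {
  d <- cache$in_dim
  i1 <- seq.int(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq.int(1L, d[2], 2L); j2 <- j1 + 1L
  dx <- array(0, d)
  dx[i1, j1, ] <- dout * cache$masks[[1]]
  dx[i2, j1, ] <- dout * cache$masks[[2]]
  dx[i1, j2, ] <- dout * cache$masks[[3]]
  dx[i2, j2, ] <- dout * cache$masks[[4]]
  dx
}

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# single LSTM layer unrolled over a short list of input vectors; gate order
# within the 4h-wide weight blocks is (input, forget, output, candidate)
nn_lstm_forward <- function(xs, Wx, Wh, b) {
  h_dim <- ncol(Wh) / 4L
  h <- numeric(h_dim); cst <- numeric(h_dim)
  steps <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    x <- xs[[t]]
    z <- drop(crossprod(Wx, x)) + drop(crossprod(Wh, h)) + b
    i <- nn_sigmoid(z[seq_len(h_dim)])
    f <- nn_sigmoid(z[h_dim + seq_len(h_dim)])
    o <- nn_sigmoid(z[2L * h_dim + seq_len(h_dim)])
    g <- tanh(z[3L * h_dim + seq_len(h_dim)])
    c_new <- f * cst + i * g
    tc <- tanh(c_new)
    steps[[t]] <- list(x = x, h_prev = h, c_prev = cst,
                       i = i, f = f, o = o, g = g, c = c_new, tc = tc)
    h <- o * tc
    cst <- c_new
  }
  list(h = h, steps = steps)
}

nn_lstm_backward <- function(cache, Wx, Wh, dh_last) {
  h_dim <- length(dh_last)
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- numeric(4L * h_dim)
  dxs <- vector("list", length(cache$steps))
  dh <- dh_last; dc <- numeric(h_dim)
  for (t in rev(seq_along(cache$steps))) {
    s <- cache$steps[[t]]
    do <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    df <- dc * s$c_prev
    dg <- dc * s$i
    dz <- c(di * s$i * (1 - s$i),
            df * s$f * (1 - s$f),
            do * s$o * (1 - s$o),
            dg * (1 - s$g^2))
    dWx <- dWx + outer(s$x, dz)
    dWh <- dWh + outer(s$h_prev, dz)
    db <- db + dz
    dxs[[t]] <- drop(Wx %*% dz)
    dh <- drop(Wh %*% dz)
    dc <- dc * s$f
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

nn_dense_forward <- function(x, W, b) drop(crossprod(W, x)) + b

nn_dense_backward <- function(x, W, dy) {
  list(dx = drop(W %*% dy), dW = outer(x, dy), db = dy)
}

# Adam with bias correction; state carries first/second moments and the step
nn_adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

nn_adam_step <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# elementwise accumulation of two grad lists sharing names
nn_grad_add <- function(acc, g) {
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}
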