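## Gated recurrent unit primitives in plain linear algebra. Row-vector
## convention throughout: inputs x and hidden states h are length-d
## numeric vectors, weights are (input_dim x hidden) / (hidden x hidden)
## matrices, and a step computes
##   z = sigmoid(x Wz + h Uz + bz)
##   r = sigmoid(x Wr + h Ur + br)
##   n = tanh(x Wn + (r * h) Un + bn)
##   h' = (1 - z) * h + z * n
## Analytic backward passes mirror each forward and are verified against
## finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

gru_init <- function(input_dim, hidden, gen) {
  sd_in <- 1 / sqrt(input_dim)
  sd_h <- 1 / sqrt(hidden)
  list(
    Wz = matrix(gen(input_dim * hidden, sd_in), input_dim, hidden),
    Uz = matrix(gen(hidden * hidden, sd_h), hidden, hidden),
    bz = numeric(hidden),
    Wr = matrix(gen(input_dim * hidden, sd_in), input_dim, hidden),
    Ur = matrix(gen(hidden * hidden, sd_h), hidden, hidden),
    br = numeric(hidden),
    Wn = matrix(gen(input_dim * hidden, sd_in), input_dim, hidden),
    Un = matrix(gen(hidden * hidden, sd_h), hidden, hidden),
    bn = numeric(hidden)
  )
}

gru_zero_grad <- function(w) lapply(w, function(x) x * 0)

## One GRU step. Returns the new hidden state plus the cache needed by the
## backward pass.
gru_cell_forward <- function(x, h, w) {
  z <- sigmoid(as.vector(x %*% w$Wz) + as.vector(h %*% w$Uz) + w$bz)
  r <- sigmoid(as.vector(x %*% w$Wr) + as.vector(h %*% w$Ur) + w$br)
  rh <- r * h
  n <- tanh(as.vector(x %*% w$Wn) + as.vector(rh %*% w$Un) + w$bn)
  h_new <- (1 - z) * h + z * n
  list(h = h_new, cache = list(x = x, h_prev = h, z = z, r = r, n = n, rh = rh))
}

## Backward through one GRU step: given d h_new, returns d x, d h_prev and
## accumulates parameter gradients into `grad` (same structure as weights).
gru_cell_backward <- function(dh_new, cache, w, grad) {
  z <- cache$z; r <- cache$r; n <- cache$n
  h_prev <- cache$h_prev; x <- cache$x
  dn <- dh_new * z
  dz <- dh_new * (n - h_prev)
  dh_prev <- dh_new * (1 - z)

  dan <- dn * (1 - n^2)
  grad$Wn <- grad$Wn + outer(x, dan)
  grad$Un <- grad$Un + outer(cache$rh, dan)
  grad$bn <- grad$bn + dan
  drh <- as.vector(w$Un %*% dan)
  dr <- drh * h_prev
  dh_prev <- dh_prev + drh * r

  daz <- dz * z * (1 - z)
  dar <- dr * r * (1 - r)
  grad$Wz <- grad$Wz + outer(x, daz)
  grad$Uz <- grad$Uz + outer(h_prev, daz)
  grad$bz <- grad$bz + daz
  grad$Wr <- grad$Wr + outer(x, dar)
  grad$Ur <- grad$Ur + outer(h_prev, dar)
  grad$br <- grad$br + dar

  dh_prev <- dh_prev + as.vector(w$Uz %*% daz) + as.vector(w$Ur %*% dar)
  dx <- as.vector(w$Wz %*% daz) + as.vector(w$Wr %*% dar) +
    as.vector(w$Wn %*% dan)
  list(dx = dx, dh_prev = dh_prev, grad = grad)
}

## Run a unidirectional GRU over the rows of X (L x input_dim), zero
## initial state. Returns the L x hidden state matrix and per-step caches.
gru_run <- function(X, w) {
  L <- nrow(X)
  hidden <- length(w$bz)
  H <- matrix(0, L, hidden)
  caches <- vector("list", L)
  h <- numeric(hidden)
  for (t in seq_len(L)) {
    step <- gru_cell_forward(X[t, ], h, w)
    h <- step$h
    H[t, ] <- h
    caches[[t]] <- step$cache
  }
  list(H = H, caches = caches)
}

## Backward through gru_run: dH is L x hidden; returns dX and gradients.
gru_run_backward <- function(dH, caches, w) {
  L <- nrow(dH)
  grad <- gru_zero_grad(w)
  dX <- matrix(0, L, nrow(w$Wz))
  dh <- numeric(ncol(dH))
  for (t in rev(seq_len(L))) {
    dh_total <- dh + dH[t, ]
    bk <- gru_cell_backward(dh_total, caches[[t]], w, grad)
    grad <- bk$grad
    dX[t, ] <- bk$dx
    dh <- bk$dh_prev
  }
  list(dX = dX, grad = grad)
}

## Bidirectional GRU: forward pass over rows 1..L and a second pass over
## the reversed rows; outputs concatenated per residue.
bigru_forward <- function(X, w_fwd, w_bwd) {
  fwd <- gru_run(X, w_fwd)
  bwd <- gru_run(X[rev(seq_len(nrow(X))), , drop = FALSE], w_bwd)
  P <- cbind(fwd$H, bwd$H[rev(seq_len(nrow(X))), , drop = FALSE])
  list(P = P, fwd = fwd, bwd = bwd)
}

bigru_backward <- function(dP, ctx, w_fwd, w_bwd) {
  hidden <- length(w_fwd$bz)
  L <- nrow(dP)
  d_fwd <- dP[, seq_len(hidden), drop = FALSE]
  d_bwd <- dP[rev(seq_len(L)), hidden + seq_len(hidden), drop = FALSE]
  bf <- gru_run_backward(d_fwd, ctx$fwd$caches, w_fwd)
  bb <- gru_run_backward(d_bwd, ctx$bwd$caches, w_bwd)
  dX <- bf$dX + bb$dX[rev(seq_len(L)), , drop = FALSE]
  list(dX = dX, grad_fwd = bf$grad, grad_bwd = bb$grad)
}
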