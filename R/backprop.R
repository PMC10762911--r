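## Analytic gradients of the joint binary cross-entropy loss with respect
## to every trainable tensor. The structure mirrors gim_forward_full:
## head layers -> (max-pool routing for the disorder head) -> graph
## convolution -> feature mapping -> attention GRU (including the
## attention-score coupling through h_{i-1}) -> bidirectional GRU.
## Verified against central finite differences in the test suite.

zero_like_params <- function(params) {
  g <- list(
    bigru_fwd = gru_zero_grad(params$bigru_fwd),
    bigru_bwd = gru_zero_grad(params$bigru_bwd),
    W_a = params$W_a * 0,
    attn_gru = gru_zero_grad(params$attn_gru),
    W_map = lapply(params$W_map, function(x) x * 0),
    b_map = lapply(params$b_map, function(x) x * 0),
    W_gcn = lapply(params$W_gcn, function(x) x * 0),
    b_gcn = lapply(params$b_gcn, function(x) x * 0),
    adjacency = params$adjacency * 0,
    W_head = lapply(params$W_head, function(x) x * 0),
    b_head = lapply(params$b_head, function(x) x * 0)
  )
  g
}

## Loss + gradient for one protein. fw is a gim_forward_full() result
## computed with training caches; labels is L x 7; mask is an optional
## L-vector of 0/1 observation weights (1 = residue contributes).
gim_backward <- function(fw, params, labels, mask = NULL,
                           head_weights = rep(1, 7)) {
  L <- nrow(fw$scores)
  if (is.null(mask)) mask <- rep(1, L)
  n_obs <- sum(mask)
  if (n_obs == 0) abort("All residues are masked; nothing to learn from")
  eps <- 1e-7
  hw <- head_weights / sum(head_weights)
  p <- pmin(pmax(fw$scores, eps), 1 - eps)
  y <- labels
  per_head <- -colSums(mask * (y * log(p) + (1 - y) * log(1 - p))) / n_obs
  loss <- sum(hw * per_head)

  ## d loss / d logit for sigmoid + BCE is (p - y), scaled by averaging.
  dlogits <- sweep((unclass(p) - y) * (mask / n_obs), 2, hw, `*`)

  grad <- zero_like_params(params)
  F <- length(params$b_map[[1]])

  ## --- heads ---
  dhead_in <- lapply(1:6, function(n) matrix(0, L, F))
  dpooled <- outer(dlogits[, 1], params$W_head[[1]])
  grad$W_head[[1]] <- as.vector(crossprod(fw$pooled, dlogits[, 1]))
  grad$b_head[[1]] <- sum(dlogits[, 1])
  for (n in 1:6) {
    grad$W_head[[n + 1]] <- as.vector(crossprod(fw$head_in[[n]],
                                                dlogits[, n + 1]))
    grad$b_head[[n + 1]] <- sum(dlogits[, n + 1])
    dhead_in[[n]] <- dhead_in[[n]] + outer(dlogits[, n + 1],
                                           params$W_head[[n + 1]])
  }

  ## --- max-pool routing: disorder gradient flows to the winning node ---
  for (n in 1:6) {
    sel <- (fw$argmax == n) * dpooled
    dhead_in[[n]] <- dhead_in[[n]] + sel
  }

  ## --- graph convolution ---
  adj <- params$adjacency
  dX <- lapply(1:6, function(n) matrix(0, L, F))
  if (fw$use_gcn) {
    for (n in 1:6) {
      S <- Reduce(`+`, lapply(1:6, function(m) adj[n, m] * fw$X[[m]]))
      pre <- S %*% params$W_gcn[[n]] +
        matrix(params$b_gcn[[n]], L, F, byrow = TRUE)
      dpre <- dhead_in[[n]] * (pre > 0)
      grad$W_gcn[[n]] <- crossprod(S, dpre)
      grad$b_gcn[[n]] <- colSums(dpre)
      dS <- dpre %*% t(params$W_gcn[[n]])
      for (m in 1:6) {
        grad$adjacency[n, m] <- grad$adjacency[n, m] + sum(dS * fw$X[[m]])
        dX[[m]] <- dX[[m]] + adj[n, m] * dS
      }
    }
  } else {
    dX <- dhead_in
  }

  ## --- feature mapping ---
  H <- fw$H
  dH <- matrix(0, L, ncol(H))
  for (n in 1:6) {
    pre <- H %*% params$W_map[[n]] +
      matrix(params$b_map[[n]], L, F, byrow = TRUE)
    dpre <- dX[[n]] * (pre > 0)
    grad$W_map[[n]] <- crossprod(H, dpre)
    grad$b_map[[n]] <- colSums(dpre)
    dH <- dH + dpre %*% t(params$W_map[[n]])
  }
  if (!is.null(fw$drop_mask)) dH <- dH * fw$drop_mask

  ## --- attention GRU (backward over steps, including attention path) ---
  att <- fw$att
  P <- fw$enc$P
  dP <- matrix(0, nrow(P), ncol(P))
  gru_w <- params$attn_gru
  dh_next <- numeric(ncol(H))
  for (i in rev(seq_len(L))) {
    cache <- att$caches[[i]]
    dh_total <- dh_next + dH[i, ]
    bk <- gru_cell_backward(dh_total, cache$gru, gru_w, grad$attn_gru)
    grad$attn_gru <- bk$grad
    dci <- bk$dx
    dh_prev <- bk$dh_prev

    ## c_i = sum_j alpha_ij p_j
    w_i <- cache$weights
    dP <- dP + outer(w_i, dci)
    dalpha <- as.vector(P %*% dci)
    ## softmax backward
    ds <- w_i * (dalpha - sum(w_i * dalpha))
    ## s_ij = h_prev^T W_a p_j ;  q = h_prev W_a (length 2H)
    q <- as.vector(cache$h_prev %*% params$W_a)
    dq <- as.vector(crossprod(P, ds))
    dP <- dP + outer(ds, q)
    grad$W_a <- grad$W_a + outer(cache$h_prev, dq)
    dh_prev <- dh_prev + as.vector(params$W_a %*% dq)

    dh_next <- dh_prev
  }

  ## --- bidirectional GRU ---
  bb <- bigru_backward(dP, fw$enc, params$bigru_fwd, params$bigru_bwd)
  grad$bigru_fwd <- bb$grad_fwd
  grad$bigru_bwd <- bb$grad_bwd

  list(loss = loss, grad = grad)
}

## Flatten/unflatten parameter lists for the optimizer and for finite
## difference checks.
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(flat, template) {
  rel <- utils::relist(flat, lapply(template, function(x) {
    if (is.list(x)) lapply(x, function(y) y * 0) else x * 0
  }))
  out <- template
  for (nm in names(template)) {
    if (is.list(template[[nm]])) {
      for (k in seq_along(template[[nm]])) {
        v <- template[[nm]][[k]]
        r <- rel[[nm]][[k]]
        out[[nm]][[k]] <- if (is.matrix(v)) {
          matrix(r, nrow(v), ncol(v))
        } else as.numeric(r)
      }
    } else {
      v <- template[[nm]]
      out[[nm]] <- if (is.matrix(v)) matrix(rel[[nm]], nrow(v), ncol(v)) else
        as.numeric(rel[[nm]])
    }
  }
  attributes(out) <- attributes(template)
  out
}
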