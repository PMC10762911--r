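test_that("forward emits valid propensities and preserves length", {
  params <- tiny_model()
  for (L in c(1L, 2L, 50L)) {
    emb <- random_embedding(L, 4, seed = L)
    prof <- gim_forward(emb, params, protein_id = "P")
    expect_equal(nrow(prof), L)
    expect_equal(ncol(prof), 7L)
    expect_true(all(prof > 0 & prof < 1))
    expect_true(all(is.finite(prof)))
  }
  ## determinism in inference mode
  emb <- random_embedding(10, 4, seed = 2)
  expect_identical(unclass_profile(gim_forward(emb, params)),
                   unclass_profile(gim_forward(emb, params)))
  ## dimension mismatch
  expect_error(gim_forward(matrix(0, 3, 5), params), "dimension")
  ## property: random embeddings never produce NaN/Inf
  withr::local_seed(90)
  for (rep in 1:20) {
    emb <- matrix(rnorm(sample(1:30, 1) * 4, sd = runif(1, 0.1, 10)),
                  ncol = 4)
    prof <- gim_forward(emb, params)
    expect_true(all(is.finite(prof)) && all(prof > 0 & prof < 1))
  }
})

test_that("bidirectional encoder is symmetric under sequence reversal", {
  params <- tiny_model(seed = 11)
  emb <- random_embedding(7, 4, seed = 3)
  P <- encode_context(emb, params)
  ## swapping the direction blocks and reversing the input reproduces the
  ## original rows in reverse order
  params_swapped <- params
  params_swapped$bigru_fwd <- params$bigru_bwd
  params_swapped$bigru_bwd <- params$bigru_fwd
  P_rev <- encode_context(emb[7:1, ], params_swapped)
  H <- length(params$bigru_fwd$bz)
  expect_equal(P_rev[7:1, c(H + 1:H, 1:H)], P, tolerance = 1e-12)
  ## L = 1 boundary
  expect_equal(nrow(encode_context(random_embedding(1, 4), params)), 1L)
})

test_that("attention weights are a proper softmax", {
  params <- tiny_model(seed = 2)
  emb <- random_embedding(9, 4, seed = 4)
  P <- encode_context(emb, params)
  att <- attention_gru(P, params)
  expect_equal(unname(rowSums(att$weights)), rep(1, 9), tolerance = 1e-6)
  expect_true(all(att$weights >= 0))
  ## first step queries with h0 = 0: scores all zero -> uniform weights
  expect_equal(unname(att$weights[1, ]), rep(1 / 9, 9), tolerance = 1e-12)

  ## closed-form softmax and shift invariance via attention_weights()
  h <- rnorm(3)
  W <- diag(1, 3, 4)
  P2 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  aw <- attention_weights(c(log(2), 0, 0), P2, diag(1, 3, 4))
  expect_equal(aw$weights, c(2 / 3, 1 / 3), tolerance = 1e-12)
  aw_shift <- attention_weights(h, P, params$W_a)
  shifted <- list(scores = aw_shift$scores + 5)
  w2 <- exp(shifted$scores - max(shifted$scores))
  expect_equal(aw_shift$weights, w2 / sum(w2), tolerance = 1e-9)

  ## L = 1: alpha_11 = 1 and c_1 = p_1
  P1 <- encode_context(random_embedding(1, 4), params)
  att1 <- attention_gru(P1, params)
  expect_equal(att1$weights[1, 1], 1)
  expect_equal(att1$context[1, ], P1[1, ])
})

test_that("attention is global, the recurrence is causal", {
  params <- tiny_model(seed = 6)
  emb <- random_embedding(6, 4, seed = 5)
  base <- attention_gru(encode_context(emb, params), params)
  emb2 <- emb
  emb2[5, ] <- emb2[5, ] + 1  # perturb a late residue
  pert <- attention_gru(encode_context(emb2, params), params)
  ## c_1 sees the whole sequence, so it must change
  expect_gt(max(abs(pert$context[1, ] - base$context[1, ])), 0)
  ## the first hidden state is GRU(h0, c1); it changes only through c1 —
  ## verify h depends on later residues at all (global, not causal input)
  expect_gt(max(abs(pert$hidden[1, ] - base$hidden[1, ])), 0)
})

test_that("feature mapping matches the matrix-product oracle", {
  params <- tiny_model(seed = 3)
  withr::local_seed(44)
  h <- rnorm(3)
  X <- map_function_features(h, params)
  for (n in 1:6) {
    oracle <- pmax(as.vector(h %*% params$W_map[[n]]) + params$b_map[[n]], 0)
    expect_equal(X[[n]], oracle, tolerance = 1e-6)
    expect_true(all(X[[n]] >= 0))
  }
  ## zero input, zero bias -> zero features
  p0 <- params
  for (n in 1:6) p0$b_map[[n]] <- numeric(2)
  X0 <- map_function_features(numeric(3), p0)
  expect_true(all(unlist(X0) == 0))
})

test_that("adjacency initialization copies IG off-diagonals", {
  withr::local_seed(10)
  labs <- random_label_set(2, 50, 0.3)
  ig <- ig_matrix(labs)
  adj <- init_adjacency(ig, self_loop = 1)
  expect_equal(unname(diag(adj)), rep(1, 6))
  off <- upper.tri(adj)
  expect_equal(adj[off], unclass(ig)[off])
  ## zero IG -> identity-like adjacency
  ig0 <- structure(matrix(0, 6, 6), class = class(ig))
  expect_equal(init_adjacency(ig0), diag(1, 6))
  igbad <- structure(matrix(NaN, 6, 6), class = class(ig))
  expect_error(init_adjacency(igbad), "finite")
})

test_that("GCN aggregation matches the double-loop message-passing oracle", {
  params <- tiny_model(F = 4, seed = 8)
  withr::local_seed(21)
  params$adjacency <- matrix(rnorm(36), 6, 6)
  X <- lapply(1:6, function(n) abs(rnorm(4)))
  Y <- gcn_aggregate(X, params)
  for (n in 1:6) {
    msg <- numeric(4)
    for (m in 1:6) {
      msg <- msg + params$adjacency[n, m] *
        as.vector(X[[m]] %*% params$W_gcn[[n]])
    }
    expect_equal(Y[[n]], pmax(msg + params$b_gcn[[n]], 0), tolerance = 1e-6)
  }
  ## identity adjacency decouples the nodes
  params$adjacency <- diag(1, 6)
  Yd <- gcn_aggregate(X, params)
  for (n in 1:6) {
    expect_equal(Yd[[n]],
                 pmax(as.vector(X[[n]] %*% params$W_gcn[[n]]) +
                        params$b_gcn[[n]], 0), tolerance = 1e-12)
  }
  ## zero adjacency and bias -> all zero
  params$adjacency <- matrix(0, 6, 6)
  for (n in 1:6) params$b_gcn[[n]] <- numeric(4)
  expect_true(all(unlist(gcn_aggregate(X, params)) == 0))
})

test_that("disorder pooling is the elementwise node maximum", {
  X <- lapply(1:6, function(n) c(n, 7 - n, 0.5))
  expect_equal(disorder_pool(X), c(6, 6, 0.5))
  same <- lapply(1:6, function(n) c(1, 2, 3))
  expect_equal(disorder_pool(same), c(1, 2, 3))
  withr::local_seed(2)
  Xr <- lapply(1:6, function(n) matrix(rnorm(12), 3, 4))
  pooled <- disorder_pool(Xr)
  for (i in 1:3) for (j in 1:4) {
    expect_equal(pooled[i, j], max(vapply(Xr, function(m) m[i, j],
                                          numeric(1))))
  }
})

test_that("sequence-only ablation shares shape and range with the full model", {
  params <- tiny_model(seed = 13)
  emb <- random_embedding(8, 4, seed = 6)
  full <- gim_forward(emb, params)
  seq_only <- gim_forward_seq(emb, params)
  expect_equal(dim(seq_only), dim(full))
  expect_true(all(seq_only > 0 & seq_only < 1))
  expect_identical(unclass_profile(gim_forward_seq(emb, params)),
                   unclass_profile(seq_only))
  ## the two variants genuinely differ when the GCN is nontrivial
  expect_gt(max(abs(full - seq_only)), 0)
})

test_that("checkpoints round-trip bit-exactly through save/load/forward", {
  withr::local_seed(14)
  labs <- random_label_set(2, 30, 0.3)
  ig <- ig_matrix(labs)
  params <- tiny_model(seed = 15, ig = ig)
  emb <- random_embedding(12, 4, seed = 7)
  before <- gim_forward(emb, params)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(params, path)
  model <- load_checkpoint(path)
  expect_identical(model$params$adjacency, params$adjacency)
  after <- gim_forward(emb, model$params)
  expect_identical(unclass_profile(before), unclass_profile(after))
  ## corrupted checkpoint
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a checkpoint", bad)
  expect_error(load_checkpoint(bad), "[Cc]orrupted|checkpoint")
})

test_that("permuting functions with matching parameters permutes columns", {
  params <- tiny_model(seed = 23)
  emb <- random_embedding(6, 4, seed = 9)
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  pp <- params
  pp$W_map <- params$W_map[perm]
  pp$b_map <- params$b_map[perm]
  pp$W_gcn <- params$W_gcn[perm]
  pp$b_gcn <- params$b_gcn[perm]
  pp$adjacency <- params$adjacency[perm, perm]
  pp$W_head[2:7] <- params$W_head[2:7][perm]
  pp$b_head[2:7] <- params$b_head[2:7][perm]
  base <- unclass_profile(gim_forward(emb, params))
  permuted <- unclass_profile(gim_forward(emb, pp))
  expect_equal(unname(permuted[, 1 + seq_len(6)]),
               unname(base[, 1 + perm]), tolerance = 1e-12)
  expect_equal(unname(permuted[, 1]), unname(base[, 1]), tolerance = 1e-12)
})
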