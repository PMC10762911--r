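## The graph-interaction model forward pass.
##
## Pipeline per protein: per-residue embeddings r_i (L x D) -> bidirectional
## GRU context encoding P (L x 2H) -> left-to-right GRU with global
## attention producing hidden states h_i (L x A) -> six ReLU feature-mapping
## heads X^(n) (one F-vector per residue per function) -> per-residue
## six-node fully connected functional graph whose adjacency A (6 x 6,
## trainable) is initialized from the pairwise information-gain matrix ->
## graph-convolution aggregation Y^(n) -> elementwise max-pool over the six
## nodes for the disorder feature Y^IDR -> seven sigmoid output heads.

#' Model configuration
#'
#' Dimensions and seeds that fully determine parameter shapes. The
#' defaults suit 1024-dimensional protein-language-model embeddings;
#' desk-scale synthetic studies use much smaller values (see the methods
#' vignette).
#'
#' @param embed_dim Embedding dimension D.
#' @param bigru_hidden Hidden units per direction of the context encoder.
#' @param attn_hidden Hidden units of the attention GRU.
#' @param node_dim Dimension F of each functional-graph node feature.
#' @param dropout Dropout rate applied to the attention-GRU hidden states
#'   during training only (0 disables).
#' @param seed Integer seed used for parameter initialization.
#' @return A `gim_config` list.
#' @export
gim_config <- function(embed_dim, bigru_hidden = 128L, attn_hidden = 128L,
                         node_dim = 32L, dropout = 0, seed = 1L) {
  stopifnot(embed_dim >= 1, bigru_hidden >= 1, attn_hidden >= 1,
            node_dim >= 1, dropout >= 0, dropout < 1)
  structure(list(
    embed_dim = as.integer(embed_dim),
    bigru_hidden = as.integer(bigru_hidden),
    attn_hidden = as.integer(attn_hidden),
    node_dim = as.integer(node_dim),
    n_functions = n_functions(),
    dropout = dropout,
    seed = as.integer(seed)
  ), class = "gim_config")
}

#' Initialize model parameters
#'
#' Weights are drawn from scaled Gaussians using the configuration seed;
#' the functional-graph adjacency is initialized from an information-gain
#' matrix via [init_adjacency()] when one is supplied, otherwise to the
#' identity-like default (zero off-diagonals, unit self-loops).
#'
#' @param config A [gim_config()].
#' @param ig Optional 6 x 6 `ig_matrix` for adjacency initialization.
#' @param self_loop Diagonal value of the initial adjacency (default 1).
#' @return A `gim_params` list of weight tensors.
#' @export
gim_init <- function(config, ig = NULL, self_loop = 1) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  gen <- function(n, sd) rnorm(n, sd = sd)
  D <- config$embed_dim
  H <- config$bigru_hidden
  A <- config$attn_hidden
  F <- config$node_dim
  P_dim <- 2L * H
  params <- list(
    bigru_fwd = gru_init(D, H, gen),
    bigru_bwd = gru_init(D, H, gen),
    W_a = matrix(gen(A * P_dim, 1 / sqrt(A)), A, P_dim),
    attn_gru = gru_init(P_dim, A, gen),
    W_map = lapply(1:6, function(n) matrix(gen(A * F, 1 / sqrt(A)), A, F)),
    b_map = lapply(1:6, function(n) numeric(F)),
    W_gcn = lapply(1:6, function(n) matrix(gen(F * F, 1 / sqrt(F)), F, F)),
    b_gcn = lapply(1:6, function(n) numeric(F)),
    adjacency = if (is.null(ig)) diag(self_loop, 6) else
      init_adjacency(ig, self_loop = self_loop),
    W_head = lapply(1:7, function(n) gen(F, 1 / sqrt(F))),
    b_head = lapply(1:7, function(n) 0)
  )
  structure(params, class = "gim_params", config = config)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

#' Initialize the functional-graph adjacency from an IG matrix
#'
#' Off-diagonal edges are set to the pairwise information gains; the
#' diagonal is set to a constant self-loop weight so each node retains its
#' own signal. The matrix is trainable afterwards and is not constrained
#' to stay symmetric or nonnegative.
#'
#' @param ig A 6 x 6 `ig_matrix`.
#' @param self_loop Diagonal value (default 1).
#' @return A plain 6 x 6 numeric matrix.
#' @export
init_adjacency <- function(ig, self_loop = 1) {
  m <- unclass(ig)
  if (!all(is.finite(m))) abort("IG matrix contains non-finite values")
  stopifnot(all(dim(m) == c(6, 6)))
  adj <- m
  diag(adj) <- self_loop
  dimnames(adj) <- NULL
  adj
}

#' Encode per-residue context with the bidirectional GRU
#'
#' @param embeddings `L x D` embedding matrix.
#' @param params A `gim_params`.
#' @return `L x 2H` context encoding matrix `P`.
#' @export
encode_context <- function(embeddings, params) {
  config <- attr(params, "config")
  if (ncol(embeddings) != config$embed_dim) {
    abort(sprintf("Embedding dimension %d does not match config D = %d",
                  ncol(embeddings), config$embed_dim))
  }
  bigru_forward(embeddings, params$bigru_fwd, params$bigru_bwd)$P
}

#' Attention scores and weights for one decoding step
#'
#' Scores `s_j = h_prev^T W_a p_j` over all residues, normalized by a
#' softmax. Weights are invariant to adding a constant to every score.
#'
#' @param h_prev Previous hidden state of the attention GRU.
#' @param P Context encoding matrix (`L x 2H`).
#' @param W_a Attention weight matrix (`A x 2H`).
#' @return List with `scores` and `weights` (both length `L`).
#' @export
attention_weights <- function(h_prev, P, W_a) {
  q <- as.vector(h_prev %*% W_a)       # 1 x 2H
  scores <- as.vector(P %*% q)
  if (!all(is.finite(scores))) abort("Non-finite attention scores")
  w <- exp(scores - max(scores))
  list(scores = scores, weights = w / sum(w))
}

## Attention-GRU forward with full caches for backprop.
attn_gru_forward <- function(P, params) {
  A <- length(params$attn_gru$bz)
  L <- nrow(P)
  H <- matrix(0, L, A)
  alpha <- matrix(0, L, L)
  scores <- matrix(0, L, L)
  context <- matrix(0, L, ncol(P))
  caches <- vector("list", L)
  h <- numeric(A)
  for (i in seq_len(L)) {
    at <- attention_weights(h, P, params$W_a)
    ci <- as.vector(crossprod(P, at$weights))
    step <- gru_cell_forward(ci, h, params$attn_gru)
    alpha[i, ] <- at$weights
    scores[i, ] <- at$scores
    context[i, ] <- ci
    caches[[i]] <- list(gru = step$cache, h_prev = h, weights = at$weights)
    h <- step$h
    H[i, ] <- h
  }
  list(hidden = H, weights = alpha, scores = scores, context = context,
       caches = caches)
}

#' Run the attention GRU over a context encoding
#'
#' Left-to-right recurrence with zero initial state; at each step the
#' context vector `c_i` is the attention-weighted sum of all rows of `P`
#' (global, not causal, attention).
#'
#' @param P `L x 2H` context encoding.
#' @param params A `gim_params`.
#' @return List with `hidden` (`L x A`), `weights` (`L x L` attention
#'   matrix, rows sum to 1), `scores` (`L x L`) and `context` (`L x 2H`).
#' @export
attention_gru <- function(P, params) {
  out <- attn_gru_forward(P, params)
  out[c("hidden", "weights", "scores", "context")]
}

#' Map a hidden state to the six functional node features
#'
#' `X^(n) = ReLU(h W^(n) + b^(n))` for n = 1..6.
#'
#' @param h Hidden vector (length A) or `L x A` matrix.
#' @param params A `gim_params`.
#' @return List of six node-feature vectors/matrices (each `F` columns).
#' @export
map_function_features <- function(h, params) {
  hm <- if (is.matrix(h)) h else matrix(h, nrow = 1)
  lapply(1:6, function(n) {
    pre <- hm %*% params$W_map[[n]] +
      matrix(params$b_map[[n]], nrow(hm), length(params$b_map[[n]]),
             byrow = TRUE)
    out <- pmax(pre, 0)
    if (is.matrix(h)) out else as.vector(out)
  })
}

#' Graph-convolution aggregation on the functional graph
#'
#' Per residue, target node n aggregates messages from every node m of the
#' fully connected six-node graph with edge weight `A[n, m]`:
#' `Y^(n) = ReLU((sum_m A[n, m] X^(m)) W'^(n) + b'^(n))`.
#'
#' @param node_features List of six `L x F` matrices (or F-vectors).
#' @param params A `gim_params` supplying adjacency and kernels.
#' @return List of six aggregated feature matrices, same shapes as input.
#' @export
gcn_aggregate <- function(node_features, params) {
  vec_in <- !is.matrix(node_features[[1]])
  X <- lapply(node_features, function(x) if (is.matrix(x)) x else
    matrix(x, nrow = 1))
  adj <- params$adjacency
  out <- lapply(1:6, function(n) {
    S <- Reduce(`+`, lapply(1:6, function(m) adj[n, m] * X[[m]]))
    pre <- S %*% params$W_gcn[[n]] +
      matrix(params$b_gcn[[n]], nrow(S), ncol(S), byrow = TRUE)
    pmax(pre, 0)
  })
  if (vec_in) lapply(out, as.vector) else out
}

#' Disorder feature by max-pooling over the functional graph
#'
#' Elementwise maximum over the six aggregated node features.
#'
#' @param aggregated List of six `L x F` matrices (or F-vectors).
#' @return The pooled `L x F` matrix (or F-vector).
#' @export
disorder_pool <- function(aggregated) {
  Reduce(pmax, aggregated)
}

## Which node attains the max in each (residue, feature) cell; ties go to
## the lowest node index (used to route gradients and LRP relevance).
pool_argmax <- function(aggregated, pooled) {
  win <- matrix(1L, nrow(pooled), ncol(pooled))
  for (n in 6:1) {
    win[aggregated[[n]] == pooled] <- n
  }
  win
}

#' Full forward pass of the graph-interaction model
#'
#' @param embeddings `L x D` embedding matrix for one protein.
#' @param params A `gim_params`.
#' @param protein_id Optional id attached to the returned profile.
#' @param traces If `TRUE`, attach the intermediate states needed for
#'   attribution (context encoding, attention state, node features,
#'   aggregated features, pre-sigmoid logits) as attribute `"traces"`.
#' @param training If `TRUE`, apply dropout (when configured) and return
#'   backprop caches; inference is deterministic.
#' @return A `propensity_profile`: `L x 7` matrix of scores in (0, 1),
#'   columns in canonical label order.
#' @export
gim_forward <- function(embeddings, params, protein_id = NULL,
                          traces = FALSE, training = FALSE) {
  fw <- gim_forward_full(embeddings, params, training = training)
  profile_from_forward(fw, protein_id, traces)
}

#' Forward pass of the sequence-only ablation
#'
#' The graph-interaction unit and graph convolution are removed: the seven
#' heads read the mapped node features directly (disorder from their
#' max-pool). Used for graph-vs-sequence ablation studies.
#'
#' @inheritParams gim_forward
#' @return A `propensity_profile`, same shape and range as
#'   [gim_forward()].
#' @export
gim_forward_seq <- function(embeddings, params, protein_id = NULL,
                              traces = FALSE, training = FALSE) {
  fw <- gim_forward_full(embeddings, params, training = training,
                         use_gcn = FALSE)
  profile_from_forward(fw, protein_id, traces)
}

## Shared forward machinery. Returns every intermediate needed for either
## the backward pass or attribution.
gim_forward_full <- function(embeddings, params, training = FALSE,
                               use_gcn = TRUE) {
  config <- attr(params, "config")
  if (!is.matrix(embeddings) || nrow(embeddings) < 1) {
    abort("Embeddings must be a matrix with at least one row")
  }
  if (ncol(embeddings) != config$embed_dim) {
    abort(sprintf("Embedding dimension %d does not match config D = %d",
                  ncol(embeddings), config$embed_dim))
  }
  if (!all(is.finite(embeddings))) abort("Embeddings contain non-finite values")
  L <- nrow(embeddings)
  enc <- bigru_forward(embeddings, params$bigru_fwd, params$bigru_bwd)
  att <- attn_gru_forward(enc$P, params)
  H <- att$hidden
  drop_mask <- NULL
  if (training && config$dropout > 0) {
    drop_mask <- matrix(rbinom(length(H), 1, 1 - config$dropout) /
                          (1 - config$dropout), nrow(H), ncol(H))
    H <- H * drop_mask
  }
  X <- map_function_features(H, params)          # list of 6 L x F
  if (use_gcn) {
    Y <- gcn_aggregate(X, params)
    head_in <- Y
  } else {
    Y <- NULL
    head_in <- X
  }
  pooled <- disorder_pool(head_in)
  logits <- matrix(0, L, 7)
  logits[, 1] <- as.vector(pooled %*% params$W_head[[1]]) + params$b_head[[1]]
  for (n in 1:6) {
    logits[, n + 1] <- as.vector(head_in[[n]] %*% params$W_head[[n + 1]]) +
      params$b_head[[n + 1]]
  }
  scores <- sigmoid(logits)
  colnames(scores) <- idr_labels()
  list(embeddings = embeddings, enc = enc, att = att, H = H,
       drop_mask = drop_mask, X = X, Y = Y, head_in = head_in,
       pooled = pooled, argmax = pool_argmax(head_in, pooled),
       logits = logits, scores = scores, use_gcn = use_gcn)
}

profile_from_forward <- function(fw, protein_id, traces) {
  prof <- fw$scores
  class(prof) <- c("propensity_profile", class(prof))
  attr(prof, "protein_id") <- protein_id
  if (traces) {
    attr(prof, "traces") <- fw[c("enc", "att", "H", "X", "Y", "head_in",
                                 "pooled", "argmax", "logits", "use_gcn")]
  }
  prof
}

#' @export
print.propensity_profile <- function(x, ...) {
  cat(sprintf("<propensity_profile> %s: %d residues x 7 heads\n",
              attr(x, "protein_id") %||% "(unnamed)", nrow(x)))
  print(utils::head(round(unclass_profile(x), 4)))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' @export
autoplot.propensity_profile <- function(object, ...) {
  df <- as_tibble(as.data.frame(unclass_profile(object)))
  df$pos <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df, cols = idr_labels(),
                              names_to = "label", values_to = "propensity")
  long$label <- factor(long$label, levels = idr_labels())
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pos, y = .data$propensity)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::facet_wrap(~label, ncol = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "residue position", y = "propensity",
                  title = attr(object, "protein_id") %||% NULL) +
    ggplot2::theme_minimal()
}

#' Save a model checkpoint
#'
#' A single-file container holding the configuration, parameters,
#' calibrated thresholds, the IG matrix used at adjacency initialization
#' and the package version. Round-trips bit-exactly.
#'
#' @param model A `gim_model` (from [train_gim()]) or a bare
#'   `gim_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "gim_params")) {
    model <- structure(list(params = model, config = attr(model, "config"),
                            thresholds = rep(0.5, 7), ig = NULL,
                            history = NULL), class = "gim_model")
  }
  stopifnot(inherits(model, "gim_model"))
  model$package_version <- as.character(packageVersion("idrgraph"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return A `gim_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) abort(paste0("Checkpoint not found: ", path))
  model <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("Corrupted or unreadable checkpoint: ", path))
  })
  if (!inherits(model, "gim_model")) {
    abort(paste0("Not a model checkpoint: ", path))
  }
  model
}
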