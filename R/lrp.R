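## Layer-wise relevance propagation with the alpha-beta rule through the
## output heads and the graph-interaction unit. Relevance is seeded with a
## head's pre-sigmoid logit and propagated back to the six mapped node
## features X^(n); per-node contribution scores sum the relevance over a
## node's features, and an edge's contribution is the sum of its two
## endpoint node scores.

#' LRP configuration
#'
#' The alpha-beta rule splits each layer's contributions into positive and
#' negative parts weighted by `alpha` and `beta`. The conservation
#' convention requires `alpha - beta == 1`; the default `alpha = 1,
#' beta = 0` keeps only positive contributions.
#'
#' @param alpha Nonnegative weight of positive contributions.
#' @param beta Nonnegative weight of negative contributions.
#' @return An `lrp_config` list.
#' @export
lrp_config <- function(alpha = 1, beta = 0) {
  stopifnot(alpha >= 0, beta >= 0)
  if (abs(alpha - beta - 1) > 1e-12) {
    abort("LRP requires alpha - beta == 1")
  }
  structure(list(alpha = alpha, beta = beta), class = "lrp_config")
}

#' Propagate relevance through one linear layer (alpha-beta rule)
#'
#' Distributes the output relevance `R_k` over inputs `h_j` of a layer
#' `a_k = sum_j h_j w_jk + b_k` proportionally to the signed contributions
#' `w_jk h_j`, with positive and negative parts weighted by `alpha` and
#' `beta`. Denominators are stabilized by adding a sign-matched 1e-9.
#'
#' @param relevance_out Relevance vector of the layer outputs.
#' @param weights Weight matrix (`n_in x n_out`).
#' @param bias Bias vector of the outputs.
#' @param activations_in Input activation vector `h`.
#' @param config An [lrp_config()].
#' @return Relevance vector over the inputs.
#' @export
lrp_linear <- function(relevance_out, weights, bias, activations_in,
                       config = lrp_config()) {
  stopifnot(nrow(weights) == length(activations_in),
            ncol(weights) == length(relevance_out))
  z <- weights * activations_in          # z_jk = w_jk * h_j (recycled by col)
  zp <- pmax(z, 0)
  zn <- pmin(z, 0)
  bp <- pmax(bias, 0)
  bn <- pmin(bias, 0)
  denom_p <- colSums(zp) + bp + 1e-9
  denom_n <- colSums(zn) + bn - 1e-9
  frac <- config$alpha * sweep(zp, 2, denom_p, `/`) -
    config$beta * sweep(zn, 2, denom_n, `/`)
  as.vector(frac %*% relevance_out)
}

#' Explain one residue's prediction on the functional graph
#'
#' Requires a forward pass run with `traces = TRUE`. Relevance is seeded
#' with the head's pre-sigmoid logit, propagated through the output head
#' to the aggregated node features (for the disorder head, through the
#' max-pool to the winning node of each feature dimension), then through
#' the graph convolution to the six mapped node features. The node score
#' of function `n` is the summed relevance over node n's features; the
#' edge score of a pair is the sum of its two node scores.
#'
#' @param profile A `propensity_profile` from
#'   [gim_forward()]`(..., traces = TRUE)`.
#' @param params The `gim_params` used for the forward pass.
#' @param residue 1-based residue index.
#' @param head Head to explain: 1 = disorder, 2..7 = the six functions (or
#'   a label name).
#' @param config An [lrp_config()].
#' @return A `relevance_map`: list with `node_scores` (named length-6),
#'   `edge_scores` (tibble `node_a`, `node_b`, `score` over the 15
#'   unordered pairs), `layer_traces` (relevance vector per traversed
#'   layer) and the seeding metadata.
#' @export
explain_residue <- function(profile, params, residue, head,
                            config = lrp_config()) {
  traces <- attr(profile, "traces")
  if (is.null(traces)) {
    abort("No traces on this profile; rerun gim_forward(traces = TRUE)")
  }
  if (is.character(head)) head <- match(head, idr_labels())
  stopifnot(head >= 1, head <= 7, residue >= 1, residue <= nrow(profile))
  F <- length(params$b_gcn[[1]])
  Xn <- lapply(traces$X, function(m) m[residue, ])
  head_in <- lapply(traces$head_in, function(m) m[residue, ])
  logit <- traces$logits[residue, head]
  layer_traces <- list(output = logit)

  ## head layer: logit = head_in . v + b
  if (head == 1) {
    pooled <- traces$pooled[residue, ]
    r_pooled <- lrp_linear(logit, matrix(params$W_head[[1]], ncol = 1),
                           params$b_head[[1]], pooled, config)
    layer_traces$pooled <- r_pooled
    ## max-pool: each pooled dimension's relevance goes to the winning node
    win <- traces$argmax[residue, ]
    r_nodes_Y <- lapply(1:6, function(n) r_pooled * (win == n))
  } else {
    n <- head - 1L
    r_y <- lrp_linear(logit, matrix(params$W_head[[head]], ncol = 1),
                      params$b_head[[head]], head_in[[n]], config)
    r_nodes_Y <- lapply(1:6, function(m) if (m == n) r_y else numeric(F))
  }
  layer_traces$aggregated <- unlist(r_nodes_Y)

  if (traces$use_gcn) {
    ## graph convolution: Y^(n) = ReLU((sum_m A[n,m] X^(m)) W'^(n) + b'),
    ## viewed as one linear map from the concatenated X (6F) to Y^(n).
    adj <- params$adjacency
    r_X <- lapply(1:6, function(m) numeric(F))
    x_cat <- unlist(Xn)
    for (n in 1:6) {
      if (all(r_nodes_Y[[n]] == 0)) next
      W_eff <- do.call(rbind, lapply(1:6, function(m) {
        adj[n, m] * params$W_gcn[[n]]
      }))                                    # (6F) x F
      r_in <- lrp_linear(r_nodes_Y[[n]], W_eff, params$b_gcn[[n]], x_cat,
                         config)
      for (m in 1:6) {
        r_X[[m]] <- r_X[[m]] + r_in[(m - 1) * F + seq_len(F)]
      }
    }
  } else {
    r_X <- r_nodes_Y
  }
  layer_traces$node_features <- unlist(r_X)

  node_scores <- setNames(vapply(r_X, sum, numeric(1)),
                          idr_function_labels())
  pairs <- utils::combn(6, 2)
  edge_scores <- tibble(
    node_a = idr_function_labels()[pairs[1, ]],
    node_b = idr_function_labels()[pairs[2, ]],
    score = unname(node_scores[pairs[1, ]] + node_scores[pairs[2, ]])
  )
  structure(list(
    protein_id = attr(profile, "protein_id"),
    residue = residue,
    head = idr_labels()[head],
    seed_logit = logit,
    node_scores = node_scores,
    edge_scores = edge_scores,
    layer_traces = layer_traces,
    config = config
  ), class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat(sprintf("<relevance_map> %s residue %d, head '%s' (logit %.4f)\n",
              x$protein_id %||% "(unnamed)", x$residue, x$head,
              x$seed_logit))
  print(round(x$node_scores, 4))
  invisible(x)
}

#' @export
tidy.relevance_map <- function(x, ...) {
  tibble(node = names(x$node_scores), score = unname(x$node_scores),
         residue = x$residue, head = x$head)
}

#' @export
autoplot.relevance_map <- function(object, ...) {
  df <- tidy(object)
  df$node <- factor(df$node, levels = idr_function_labels())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$score)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(title = sprintf("Node contributions to %s at residue %d",
                                  object$head, object$residue),
                  x = NULL, y = "relevance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Aggregate relevance over true-positive residues
#'
#' For one explained head, sums node and edge contribution scores over all
#' residues that are true positives at the supplied thresholds.
#'
#' @param profiles Named list of `propensity_profile`s computed with
#'   traces.
#' @param labels Named list of matching label matrices.
#' @param params The `gim_params` used for the forward passes.
#' @param head Head to explain (index 1..7 or label name).
#' @param thresholds Length-7 vector or [calibrate_thresholds()] tibble.
#' @param config An [lrp_config()].
#' @return List with `node_scores` (length 6), `edge_scores` (15-row
#'   tibble) and `n_true_positive`. Zero vectors with a warning when the
#'   head has no true positives.
#' @export
aggregate_importance <- function(profiles, labels, params, head, thresholds,
                                 config = lrp_config()) {
  if (is.character(head)) head <- match(head, idr_labels())
  thr <- threshold_vector(thresholds)
  node_total <- setNames(numeric(6), idr_function_labels())
  edge_total <- NULL
  n_tp <- 0L
  for (id in names(profiles)) {
    prof <- profiles[[id]]
    sc <- unclass_profile(prof)[, head]
    y <- unclass(labels[[id]])[, head]
    tp_rows <- which(sc >= thr[head] & y == 1)
    for (i in tp_rows) {
      rm <- explain_residue(prof, params, i, head, config)
      node_total <- node_total + rm$node_scores
      edge_total <- if (is.null(edge_total)) rm$edge_scores else {
        dplyr::mutate(edge_total, score = .data$score + rm$edge_scores$score)
      }
      n_tp <- n_tp + 1L
    }
  }
  if (n_tp == 0) {
    warn(sprintf("No true-positive residues for head '%s'",
                 idr_labels()[head]))
    pairs <- utils::combn(6, 2)
    edge_total <- tibble(node_a = idr_function_labels()[pairs[1, ]],
                         node_b = idr_function_labels()[pairs[2, ]],
                         score = 0)
  }
  list(node_scores = node_total, edge_scores = edge_total,
       n_true_positive = n_tp)
}
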