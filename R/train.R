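## Joint training of the seven sigmoid heads with a combined binary
## cross-entropy loss: per head the BCE is averaged over (unmasked)
## residues, and the head losses are averaged. Parameters achieving the
## minimum validation loss are returned (not the final epoch). Adam is
## implemented directly on the flattened parameter vector.

#' Joint binary cross-entropy loss
#'
#' Mean over the seven heads of the per-head binary cross-entropy (natural
#' log), each averaged over unmasked residues. Scores are clipped to
#' `[1e-7, 1 - 1e-7]` before taking logs.
#'
#' @param profile `L x 7` propensity matrix.
#' @param labels `L x 7` binary label matrix.
#' @param mask Optional length-`L` 0/1 vector; masked residues (0) are
#'   excluded from the average.
#' @return Nonnegative scalar loss in nats.
#' @examples
#' p <- matrix(0.5, 1, 7)
#' y <- matrix(c(1L, rep(0L, 6)), 1, 7)
#' joint_bce_loss(p, y)  # log(2)
#' @export
joint_bce_loss <- function(profile, labels, mask = NULL) {
  scores <- unclass_profile(profile)
  if (!all(dim(scores) == dim(labels))) {
    abort(sprintf("Profile is %d x %d but labels are %d x %d",
                  nrow(scores), ncol(scores), nrow(labels), ncol(labels)))
  }
  L <- nrow(scores)
  if (is.null(mask)) mask <- rep(1, L)
  n_obs <- sum(mask)
  if (n_obs == 0) abort("All residues are masked")
  eps <- 1e-7
  p <- pmin(pmax(scores, eps), 1 - eps)
  -sum(mask * (labels * log(p) + (1 - labels) * log(1 - p))) / (n_obs * 7)
}

adam_state <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(theta, grad, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, state = state)
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Proteins per gradient step (default 8).
#' @param max_epochs Maximum training epochs (default 200).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 20).
#' @param seed Integer seed controlling shuffling and dropout.
#' @param head_weights Length-7 loss weights, uniform by default.
#' @param clip_norm Global gradient-norm clip for the recurrent layers'
#'   stability (default 5; `Inf` disables).
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 8L,
                         max_epochs = 200L, patience = 20L, seed = 1L,
                         head_weights = rep(1, 7), clip_norm = 5) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, length(head_weights) == 7, all(head_weights >= 0),
            clip_norm > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 optimizer = "adam",
                 head_weights = head_weights,
                 clip_norm = clip_norm), class = "train_config")
}

dataset_loss <- function(params, embeddings, labels, masks, head_weights) {
  total <- 0
  for (id in names(embeddings)) {
    fw <- gim_forward_full(embeddings[[id]], params)
    total <- total + weighted_bce(fw$scores, labels[[id]], masks[[id]],
                                  head_weights)
  }
  total / length(embeddings)
}

weighted_bce <- function(scores, labels, mask, head_weights) {
  L <- nrow(scores)
  if (is.null(mask)) mask <- rep(1, L)
  eps <- 1e-7
  p <- pmin(pmax(unclass(scores), eps), 1 - eps)
  per_head <- -colSums(mask * (labels * log(p) + (1 - labels) * log(1 - p))) /
    sum(mask)
  sum(per_head * head_weights) / sum(head_weights)
}

#' Train the graph-interaction model
#'
#' Adam on the joint BCE loss with per-protein gradient accumulation
#' within batches; the functional-graph adjacency is initialized from the
#' training set's information-gain matrix before the first step. The
#' parameters with minimum validation loss are returned together with
#' max-F1 calibrated thresholds (computed on the validation set) and the
#' per-epoch history. Fully reproducible given the seeds.
#'
#' @param train_embeddings,train_labels Named lists (same ids) of `L x D`
#'   embedding and `L x 7` label matrices.
#' @param val_embeddings,val_labels Validation set in the same form.
#' @param mconfig A [gim_config()].
#' @param tconfig A [train_config()].
#' @param train_masks,val_masks Optional named lists of 0/1 residue masks.
#' @param ig Optional precomputed `ig_matrix`; default computes it from
#'   `train_labels`.
#' @param verbose Print per-epoch losses.
#' @return A `gim_model` list: `params`, `config`, `thresholds`
#'   (tibble from [calibrate_thresholds()]), `ig`, `history` (tibble of
#'   epoch, train_loss, val_loss), `best_epoch`, `best_val_loss`.
#' @export
train_gim <- function(train_embeddings, train_labels, val_embeddings,
                        val_labels, mconfig, tconfig = train_config(),
                        train_masks = NULL, val_masks = NULL, ig = NULL,
                        verbose = FALSE) {
  stopifnot(length(train_embeddings) > 0, length(val_embeddings) > 0)
  ids <- names(train_embeddings)
  if (!setequal(ids, names(train_labels))) {
    abort("Training embedding and label ids differ")
  }
  if (is.null(train_masks)) {
    train_masks <- setNames(vector("list", length(ids)), ids)
  }
  if (is.null(val_masks)) {
    val_masks <- setNames(vector("list", length(val_embeddings)),
                          names(val_embeddings))
  }
  if (is.null(ig)) ig <- ig_matrix(train_labels)
  params <- gim_init(mconfig, ig = ig)

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(tconfig$seed)

  theta <- flatten_params(params)
  opt <- adam_state(length(theta))
  hw <- tconfig$head_weights / sum(tconfig$head_weights) * 7

  best_val <- Inf
  best_theta <- theta
  best_epoch <- 0L
  stall <- 0L
  history <- list()

  for (epoch in seq_len(tconfig$max_epochs)) {
    order_ids <- sample(ids)
    batches <- split(order_ids,
                     ceiling(seq_along(order_ids) / tconfig$batch_size))
    epoch_loss <- 0
    for (batch in batches) {
      params <- unflatten_params(theta, params)
      gsum <- NULL
      bloss <- 0
      for (id in batch) {
        fw <- gim_forward_full(train_embeddings[[id]], params,
                               training = TRUE)
        bk <- gim_backward(fw, params, train_labels[[id]],
                           mask = train_masks[[id]], head_weights = hw)
        if (!is.finite(bk$loss)) {
          abort(sprintf("Training loss diverged (non-finite) at epoch %d",
                        epoch))
        }
        bloss <- bloss + bk$loss
        gflat <- flatten_params(bk$grad)
        gsum <- if (is.null(gsum)) gflat else gsum + gflat
      }
      gsum <- gsum / length(batch)
      gnorm <- sqrt(sum(gsum^2))
      clip <- tconfig$clip_norm %||% Inf
      if (is.finite(clip) && gnorm > clip) gsum <- gsum * (clip / gnorm)
      step <- adam_step(theta, gsum, opt, lr = tconfig$learning_rate)
      theta <- step$theta
      opt <- step$state
      epoch_loss <- epoch_loss + bloss
    }
    epoch_loss <- epoch_loss / length(ids)
    params <- unflatten_params(theta, params)
    val_loss <- dataset_loss(params, val_embeddings, val_labels, val_masks,
                             rep(1, 7))
    history[[epoch]] <- tibble(epoch = epoch, train_loss = epoch_loss,
                               val_loss = val_loss)
    if (verbose) {
      inform(sprintf("epoch %3d  train %.5f  val %.5f", epoch, epoch_loss,
                     val_loss))
    }
    if (val_loss < best_val) {
      best_val <- val_loss
      best_theta <- theta
      best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tconfig$patience) break
    }
  }

  best_params <- unflatten_params(best_theta, params)
  val_profiles <- lapply(names(val_embeddings), function(id) {
    gim_forward(val_embeddings[[id]], best_params, protein_id = id)
  })
  names(val_profiles) <- names(val_embeddings)
  thresholds <- calibrate_thresholds(val_profiles,
                                     val_labels[names(val_embeddings)])
  structure(list(
    params = best_params,
    config = mconfig,
    train_config = tconfig,
    thresholds = thresholds,
    ig = ig,
    history = dplyr::bind_rows(history),
    best_epoch = best_epoch,
    best_val_loss = best_val
  ), class = "gim_model")
}

#' Calibrate per-head decision thresholds by maximum F1
#'
#' For each head, sweeps the finite set of observed scores as candidate
#' thresholds (call positive when `score >= threshold`) and keeps the one
#' maximizing F1, breaking ties toward the larger threshold. A head with
#' no positives (or no negatives) falls back to 0.5 with a warning.
#'
#' @param profiles Named list of `L x 7` propensity matrices.
#' @param labels Named list of matching `L x 7` label matrices.
#' @param masks Optional named list of residue masks.
#' @return A tibble with columns `label`, `threshold`, `f1`, and attribute
#'   `method = "max_f1"`. Use [threshold_vector()] for the bare 7-vector.
#' @export
calibrate_thresholds <- function(profiles, labels, masks = NULL) {
  if (length(profiles) == 0) abort("No profiles supplied")
  sc <- do.call(rbind, lapply(profiles, unclass_profile))
  lb <- do.call(rbind, lapply(labels, unclass))
  if (!is.null(masks)) {
    mk <- unlist(lapply(names(profiles), function(id) {
      masks[[id]] %||% rep(1, nrow(profiles[[id]]))
    }))
    sc <- sc[mk > 0, , drop = FALSE]
    lb <- lb[mk > 0, , drop = FALSE]
  }
  rows <- lapply(seq_len(n_heads()), function(h) {
    y <- lb[, h]
    s <- sc[, h]
    if (sum(y) == 0 || sum(y) == length(y)) {
      warn(sprintf("Head '%s' has a single class; threshold defaults to 0.5",
                   idr_labels()[h]))
      return(tibble(label = idr_labels()[h], threshold = 0.5, f1 = NA_real_))
    }
    sweep <- f1_sweep(s, y)
    tibble(label = idr_labels()[h], threshold = sweep$threshold,
           f1 = sweep$f1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "method") <- "max_f1"
  out
}

## Exhaustive F1 sweep over the observed score set; ties toward the larger
## threshold.
f1_sweep <- function(scores, y) {
  cand <- sort(unique(scores), decreasing = TRUE)
  best_f1 <- -1
  best_thr <- cand[1]
  n_pos <- sum(y)
  for (t in cand) {
    pred <- scores >= t
    tp <- sum(pred & y == 1)
    fp <- sum(pred & y == 0)
    f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + (n_pos - tp))
    if (f1 > best_f1) {
      best_f1 <- f1
      best_thr <- t
    }
  }
  list(threshold = best_thr, f1 = best_f1)
}

#' Extract the bare length-7 threshold vector
#'
#' @param thresholds Tibble from [calibrate_thresholds()] or a numeric
#'   7-vector (returned unchanged).
#' @return Named numeric vector of 7 thresholds in canonical label order.
#' @export
threshold_vector <- function(thresholds) {
  if (is.numeric(thresholds)) {
    stopifnot(length(thresholds) == 7)
    return(setNames(as.numeric(thresholds), idr_labels()))
  }
  setNames(thresholds$threshold[match(idr_labels(), thresholds$label)],
           idr_labels())
}

#' @export
print.gim_model <- function(x, ...) {
  cat("<gim_model>\n")
  cat(sprintf("  embed_dim %d, bigru %d, attn %d, node_dim %d\n",
              x$config$embed_dim, x$config$bigru_hidden,
              x$config$attn_hidden, x$config$node_dim))
  cat(sprintf("  best epoch %d (val loss %.5f) of %d run\n",
              x$best_epoch %||% NA, x$best_val_loss %||% NA,
              if (!is.null(x$history)) nrow(x$history) else 0L))
  invisible(x)
}

#' Tidy a fitted model: calibrated thresholds and validation F1 per head
#'
#' @param x A `gim_model`.
#' @param ... Unused.
#' @return The threshold tibble (`label`, `threshold`, `f1`).
#' @export
tidy.gim_model <- function(x, ...) {
  as_tibble(x$thresholds)
}

#' One-row summary of a fitted model
#'
#' @param x A `gim_model`.
#' @param ... Unused.
#' @return Tibble with epochs run, best epoch, best validation loss and
#'   parameter count.
#' @export
glance.gim_model <- function(x, ...) {
  tibble(
    epochs_run = if (!is.null(x$history)) nrow(x$history) else NA_integer_,
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_loss = x$best_val_loss %||% NA_real_,
    n_parameters = length(flatten_params(x$params))
  )
}

#' Plot training history
#'
#' @param object A `gim_model`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss by epoch.
#' @export
autoplot.gim_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, cols = c("train_loss", "val_loss"),
                           names_to = "split", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::labs(title = "Training history", y = "joint BCE loss") +
    ggplot2::theme_minimal()
}
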