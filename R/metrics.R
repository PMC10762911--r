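## CAID-style evaluation: threshold-independent metrics (AUC, AUPR, APS,
## Fmax) and binary metrics (MCC, BACC) at a given threshold, with pooled
## and per-protein aggregation, multifunctional-residue evaluation, and a
## paired bootstrap comparison of two predictors.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a random positive
#' outscores a random negative, with ties counted one half.
#'
#' @param scores Numeric score vector.
#' @param labels Binary 0/1 vector of the same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' metric_auc(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
metric_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("AUC requires both classes present")
  }
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Area under the precision-recall curve and average precision
#'
#' `AUPR` integrates the PR curve trapezoidally over the observed score
#' thresholds; `APS` is the step-wise average precision
#' `sum((R_k - R_{k-1}) * P_k)` along the same sweep.
#'
#' @inheritParams metric_auc
#' @return Named list with `aupr` and `aps`, both in `[0, 1]`.
#' @export
metric_aupr_aps <- function(scores, labels) {
  if (sum(labels == 1) == 0) abort("PR metrics require at least one positive")
  pr <- pr_curve(scores, labels)
  rec <- pr$recall
  prec <- pr$precision
  ## prepend the (R=0, P=first precision) anchor for integration
  r0 <- c(0, rec)
  p0 <- c(prec[1], prec)
  aupr <- sum(diff(r0) * (head(p0, -1) + tail(p0, -1)) / 2)
  aps <- sum(diff(r0) * tail(p0, -1))
  list(aupr = aupr, aps = aps)
}

## Precision/recall at every observed score threshold (call positive when
## score >= t), thresholds descending so recall is nondecreasing.
pr_curve <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  keep <- c(diff(s) != 0, TRUE)  # collapse tied scores to one operating point
  tp <- cumsum(y)[keep]
  n_call <- seq_along(y)[keep]
  precision <- tp / n_call
  recall <- tp / sum(labels == 1)
  list(precision = precision, recall = recall,
       threshold = s[keep])
}

#' Maximum F1 over all thresholds
#'
#' Sweeps the observed score set (positive when `score >= t`), breaking
#' ties toward the larger threshold.
#'
#' @inheritParams metric_auc
#' @return Named list with `fmax` and `threshold`.
#' @export
metric_fmax <- function(scores, labels) {
  if (sum(labels == 1) == 0) abort("Fmax requires at least one positive")
  sweep <- f1_sweep(scores, labels)
  list(fmax = sweep$f1, threshold = sweep$threshold)
}

#' Matthews correlation coefficient and balanced accuracy
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined
#' as 0 when any factor of the denominator is 0; `BACC = (TPR + TNR) / 2`.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @return Named list with `mcc` in `[-1, 1]` and `bacc` in `[0, 1]`.
#' @examples
#' metric_mcc_bacc(tp = 3, fp = 1, tn = 4, fn = 2)
#' @export
metric_mcc_bacc <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  denom_terms <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(denom_terms == 0)) 0 else {
    (tp * tn - fp * fn) / sqrt(prod(denom_terms))
  }
  tpr <- if (tp + fn == 0) 0 else tp / (tp + fn)
  tnr <- if (tn + fp == 0) 0 else tn / (tn + fp)
  list(mcc = mcc, bacc = (tpr + tnr) / 2)
}

#' Evaluate predictions against labels across all heads
#'
#' Residues are pooled across proteins per head for the dataset-level
#' report; in per-protein mode the metrics are computed within each
#' protein and averaged over proteins that contain both classes for that
#' head.
#'
#' @param profiles Named list of `L x 7` propensity matrices.
#' @param labels Named list of matching `L x 7` label matrices.
#' @param thresholds Length-7 numeric vector or a
#'   [calibrate_thresholds()] tibble used for the binary metrics.
#' @param per_protein If `TRUE`, average per-protein metrics instead of
#'   pooling residues.
#' @param masks Optional named list of residue masks.
#' @return A tibble with one row per head: `label`, `auc`, `aupr`, `aps`,
#'   `fmax`, `mcc`, `bacc`, `threshold`, `n_pos`, `n_neg` (pooled mode) or
#'   the per-protein averages plus `n_proteins` (per-protein mode).
#' @export
evaluate_predictions <- function(profiles, labels, thresholds,
                                 per_protein = FALSE, masks = NULL) {
  ids <- names(profiles)
  if (!setequal(ids, names(labels))) {
    abort("Profile and label ids differ")
  }
  for (id in ids) {
    if (nrow(profiles[[id]]) != nrow(labels[[id]])) {
      abort(paste0("Length mismatch between profile and labels for ", id))
    }
  }
  thr <- threshold_vector(thresholds)
  if (!per_protein) {
    sc <- do.call(rbind, lapply(ids, function(id) unclass_profile(profiles[[id]])))
    lb <- do.call(rbind, lapply(ids, function(id) unclass(labels[[id]])))
    if (!is.null(masks)) {
      mk <- unlist(lapply(ids, function(id) {
        masks[[id]] %||% rep(1, nrow(profiles[[id]]))
      }))
      sc <- sc[mk > 0, , drop = FALSE]
      lb <- lb[mk > 0, , drop = FALSE]
    }
    return(dplyr::bind_rows(lapply(seq_len(n_heads()), function(h) {
      head_metrics(sc[, h], lb[, h], thr[h], idr_labels()[h])
    })))
  }
  per <- lapply(ids, function(id) {
    sc <- unclass_profile(profiles[[id]])
    lb <- unclass(labels[[id]])
    if (!is.null(masks) && !is.null(masks[[id]])) {
      sc <- sc[masks[[id]] > 0, , drop = FALSE]
      lb <- lb[masks[[id]] > 0, , drop = FALSE]
    }
    dplyr::bind_rows(lapply(seq_len(n_heads()), function(h) {
      if (length(unique(lb[, h])) < 2) return(NULL)
      m <- head_metrics(sc[, h], lb[, h], thr[h], idr_labels()[h])
      m$protein_id <- id
      m
    }))
  })
  all <- dplyr::bind_rows(per)
  if (nrow(all) == 0) abort("No protein contains both classes for any head")
  out <- dplyr::summarise(
    dplyr::group_by(all, .data$label),
    dplyr::across(c("auc", "aupr", "aps", "fmax", "mcc", "bacc"),
                  mean),
    threshold = thr[unique(.data$label)],
    n_proteins = dplyr::n(),
    .groups = "drop")
  out[match(intersect(idr_labels(), out$label), out$label), ]
}

head_metrics <- function(s, y, threshold, label) {
  both <- length(unique(y)) == 2
  auc <- if (both) metric_auc(s, y) else NA_real_
  pr <- if (sum(y) > 0) metric_aupr_aps(s, y) else list(aupr = NA_real_,
                                                        aps = NA_real_)
  fm <- if (sum(y) > 0) metric_fmax(s, y)$fmax else NA_real_
  pred <- as.integer(s >= threshold)
  mb <- metric_mcc_bacc(tp = sum(pred == 1 & y == 1),
                        fp = sum(pred == 1 & y == 0),
                        tn = sum(pred == 0 & y == 0),
                        fn = sum(pred == 0 & y == 1))
  tibble(label = label, auc = auc, aupr = pr$aupr, aps = pr$aps, fmax = fm,
         mcc = mb$mcc, bacc = mb$bacc, threshold = unname(threshold),
         n_pos = sum(y == 1), n_neg = sum(y == 0))
}

#' Multifunctional-residue evaluation
#'
#' Residues carrying two or more true function labels are grouped by their
#' exact label set (the "MF type"). A residue of a type is counted as
#' correctly predicted only if every function of that type is called
#' positive. For the threshold-free Fmax, every residue is assigned a
#' type-level score equal to the minimum of the involved heads' scores
#' (the conservative AND-consistent reduction) and the type indicator is
#' used as the binary truth.
#'
#' @inheritParams evaluate_predictions
#' @return A tibble with one row per MF type: `mf_type` (labels joined by
#'   `+`), `n_residues`, `n_correct` (at the supplied thresholds),
#'   `fmax`, `fmax_threshold`. Empty (with a warning) when the data
#'   contain no multifunctional residues.
#' @export
mf_residue_eval <- function(profiles, labels, thresholds) {
  ids <- names(profiles)
  thr <- threshold_vector(thresholds)
  sc <- do.call(rbind, lapply(ids, function(id) unclass_profile(profiles[[id]])))
  lb <- do.call(rbind, lapply(ids, function(id) unclass(labels[[id]])))
  fun_idx <- 2:7
  fl <- idr_function_labels()
  n_fun <- lb[, fun_idx, drop = FALSE]
  type_of <- apply(n_fun, 1, function(r) {
    if (sum(r) >= 2) paste(fl[r == 1], collapse = "+") else NA_character_
  })
  types <- sort(unique(stats::na.omit(type_of)))
  if (length(types) == 0) {
    warn("No multifunctional residues in the data")
    return(tibble(mf_type = character(), n_residues = integer(),
                  n_correct = integer(), fmax = numeric(),
                  fmax_threshold = numeric()))
  }
  dplyr::bind_rows(lapply(types, function(tp) {
    members <- strsplit(tp, "+", fixed = TRUE)[[1]]
    cols <- match(members, idr_labels())
    truth <- as.integer(!is.na(type_of) & type_of == tp)
    type_score <- apply(sc[, cols, drop = FALSE], 1, min)
    called <- rowSums(sweep(sc[, cols, drop = FALSE], 2, thr[cols],
                            `>=`)) == length(cols)
    fm <- metric_fmax(type_score, truth)
    tibble(mf_type = tp,
           n_residues = sum(truth),
           n_correct = sum(called & truth == 1),
           fmax = fm$fmax,
           fmax_threshold = fm$threshold)
  }))
}

#' Compare two predictors by paired bootstrap over proteins
#'
#' Resamples proteins with replacement, recomputes the pooled AUC of each
#' predictor per head on every resample, and reports a two-sided p-value
#' for the AUC difference.
#'
#' @param profiles_a,profiles_b Named lists of `L x 7` propensity
#'   matrices over the same proteins.
#' @param labels Named list of matching label matrices.
#' @param n_resamples Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return Tibble with `label`, `auc_a`, `auc_b`, `delta`, `p_value`.
#' @export
compare_predictors <- function(profiles_a, profiles_b, labels,
                               n_resamples = 1000L, seed = 1L) {
  ids <- names(profiles_a)
  if (!setequal(ids, names(profiles_b))) {
    abort("The two predictors cover different proteins")
  }
  if (length(ids) < 2) abort("At least two proteins are required")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  sc_a <- lapply(ids, function(id) unclass_profile(profiles_a[[id]]))
  sc_b <- lapply(ids, function(id) unclass_profile(profiles_b[[id]]))
  lb <- lapply(ids, function(id) unclass(labels[[id]]))
  pooled_auc <- function(sc_list, lb_list, h) {
    s <- unlist(lapply(sc_list, function(m) m[, h]))
    y <- unlist(lapply(lb_list, function(m) m[, h]))
    if (length(unique(y)) < 2) return(NA_real_)
    metric_auc(s, y)
  }
  draws <- lapply(seq_len(n_resamples), function(b) {
    sample.int(length(ids), replace = TRUE)
  })
  dplyr::bind_rows(lapply(seq_len(n_heads()), function(h) {
    a0 <- pooled_auc(sc_a, lb, h)
    b0 <- pooled_auc(sc_b, lb, h)
    deltas <- vapply(draws, function(idx) {
      d <- pooled_auc(sc_a[idx], lb[idx], h) - pooled_auc(sc_b[idx], lb[idx], h)
      d
    }, numeric(1))
    deltas <- deltas[is.finite(deltas)]
    p <- if (length(deltas) == 0) NA_real_ else {
      min(1, 2 * min((1 + sum(deltas <= 0)) / (length(deltas) + 1),
                     (1 + sum(deltas >= 0)) / (length(deltas) + 1)))
    }
    tibble(label = idr_labels()[h], auc_a = a0, auc_b = b0,
           delta = a0 - b0, p_value = p)
  }))
}
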