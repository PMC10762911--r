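## Shannon entropy and pairwise information gain over the six function
## labels. The information gain between two binary labels is the reduction
## in entropy achieved by predicting them jointly rather than separately,
## i.e. the mutual information H(X) + H(Y) - H(X, Y) in bits. The 6 x 6 IG
## matrix estimated on a training set initializes the functional-graph
## adjacency.

#' Shannon entropy of a discrete distribution, in bits
#'
#' @param p Probability vector (sums to 1 within 1e-9, entries >= 0).
#' @return Entropy `-sum(p * log2(p))` with `0 * log 0 := 0`; nonnegative.
#' @examples
#' entropy(c(0.5, 0.5))   # 1 bit
#' entropy(c(0.25, 0.75)) # 0.8112781
#' @export
entropy <- function(p) {
  if (any(p < 0)) abort("Probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("Probabilities must sum to 1 (got %.12f)", sum(p)))
  }
  nz <- p[p > 0]
  max(0, -sum(nz * log2(nz)))
}

#' Estimate per-label and pairwise label distributions
#'
#' Pools all residues of all supplied label matrices (the pooling unit is
#' the residue, matching the residue-level loss) and estimates, over the
#' six function columns only, the marginal probability of each label and
#' the 2 x 2 joint table of every unordered pair.
#'
#' @param labels List of `L x 7` label matrices (see
#'   [build_label_matrix()]).
#' @return A `label_distribution`: list with `marginal` (named length-6
#'   vector), `joint` (named list of 2 x 2 tables, rows = X in 0/1,
#'   columns = Y in 0/1) and `n_residues`.
#' @export
estimate_distribution <- function(labels) {
  if (length(labels) == 0) abort("At least one label matrix is required")
  fun <- do.call(rbind, lapply(labels, function(m) {
    m[, idr_function_labels(), drop = FALSE]
  }))
  n <- nrow(fun)
  if (n == 0) abort("Label matrices contain no residues")
  marginal <- colMeans(fun)
  fl <- idr_function_labels()
  joint <- list()
  for (a in seq_len(5)) {
    for (b in seq(a + 1, 6)) {
      x <- fun[, a]
      y <- fun[, b]
      tab <- matrix(c(mean(x == 0 & y == 0), mean(x == 0 & y == 1),
                      mean(x == 1 & y == 0), mean(x == 1 & y == 1)),
                    nrow = 2, byrow = TRUE,
                    dimnames = list(X = c("0", "1"), Y = c("0", "1")))
      joint[[pair_key(fl[a], fl[b])]] <- tab
    }
  }
  structure(list(marginal = marginal, joint = joint, n_residues = n),
            class = "label_distribution")
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

joint_table <- function(dist, x, y) {
  fl <- idr_function_labels()
  tab <- dist$joint[[pair_key(fl[x], fl[y])]]
  if (fl[x] > fl[y]) tab <- t(tab)  # stored with the lexicographically
  tab                               # smaller label as X
}

#' Information gain between two function labels, in bits
#'
#' `H(X) + H(Y) - H(X, Y)`: the entropy saved by predicting the pair
#' jointly instead of separately. Equals the mutual information; clipped
#' at zero to absorb floating-point rounding.
#'
#' @param dist A `label_distribution` from [estimate_distribution()].
#' @param x,y Distinct function indices in 1..6 (order of
#'   [idr_function_labels()]).
#' @return Nonnegative information gain in bits.
#' @export
information_gain <- function(dist, x, y) {
  if (x == y) abort("x and y must differ; use entropy() for a single label")
  tab <- joint_table(dist, x, y)
  hx <- entropy(c(dist$marginal[x], 1 - dist$marginal[x]))
  hy <- entropy(c(dist$marginal[y], 1 - dist$marginal[y]))
  hxy <- entropy(as.vector(tab))
  max(0, hx + hy - hxy)
}

#' Pairwise information-gain matrix over the six function labels
#'
#' Off-diagonal entries are pairwise information gains; the diagonal
#' stores each label's own entropy H(X). Symmetric by construction.
#'
#' @param labels List of `L x 7` label matrices.
#' @return A 6 x 6 `ig_matrix` (numeric matrix subclass) in bits, with
#'   function labels as dimnames.
#' @export
ig_matrix <- function(labels) {
  dist <- estimate_distribution(labels)
  fl <- idr_function_labels()
  m <- matrix(0, 6, 6, dimnames = list(fl, fl))
  for (a in 1:6) {
    m[a, a] <- entropy(c(dist$marginal[a], 1 - dist$marginal[a]))
  }
  for (a in 1:5) {
    for (b in (a + 1):6) {
      ig <- information_gain(dist, a, b)
      m[a, b] <- ig
      m[b, a] <- ig
    }
  }
  structure(m, class = c("ig_matrix", "matrix", "array"))
}

#' Write an information-gain matrix to a TSV file
#'
#' Serialized with full double precision (hex float), so a write/read
#' round-trip is bit-exact.
#'
#' @param ig An `ig_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ig_matrix <- function(ig, path) {
  fl <- idr_function_labels()
  lines <- c(paste(c("label", fl), collapse = "\t"))
  for (a in 1:6) {
    lines <- c(lines, paste(c(fl[a], sprintf("%a", unclass(ig)[a, ])),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an information-gain matrix from a TSV file
#'
#' @param path Path written by [write_ig_matrix()].
#' @return An `ig_matrix`.
#' @export
read_ig_matrix <- function(path) {
  lines <- readLines(path)
  fl <- idr_function_labels()
  body <- strsplit(lines[-1], "\t")
  m <- do.call(rbind, lapply(body, function(x) {
    vapply(x[-1], function(v) as.double(strtoi_hexfloat(v)), numeric(1))
  }))
  dimnames(m) <- list(fl, fl)
  structure(m, class = c("ig_matrix", "matrix", "array"))
}

strtoi_hexfloat <- function(s) {
  ## R's as.numeric understands C99 hex-float literals ("0x1.9p-3")
  as.numeric(s)
}

#' @export
tidy.ig_matrix <- function(x, ...) {
  m <- unclass(x)
  df <- as_tibble(as.data.frame(as.table(m), stringsAsFactors = FALSE))
  names(df) <- c("label_x", "label_y", "bits")
  df$quantity <- ifelse(df$label_x == df$label_y, "entropy",
                        "information_gain")
  as_tibble(df[, c("label_x", "label_y", "quantity", "bits")])
}

#' @export
autoplot.ig_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label_x, y = .data$label_y,
                                   fill = .data$bits)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$bits)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "bits",
                  title = "Pairwise information gain (diagonal: entropy)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
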