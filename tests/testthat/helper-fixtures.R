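## Shared fixture builders. Everything is generated in code; no binary
## fixtures on disk.

tiny_proteins <- function() {
  tibble::tibble(
    id = c("P1", "P2"),
    sequence = c("ACDEFGHIKL", "MNPQRSTVWY"),
    length = c(10L, 10L)
  )
}

tiny_regions <- function() {
  tibble::tibble(
    protein_id = c("P1", "P1", "P2"),
    label = c("disorder", "protein_binding", "linker"),
    start = c(2L, 4L, 1L),
    end = c(6L, 5L, 3L)
  )
}

## A label matrix with prescribed function columns (disorder = union).
label_matrix_from <- function(columns, L = NULL) {
  L <- L %||% length(columns[[1]])
  m <- matrix(0L, L, 7, dimnames = list(NULL, idr_labels()))
  for (nm in names(columns)) m[, nm] <- columns[[nm]]
  m[, "disorder"] <- as.integer(rowSums(m[, idr_function_labels()]) > 0)
  m
}

## Random small label sets for property tests.
random_label_set <- function(n_proteins, L, p = 0.3) {
  lapply(seq_len(n_proteins), function(i) {
    m <- matrix(rbinom(L * 7, 1, p), L, 7,
                dimnames = list(NULL, idr_labels()))
    m
  })
}

## Brute-force IG oracle: enumerate the four joint outcomes directly from
## pooled residue labels. Independent of estimate_distribution().
brute_force_ig <- function(labels, x, y) {
  fun <- do.call(rbind, lapply(labels, function(m) {
    m[, idr_function_labels(), drop = FALSE]
  }))
  xv <- fun[, x]
  yv <- fun[, y]
  n <- length(xv)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  hx <- h(c(mean(xv), 1 - mean(xv)))
  hy <- h(c(mean(yv), 1 - mean(yv)))
  pj <- c(sum(xv == 0 & yv == 0), sum(xv == 0 & yv == 1),
          sum(xv == 1 & yv == 0), sum(xv == 1 & yv == 1)) / n
  max(0, hx + hy - h(pj))
}

tiny_model <- function(D = 4, H = 3, A = 3, F = 2, seed = 5, ig = NULL) {
  cfg <- gim_config(embed_dim = D, bigru_hidden = H, attn_hidden = A,
                    node_dim = F, seed = seed)
  gim_init(cfg, ig = ig)
}

random_embedding <- function(L, D, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(L * D), L, D))
}

`%||%` <- rlang::`%||%`
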