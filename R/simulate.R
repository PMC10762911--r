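## Seeded synthetic datasets: random amino-acid sequences, contiguous
## functional regions per label with controllable pairwise co-occurrence
## (hence controllable information gain between labels), a disorder track
## that is a strict superset of all functional residues, and per-residue
## embeddings carrying a recoverable orthogonal signature for each active
## label plus Gaussian noise.

#' Simulation configuration
#'
#' @param n_proteins Number of proteins to generate.
#' @param length_range Length-2 integer range of protein lengths
#'   (inclusive, uniform).
#' @param density Expected fraction of residues covered by each function
#'   label's own (primary) regions.
#' @param mean_region_length Mean length of a contiguous region
#'   (geometric lengths, memoryless).
#' @param cooccurrence Symmetric 6 x 6 matrix of probabilities that a
#'   placed region of label x spawns an overlapping region of label y
#'   (diagonal ignored). Scalar shorthand fills all off-diagonals.
#' @param disorder_density Expected coverage of disorder-only regions
#'   added on top of the functional union.
#' @param embed_dim Embedding dimension D (must be at least 7).
#' @param snr Signal-to-noise ratio of the embeddings: signature vectors
#'   have unit norm and the Gaussian noise has sd `1/snr`.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 20L, length_range = c(40L, 80L),
                       density = 0.12, mean_region_length = 8,
                       cooccurrence = 0, disorder_density = 0.08,
                       embed_dim = 16L, snr = 5, seed) {
  if (missing(seed)) abort("sim_config() requires an explicit seed")
  if (length(cooccurrence) == 1) {
    cooccurrence <- matrix(cooccurrence, 6, 6)
  }
  diag(cooccurrence) <- 0
  stopifnot(all(cooccurrence >= 0), all(cooccurrence <= 1),
            isTRUE(all.equal(cooccurrence, t(cooccurrence))),
            length(length_range) == 2, length_range[1] >= 1,
            length_range[2] >= length_range[1],
            density > 0, density <= 1, disorder_density >= 0,
            mean_region_length >= 1, embed_dim >= 7, snr > 0)
  ## expected total coverage per label: primary regions plus spawned ones
  expected <- density * (1 + colSums(cooccurrence))
  if (any(expected > 1)) {
    abort(paste0("Infeasible densities: expected coverage above 1 for ",
                 paste(idr_function_labels()[expected > 1], collapse = ", ")))
  }
  dimnames(cooccurrence) <- list(idr_function_labels(),
                                 idr_function_labels())
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 density = density,
                 mean_region_length = mean_region_length,
                 cooccurrence = cooccurrence,
                 disorder_density = disorder_density,
                 embed_dim = as.integer(embed_dim),
                 snr = snr,
                 seed = as.integer(seed)), class = "sim_config")
}

sample_regions_for_label <- function(L, label, density, mean_len) {
  n_reg <- rpois(1, L * density / mean_len)
  if (n_reg == 0) return(NULL)
  start <- sample.int(L, n_reg, replace = TRUE)
  len <- pmin(1 + stats::rgeom(n_reg, 1 / mean_len), L)
  tibble(label = label, start = start,
         end = pmin(start + len - 1L, L))
}

#' Generate a complete synthetic dataset
#'
#' For each protein, contiguous regions are placed per function label; for
#' every placed region of label x and every other label y, an overlapping
#' region of y is added with the configured co-occurrence probability
#' (sharing the x-region's start). Disorder is the union of all
#' functional residues plus independent disorder-only regions. Embeddings
#' carry one orthogonal unit signature per active label plus noise.
#' Bit-reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @return List with `proteins` (tibble id/sequence/length), `regions`
#'   (tibble), `labels` (named list of `L x 7` matrices), `embeddings`
#'   (named list of `L x D` matrices).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  fl <- idr_function_labels()
  proteins <- list()
  regions <- list()
  for (k in seq_len(config$n_proteins)) {
    id <- sprintf("SYN%04d", k)
    L <- sample(seq(config$length_range[1], config$length_range[2]), 1)
    seq_chars <- sample(AA_CANONICAL, L, replace = TRUE)
    proteins[[k]] <- tibble(id = id,
                            sequence = paste(seq_chars, collapse = ""),
                            length = L)
    reg_k <- list()
    for (x in seq_along(fl)) {
      primary <- sample_regions_for_label(L, fl[x], config$density,
                                          config$mean_region_length)
      if (is.null(primary)) next
      reg_k[[length(reg_k) + 1]] <- primary
      ## spawned overlapping regions of correlated labels
      for (r in seq_len(nrow(primary))) {
        for (y in seq_along(fl)) {
          if (y == x) next
          if (runif(1) < config$cooccurrence[x, y]) {
            len <- pmin(1 + stats::rgeom(1, 1 / config$mean_region_length), L)
            reg_k[[length(reg_k) + 1]] <- tibble(
              label = fl[y], start = primary$start[r],
              end = pmin(primary$start[r] + len - 1L, L))
          }
        }
      }
    }
    ## disorder: union of functional regions plus disorder-only stretches
    fun_reg <- dplyr::bind_rows(reg_k)
    if (nrow(fun_reg) > 0) {
      reg_k[[length(reg_k) + 1]] <- tibble(label = "disorder",
                                           start = fun_reg$start,
                                           end = fun_reg$end)
    }
    dis_only <- sample_regions_for_label(L, "disorder",
                                         config$disorder_density,
                                         config$mean_region_length)
    if (!is.null(dis_only)) reg_k[[length(reg_k) + 1]] <- dis_only
    if (length(reg_k) > 0) {
      rk <- dplyr::bind_rows(reg_k)
      rk$protein_id <- id
      regions[[length(regions) + 1]] <- rk[, c("protein_id", "label",
                                               "start", "end")]
    }
  }
  proteins <- dplyr::bind_rows(proteins)
  regions <- if (length(regions) > 0) dplyr::bind_rows(regions) else {
    tibble(protein_id = character(), label = character(),
           start = integer(), end = integer())
  }
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  labels <- build_label_matrices(proteins, regions)
  embeddings <- lapply(labels, function(lab) {
    signal_embedding_matrix(lab, config$embed_dim, config$snr)
  })
  list(proteins = proteins, regions = regions, labels = labels,
       embeddings = embeddings)
}

label_signatures <- function(D) {
  ## orthonormal signatures: one coordinate axis per label
  diag(1, n_heads(), D)
}

signal_embedding_matrix <- function(labels, D, snr) {
  sig <- label_signatures(D)
  base <- unclass(labels) %*% sig           # L x D sum of active signatures
  noise <- matrix(rnorm(length(base), sd = 1 / snr), nrow(base), ncol(base))
  base + noise
}

#' Embeddings carrying a recoverable per-label signal
#'
#' Each residue's vector is the sum of one orthogonal unit signature per
#' active label plus isotropic Gaussian noise with sd `1/snr`.
#'
#' @param labels An `L x 7` label matrix.
#' @param config A [sim_config()] (supplies `embed_dim`, `snr`, `seed`).
#' @return An `L x D` embedding matrix.
#' @export
make_signal_embeddings <- function(labels, config) {
  if (config$embed_dim < n_heads()) {
    abort("embed_dim must be at least the number of labels (7)")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)
  signal_embedding_matrix(labels, config$embed_dim, config$snr)
}
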