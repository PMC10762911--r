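## Per-residue embedding storage and built-in encoders.
##
## Embeddings live in a directory container: one tab-separated L x D matrix
## per protein (<id>.tsv) plus a meta.tsv recording the encoder tag and
## dimension. The same per-protein plain-text matrix format is accepted
## standalone, so precomputed protein-language-model or PSSM features can
## be dropped in from any external pipeline.

#' Write an embedding set to a directory container
#'
#' @param embeddings Named list of `L x D` numeric matrices keyed by
#'   protein id.
#' @param dir Directory to create/overwrite.
#' @param encoder_tag Free string naming the encoder that produced the
#'   vectors (e.g. `"one_hot"`, `"synthetic"`, `"prot_t5"`).
#' @return `dir`, invisibly.
#' @export
write_embeddings <- function(embeddings, dir, encoder_tag = "unknown") {
  dims <- unique(vapply(embeddings, ncol, integer(1)))
  if (length(dims) != 1) {
    abort("All embedding matrices in a set must share one dimension D")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(embeddings)) {
    m <- embeddings[[id]]
    if (!all(is.finite(m))) abort(paste0("Non-finite embedding for ", id))
    utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                       file.path(dir, paste0(id, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  writeLines(c(paste0("encoder_tag\t", encoder_tag),
               paste0("dim\t", dims)),
             file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' Read an embedding set from a directory container
#'
#' @param dir Directory written by [write_embeddings()].
#' @param ids Optional protein ids to load (default: all present).
#' @return Named list of `L x D` matrices with attribute `encoder_tag`.
#' @export
read_embeddings <- function(dir, ids = NULL) {
  if (!dir.exists(dir)) abort(paste0("Embedding directory not found: ", dir))
  meta_path <- file.path(dir, "meta.tsv")
  tag <- "unknown"
  if (file.exists(meta_path)) {
    meta <- readLines(meta_path)
    tag <- sub("^encoder_tag\t", "", meta[startsWith(meta, "encoder_tag")])
  }
  files <- list.files(dir, pattern = "\\.tsv$", full.names = FALSE)
  files <- setdiff(files, "meta.tsv")
  have <- sub("\\.tsv$", "", files)
  if (is.null(ids)) ids <- have
  missing <- setdiff(ids, have)
  if (length(missing) > 0) {
    abort(paste0("No embedding stored for id(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- lapply(ids, function(id) {
    as.matrix(utils::read.table(file.path(dir, paste0(id, ".tsv")),
                                sep = "\t", colClasses = "numeric"))
  })
  out <- lapply(out, function(m) {
    dimnames(m) <- NULL
    m
  })
  out <- setNames(out, ids)
  attr(out, "encoder_tag") <- tag
  out
}

#' One-hot encode amino-acid sequences
#'
#' A built-in encoder producing `L x 21` matrices over the 20 canonical
#' amino acids plus `X`. Carries no context; useful as a baseline feature
#' set and for exercising the model machinery without external embeddings.
#'
#' @param proteins Protein tibble from [read_fasta()].
#' @return Named list of `L x 21` 0/1 matrices.
#' @export
encode_one_hot <- function(proteins) {
  alphabet <- c(AA_CANONICAL, "X")
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    chars <- strsplit(proteins$sequence[i], "")[[1]]
    idx <- match(chars, alphabet)
    idx[is.na(idx)] <- length(alphabet)
    m <- matrix(0, nrow = length(chars), ncol = length(alphabet))
    m[cbind(seq_along(chars), idx)] <- 1
    m
  })
  setNames(out, proteins$id)
}
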