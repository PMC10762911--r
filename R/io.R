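## Sequence, region-annotation and prediction-file input/output.
## Coordinates in files are 1-based inclusive (DisProt convention); the
## package keeps them 1-based inclusive in all user-facing tibbles too and
## only converts where indexing demands it.

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and any letter outside the 20 canonical amino
#' acids (and `X`) is mapped to `X` with a warning. Duplicate identifiers
#' and sequences longer than `max_length` are errors; very long chains are
#' rejected rather than windowed.
#'
#' @param path Path to a FASTA file.
#' @param max_length Maximum accepted sequence length (default 30000).
#' @return A tibble with columns `id`, `sequence`, `length`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1", "ACDE", ">P2", "MKV"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, max_length = 30000L) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(paste0("FASTA file is empty: ", path))
  ids <- sub("\\s.*$", "", names(aa))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(aa))
  cleaned <- gsub(paste0("[^", paste(AA_CANONICAL, collapse = ""), "X]"),
                  "X", seqs)
  if (any(cleaned != seqs)) {
    warn(paste0(sum(cleaned != seqs),
                " sequence(s) contained non-canonical letters; mapped to X"))
  }
  len <- nchar(cleaned)
  too_long <- len > max_length
  if (any(too_long)) {
    abort(paste0("Sequence(s) exceed max_length = ", max_length, ": ",
                 paste(ids[too_long], collapse = ", ")))
  }
  tibble(id = unname(ids), sequence = unname(cleaned), length = unname(len))
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Tibble with columns `id`, `sequence` (as from
#'   [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a region annotation table
#'
#' Reads a tab-separated table with columns `protein_id`, `label`, `start`,
#' `end` (1-based inclusive, `#` comments allowed) and validates every
#' region against the referenced protein: known id, label from the
#' seven-label vocabulary, and `1 <= start <= end <= L`.
#'
#' @param path Path to the TSV region table.
#' @param proteins Protein tibble from [read_fasta()] used for validation.
#' @return A tibble with columns `protein_id`, `label`, `start`, `end`.
#' @export
read_regions <- function(path, proteins) {
  if (!file.exists(path)) abort(paste0("Region file not found: ", path))
  reg <- readr::read_tsv(path, comment = "#",
                         col_names = c("protein_id", "label", "start", "end"),
                         col_types = readr::cols(
                           protein_id = readr::col_character(),
                           label = readr::col_character(),
                           start = readr::col_integer(),
                           end = readr::col_integer()))
  validate_regions(reg, proteins)
}

#' Validate a region annotation tibble
#'
#' @param regions Tibble with columns `protein_id`, `label`, `start`, `end`.
#' @param proteins Protein tibble for length lookup.
#' @return The validated `regions` tibble.
#' @export
validate_regions <- function(regions, proteins) {
  assert_label(regions$label)
  unknown <- setdiff(unique(regions$protein_id), proteins$id)
  if (length(unknown) > 0) {
    abort(paste0("Region(s) refer to unknown protein id(s): ",
                 paste(unknown, collapse = ", ")))
  }
  len <- setNames(proteins$length, proteins$id)
  bad <- regions$start < 1L | regions$start > regions$end |
    regions$end > len[regions$protein_id]
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "Region out of bounds for protein %s: %s [%d, %d] with L = %d",
      regions$protein_id[i], regions$label[i], regions$start[i],
      regions$end[i], len[[regions$protein_id[i]]]))
  }
  as_tibble(regions)
}

#' Write a region annotation table
#'
#' @param regions Region tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  readr::write_tsv(regions[, c("protein_id", "label", "start", "end")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Build a per-residue label matrix from region annotations
#'
#' Position `p` gets a 1 in column `c` iff some region with label `c`
#' covers it; overlapping regions of the same label are idempotent, and the
#' result is invariant to region order.
#'
#' @param protein One-row protein tibble (or a row of [read_fasta()] output).
#' @param regions Region tibble; only rows matching the protein id are used.
#' @return An `L x 7` binary matrix with labelled columns and attribute
#'   `protein_id`.
#' @examples
#' p <- tibble::tibble(id = "P1", sequence = "ACDE", length = 4L)
#' r <- tibble::tibble(protein_id = "P1", label = "disorder",
#'                     start = 2L, end = 3L)
#' build_label_matrix(p, r)
#' @export
build_label_matrix <- function(protein, regions) {
  stopifnot(nrow(protein) == 1)
  L <- protein$length
  lab <- matrix(0L, nrow = L, ncol = n_heads(),
                dimnames = list(NULL, idr_labels()))
  reg <- regions[regions$protein_id == protein$id, , drop = FALSE]
  if (nrow(reg) > 0) {
    assert_label(reg$label)
    if (any(reg$end > L | reg$start < 1L)) {
      abort(paste0("Region out of bounds for protein ", protein$id))
    }
    for (k in seq_len(nrow(reg))) {
      lab[reg$start[k]:reg$end[k], reg$label[k]] <- 1L
    }
  }
  attr(lab, "protein_id") <- protein$id
  lab
}

#' Build label matrices for many proteins
#'
#' @param proteins Protein tibble.
#' @param regions Region tibble covering any subset of the proteins.
#' @return Named list of label matrices, one per protein, in `proteins` order.
#' @export
build_label_matrices <- function(proteins, regions) {
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    build_label_matrix(proteins[i, ], regions)
  })
  setNames(out, proteins$id)
}

#' Write a per-residue prediction file
#'
#' CAID-style per-residue output: two header lines (`# <protein_id>` and
#' `# thresholds t1..t7`), then tab-separated rows of position, residue
#' letter, seven propensity scores (4 decimal places) and seven binary
#' calls. A score equal to its threshold is called positive.
#'
#' @param profile `L x 7` propensity matrix (a [gim_forward()] result).
#' @param sequence Amino-acid string of length `L`.
#' @param thresholds Numeric vector of 7 thresholds in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(profile, sequence, thresholds, path) {
  scores <- unclass_profile(profile)
  L <- nrow(scores)
  if (nchar(sequence) != L) {
    abort(sprintf("Profile has %d rows but sequence has %d residues",
                  L, nchar(sequence)))
  }
  stopifnot(length(thresholds) == n_heads())
  id <- attr(profile, "protein_id") %||% "unknown"
  rounded <- round(scores, 4)
  binary <- matrix(as.integer(sweep(rounded, 2, thresholds, `>=`)),
                   nrow = L)
  lines <- c(
    paste0("# ", id),
    paste0("# thresholds ", paste(sprintf("%.4f", thresholds), collapse = "\t"))
  )
  body <- vapply(seq_len(L), function(i) {
    paste(c(i, substr(sequence, i, i),
            sprintf("%.4f", rounded[i, ]), binary[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a per-residue prediction file
#'
#' @param path Path written by [write_predictions()].
#' @return A list with `protein_id`, `thresholds` (length 7), `scores`
#'   (`L x 7` matrix), `binary` (`L x 7` integer matrix), `residues`
#'   (character vector) and `positions`.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) abort(paste0("Malformed prediction file: ", path))
  id <- sub("^# ", "", lines[1])
  thr <- as.numeric(strsplit(sub("^# thresholds ", "", lines[2]), "\t")[[1]])
  body <- strsplit(lines[-(1:2)], "\t")
  mat <- do.call(rbind, lapply(body, function(x) as.numeric(x[-2])))
  pos <- as.integer(mat[, 1])
  if (!identical(pos, seq_along(pos))) {
    abort(paste0("Prediction file positions are not consecutive 1..L: ", path))
  }
  scores <- mat[, 2:8, drop = FALSE]
  colnames(scores) <- idr_labels()
  binary <- matrix(as.integer(mat[, 9:15]), ncol = n_heads(),
                   dimnames = list(NULL, idr_labels()))
  structure(list(
    protein_id = id,
    thresholds = thr,
    scores = scores,
    binary = binary,
    residues = vapply(body, `[`, character(1), 2),
    positions = pos
  ), class = "idr_prediction")
}

#' Convert a prediction to a tidy tibble
#'
#' @param x An `idr_prediction` from [read_predictions()].
#' @param ... Unused.
#' @return A long tibble with `protein_id`, `pos`, `residue`, `label`,
#'   `score`, `call`.
#' @export
tidy.idr_prediction <- function(x, ...) {
  wide <- tibble(
    protein_id = x$protein_id,
    pos = x$positions,
    residue = x$residues
  )
  sc <- as_tibble(x$scores)
  bn <- as_tibble(x$binary)
  names(bn) <- paste0(names(bn), "_call")
  long_s <- tidyr::pivot_longer(cbind(wide, sc), cols = idr_labels(),
                                names_to = "label", values_to = "score")
  long_b <- tidyr::pivot_longer(cbind(wide, bn),
                                cols = paste0(idr_labels(), "_call"),
                                names_to = "label", values_to = "call")
  long_s$call <- long_b$call
  as_tibble(long_s)
}

unclass_profile <- function(profile) {
  m <- unclass(profile)
  attr(m, "protein_id") <- NULL
  m
}
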