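#' Label vocabulary
#'
#' The package tracks seven per-residue binary labels: intrinsic disorder
#' plus six disordered functions. Column order is fixed everywhere:
#' disorder first, then the six functions.
#'
#' @return `idr_labels()` returns the seven label names in canonical order;
#'   `idr_function_labels()` returns the six function labels (disorder
#'   excluded), the unit over which information gain is computed.
#' @examples
#' idr_labels()
#' idr_function_labels()
#' @export
idr_labels <- function() {
  c("disorder", "protein_binding", "dna_binding", "rna_binding",
    "ion_binding", "lipid_binding", "linker")
}

#' @rdname idr_labels
#' @export
idr_function_labels <- function() {
  idr_labels()[-1L]
}

n_heads <- function() 7L
n_functions <- function() 6L

assert_label <- function(label) {
  bad <- setdiff(unique(label), idr_labels())
  if (length(bad) > 0) {
    abort(paste0("Unknown label(s): ", paste(bad, collapse = ", "),
                 ". Allowed: ", paste(idr_labels(), collapse = ", ")))
  }
  invisible(label)
}
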