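#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes in the fixed order used by
#' every property matrix and encoder in this package.
#'
#' @return Character vector of length 20 (`ACDEFGHIKLMNPQRSTVWY`).
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Split a sequence string into residues, validating against the canonical
# alphabet. `what` names the sequence in error messages.
split_residues <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a non-empty character string", call. = FALSE)
  res <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- which(!res %in% amino_acids())
  if (length(bad))
    stop(sprintf("%s contains non-canonical residue '%s' at position %d",
                 what, res[bad[1L]], bad[1L]), call. = FALSE)
  res
}
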