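#' HLA contact-residue pseudo-sequences
#'
#' A pseudo-sequence is the ordered subset of HLA residues that contact the
#' bound peptide (34 positions in the NetMHCpan-style scheme used here); it
#' is the compact allele representation that makes the classifier
#' pan-specific.  A `pseudoseq_registry` maps normalized allele names to
#' fixed-length pseudo-sequences and defines the columns of the image-like
#' array.
#'
#' @name pseudosequences
NULL

#' Normalize an HLA allele name
#'
#' Accepts the common spellings of classical class I allele names —
#' `HLA-A*31:01`, `HLA-A3101`, `A*31:01`, `A31:01`, `HLA-A*3101` — and
#' returns the canonical `HLA-A*31:01` form.  Names that do not look like
#' classical HLA class I alleles (for example the synthetic `SYN-A*01:01`
#' alleles) are returned unchanged apart from whitespace trimming.
#'
#' @param allele Character vector of allele names.
#' @return Character vector of normalized names.
#' @export
normalize_allele <- function(allele) {
  x <- trimws(as.character(allele))
  m <- regexec("^(?:HLA-)?([ABC])\\*?([0-9]{2,3}):?([0-9]{2,3})$", x)
  vapply(seq_along(x), function(i) {
    g <- regmatches(x[i], m[i])[[1L]]
    if (length(g) == 4L)
      sprintf("HLA-%s*%s:%s", g[2L], g[3L], g[4L])
    else x[i]
  }, character(1L))
}

#' Locus of an allele name
#'
#' Extracts the one-letter locus (e.g. `"A"` from `HLA-A*31:01` or
#' `SYN-A*01:01`), or `NA` when no locus can be identified.
#'
#' @param allele Character vector of allele names.
#' @return Character vector of locus letters.
#' @export
allele_locus <- function(allele) {
  x <- normalize_allele(allele)
  m <- regexec("^[A-Z]+-([A-Z]+)\\*", x)
  vapply(seq_along(x), function(i) {
    g <- regmatches(x[i], m[i])[[1L]]
    if (length(g) == 2L) g[2L] else NA_character_
  }, character(1L))
}

#' Load a pseudo-sequence registry
#'
#' Reads a NetMHCpan-style two-column text file (allele name, whitespace,
#' residue string, one entry per line; `#` comments and blank lines
#' ignored).  The contact-residue count is inferred from the first entry
#' and every other entry must match it.
#'
#' @param path Path to the pseudo-sequence file.
#' @param scheme_name Identifier stored with the registry.
#' @return A `pseudoseq_registry`: list with `scheme_name`,
#'   `contact_count`, and `entries` (named character vector keyed by
#'   normalized allele name).
#' @export
load_pseudosequences <- function(path, scheme_name = "netmhcpan-contact") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("pseudo-sequence file is empty: ", path,
                           call. = FALSE)
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed pseudo-sequence line ", bad[1L], ": '", lines[bad[1L]],
         "'", call. = FALSE)
  alleles <- normalize_allele(vapply(parts, `[[`, "", 1L))
  seqs <- toupper(vapply(parts, `[[`, "", 2L))
  n <- nchar(seqs[1L])
  mismatch <- which(nchar(seqs) != n)
  if (length(mismatch))
    stop(sprintf(
      "pseudo-sequence length mismatch for allele %s: %d residues, expected %d",
      alleles[mismatch[1L]], nchar(seqs[mismatch[1L]]), n), call. = FALSE)
  for (i in seq_along(seqs)) split_residues(seqs[i], paste0("pseudo-sequence ",
                                                            alleles[i]))
  if (anyDuplicated(alleles))
    stop("duplicate allele in pseudo-sequence file: ",
         alleles[duplicated(alleles)][1L], call. = FALSE)
  entries <- stats::setNames(seqs, alleles)
  structure(list(scheme_name = scheme_name, contact_count = n,
                 entries = entries),
            class = "pseudoseq_registry")
}

#' Look up an allele's pseudo-sequence
#'
#' The query name is normalized first, so `HLA-A*31:01`, `HLA-A3101` and
#' `A*31:01` all resolve to the same entry.  Unknown alleles raise an
#' error listing the nearest covered names.
#'
#' @param registry A `pseudoseq_registry`.
#' @param allele Allele name in any accepted spelling.
#' @return A `pseudosequence`: list with `allele` (normalized) and
#'   `residues` (the contact-residue string).
#' @export
lookup_pseudosequence <- function(registry, allele) {
  stopifnot(inherits(registry, "pseudoseq_registry"))
  key <- normalize_allele(allele)
  if (length(key) != 1L) stop("lookup one allele at a time", call. = FALSE)
  if (!key %in% names(registry$entries)) {
    near <- names(registry$entries)[
      order(utils::adist(key, names(registry$entries)))]
    stop(sprintf("allele not covered: %s (nearest: %s)", key,
                 paste(utils::head(near, 3L), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(allele = key, residues = registry$entries[[key]]),
            class = "pseudosequence")
}

#' @export
print.pseudoseq_registry <- function(x, ...) {
  cat(sprintf("Pseudo-sequence registry '%s': %d allele(s), %d contact residues\n",
              x$scheme_name, length(x$entries), x$contact_count))
  invisible(x)
}

#' @export
print.pseudosequence <- function(x, ...) {
  cat(sprintf("%s  %s\n", x$allele, x$residues))
  invisible(x)
}
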