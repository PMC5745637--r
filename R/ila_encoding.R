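#' Image-like array (ILA) encoding
#'
#' A peptide-HLA pair is encoded as a W x H x C numeric array: width W
#' indexes the HLA contact residues (34 in the default scheme), height H
#' the peptide positions (9 for nonapeptides), and the C = 2*S channels
#' hold the physicochemical property values of the residue pair at each
#' contact "pixel".  Channels `1..S` carry the peptide residue's property
#' values and channels `S+1..2S` the HLA residue's values; with the default
#' 9-scale property set this is the 34 x 9 x 18 encoding.
#'
#' @name ila_encoding
NULL

#' Encode one peptide-allele pair as an image-like array
#'
#' @param peptide Peptide sequence (canonical one-letter amino acids).
#' @param pseudo A `pseudosequence` (see [lookup_pseudosequence()]) or a
#'   plain contact-residue string.
#' @param scales A standardized `property_scales` object.
#' @return An `ila_array`: list with `data` (W x H x C array), `peptide`,
#'   `allele`, and `scale_names`.
#' @export
#' @examples
#' sc <- default_property_scales()
#' ps <- structure(list(allele = "HLA-X*00:00",
#'                      residues = strrep("A", 34)), class = "pseudosequence")
#' ila <- encode_pair("KVFGPIHEL", ps, sc)
#' dim(ila$data)   # 34 9 18
encode_pair <- function(peptide, pseudo, scales) {
  stopifnot(inherits(scales, "property_scales"))
  if (!scales$standardized)
    stop("property scales must be standardized before encoding",
         call. = FALSE)
  if (is.character(pseudo))
    pseudo <- structure(list(allele = NA_character_, residues = pseudo),
                        class = "pseudosequence")
  stopifnot(inherits(pseudo, "pseudosequence"))
  pep <- split_residues(peptide, "peptide")
  hla <- split_residues(pseudo$residues, "pseudo-sequence")
  W <- length(hla); H <- length(pep); S <- ncol(scales$values)
  pepv <- scales$values[pep, , drop = FALSE]   # H x S
  hlav <- scales$values[hla, , drop = FALSE]   # W x S
  data <- array(0, dim = c(W, H, 2L * S))
  for (s in seq_len(S)) {
    data[, , s] <- matrix(pepv[, s], nrow = W, ncol = H, byrow = TRUE)
    data[, , S + s] <- matrix(hlav[, s], nrow = W, ncol = H)
  }
  structure(list(data = data, peptide = toupper(peptide),
                 allele = pseudo$allele, scale_names = scales$scale_names),
            class = "ila_array")
}

#' Encode a batch of binding records
#'
#' Encodes every record whose allele resolves in the registry, preserving
#' input order.  Records with unresolvable alleles are collected into a
#' skip list, never silently dropped.
#'
#' @param records Binding-record data frame with at least `peptide` and
#'   `allele` columns (see [parse_binding_tsv()]).
#' @param registry A `pseudoseq_registry`.
#' @param scales A standardized `property_scales` object.
#' @return List with `ilas` (list of `ila_array`), `labels` (the records'
#'   `label` column subset to the encoded rows, or `NULL`), and `skipped`
#'   (data frame of row index, allele and reason).
#' @export
encode_batch <- function(records, registry, scales) {
  stopifnot(is.data.frame(records))
  ilas <- vector("list", nrow(records))
  ok <- logical(nrow(records))
  reasons <- character(0); skip_idx <- integer(0)
  for (i in seq_len(nrow(records))) {
    ps <- tryCatch(lookup_pseudosequence(registry, records$allele[i]),
                   error = function(e) conditionMessage(e))
    if (is.character(ps)) {
      skip_idx <- c(skip_idx, i); reasons <- c(reasons, ps)
      next
    }
    ilas[[i]] <- encode_pair(records$peptide[i], ps, scales)
    ok[i] <- TRUE
  }
  skipped <- data.frame(index = skip_idx,
                        allele = records$allele[skip_idx],
                        reason = reasons, stringsAsFactors = FALSE)
  labels <- if ("label" %in% names(records)) records$label[ok] else NULL
  list(ilas = ilas[ok], labels = labels, skipped = skipped)
}

#' Stack image-like arrays into a design matrix
#'
#' Flattens each W x H x C array column-major into one column of a
#' `(W*H*C) x n` matrix, the layout consumed by the network code.
#'
#' @param ilas List of `ila_array` objects of identical dimensions.
#' @return Numeric matrix, one column per array.
#' @export
ila_stack <- function(ilas) {
  stopifnot(length(ilas) > 0L)
  d <- dim(ilas[[1L]]$data)
  X <- matrix(0, nrow = prod(d), ncol = length(ilas))
  for (i in seq_along(ilas)) {
    di <- dim(ilas[[i]]$data)
    if (!identical(di, d))
      stop(sprintf("ILA %d has dims %s, expected %s", i,
                   paste(di, collapse = "x"), paste(d, collapse = "x")),
           call. = FALSE)
    X[, i] <- as.vector(ilas[[i]]$data)
  }
  attr(X, "ila_dim") <- d
  X
}

#' Export an image-like array as per-channel CSV files
#'
#' Debugging aid: writes one CSV per channel (`<prefix>_ch<k>.csv`), rows =
#' peptide positions (1-based), columns = contact residues.
#'
#' @param ila An `ila_array`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file names.
#' @export
write_ila_csv <- function(ila, prefix) {
  stopifnot(inherits(ila, "ila_array"))
  d <- dim(ila$data)
  files <- character(d[3L])
  for (k in seq_len(d[3L])) {
    m <- t(ila$data[, , k])            # H x W for display
    dimnames(m) <- list(paste0("pos", seq_len(d[2L])),
                        paste0("hla", seq_len(d[1L])))
    files[k] <- sprintf("%s_ch%02d.csv", prefix, k)
    utils::write.csv(m, files[k])
  }
  invisible(files)
}

#' @export
print.ila_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ILA %s / %s: %d (contact residues) x %d (peptide) x %d channels\n",
              x$peptide, if (is.na(x$allele)) "<no allele>" else x$allele,
              d[1L], d[2L], d[3L]))
  invisible(x)
}
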