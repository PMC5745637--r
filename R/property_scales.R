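#' Amino-acid physicochemical property scales
#'
#' A `property_scales` object holds a 20 x S matrix of per-amino-acid
#' physicochemical scores (one column per scale), with rows fixed to the
#' canonical amino-acid order ([amino_acids()]).  Scales populate the
#' channels of the image-like array encoding: each retained scale
#' contributes one peptide channel and one HLA channel, so an S-scale set
#' yields 2*S channels.
#'
#' @name property_scales
NULL

new_property_scales <- function(values, standardized = FALSE) {
  stopifnot(is.matrix(values), nrow(values) == 20L)
  structure(list(values = values,
                 scale_names = colnames(values),
                 standardized = isTRUE(standardized)),
            class = "property_scales")
}

#' Load an amino-acid property matrix
#'
#' Reads a plain CSV/TSV property table: a header of scale names, a first
#' column of one-letter amino-acid codes, and exactly 20 data rows.  Column
#' order in the file is preserved; values are returned unstandardized.
#'
#' @param path Path to the property table (comma- or tab-separated,
#'   inferred from the file extension; `.tsv`/`.txt` means tab).
#' @return A `property_scales` object with `standardized = FALSE`.
#' @seealso [standardize_scales()], [prune_correlated_scales()],
#'   [default_property_scales()]
#' @export
load_property_matrix <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L)
    stop("property table needs an amino-acid column plus at least one scale",
         call. = FALSE)
  aa <- toupper(trimws(as.character(tab[[1L]])))
  missing <- setdiff(amino_acids(), aa)
  if (length(missing))
    stop("property table is missing amino acid row(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  dup <- aa[duplicated(aa)]
  if (length(dup))
    stop("property table has duplicated amino acid row(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  scale_names <- colnames(tab)[-1L]
  if (anyDuplicated(scale_names))
    stop("duplicate scale name(s): ",
         paste(unique(scale_names[duplicated(scale_names)]), collapse = ", "),
         call. = FALSE)
  values <- as.matrix(tab[match(amino_acids(), aa), -1L, drop = FALSE])
  if (!is.numeric(values)) stop("property table has non-numeric values",
                                call. = FALSE)
  rownames(values) <- amino_acids()
  colnames(values) <- scale_names
  new_property_scales(values, standardized = FALSE)
}

#' Z-score property scales over the 20 amino acids
#'
#' Each scale column is centred to mean 0 and scaled to unit standard
#' deviation across the 20 amino acids.  The operation is idempotent.
#'
#' @param scales A `property_scales` object.
#' @return A standardized `property_scales` object.
#' @export
standardize_scales <- function(scales) {
  stopifnot(inherits(scales, "property_scales"))
  v <- scales$values
  sds <- apply(v, 2L, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero))
    stop("zero-variance scale(s): ",
         paste(colnames(v)[zero], collapse = ", "), call. = FALSE)
  v <- scale(v)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  new_property_scales(v, standardized = TRUE)
}

#' Drop highly correlated property scales
#'
#' Removes scales until no pair has squared Pearson correlation above
#' `r2_threshold` (default 0.8, the conventional redundancy cut-off for
#' this encoding).  Removal is greedy: among scales participating in a
#' violating pair, the one with the highest mean absolute correlation to
#' all remaining scales is dropped (ties broken in favour of dropping the
#' later column), and the scan repeats.  Relative order of survivors is
#' preserved.  Pearson correlation is shift/scale invariant, so pruning
#' commutes with [standardize_scales()].
#'
#' @param scales A `property_scales` object with at least two scales.
#' @param r2_threshold Squared-correlation threshold in (0, 1).
#' @return A `property_scales` object with the violating scales removed.
#' @export
prune_correlated_scales <- function(scales, r2_threshold = 0.8) {
  stopifnot(inherits(scales, "property_scales"))
  if (ncol(scales$values) < 2L)
    stop("need at least two scales to prune", call. = FALSE)
  if (!(r2_threshold > 0 && r2_threshold < 1))
    stop("r2_threshold must be in (0, 1)", call. = FALSE)
  keep <- seq_len(ncol(scales$values))
  repeat {
    if (length(keep) == 1L) {
      warning("all scales mutually correlated; a single scale remains")
      break
    }
    cm <- stats::cor(scales$values[, keep, drop = FALSE])
    r2 <- cm^2
    diag(r2) <- 0
    if (all(r2 <= r2_threshold)) break
    involved <- which(apply(r2 > r2_threshold, 1L, any))
    mean_abs <- rowSums(abs(cm)[involved, , drop = FALSE]) - 1
    mean_abs <- mean_abs / (length(keep) - 1L)
    worst <- involved[mean_abs >= max(mean_abs) - 1e-12]
    drop_local <- max(worst)   # tie-break: later column
    keep <- keep[-drop_local]
  }
  new_property_scales(scales$values[, keep, drop = FALSE],
                      standardized = scales$standardized)
}

#' Default property scale set
#'
#' Loads the property table shipped with the package: 11 widely used
#' published amino-acid indices (Kyte-Doolittle hydropathy, Hopp-Woods
#' hydrophilicity, residue volume, residue mass, Zimmerman bulkiness,
#' Grantham polarity, Zimmerman isoelectric point, side-chain net charge,
#' Bhaskaran-Ponnuswamy flexibility, and Chou-Fasman helix/sheet
#' propensities).  By default the table is correlation-pruned
#' at `r2_threshold` — which retains 9 of the 11 scales — and z-scored, the
#' working configuration of the default 18-channel encoder.
#'
#' @param pruned Apply [prune_correlated_scales()]? Default `TRUE`.
#' @param standardized Apply [standardize_scales()]? Default `TRUE`.
#' @param r2_threshold Squared-correlation threshold used when pruning.
#' @param path Optional replacement property table (same file format as
#'   [load_property_matrix()]).
#' @return A `property_scales` object.
#' @export
#' @examples
#' sc <- default_property_scales()
#' length(sc$scale_names)   # 9
default_property_scales <- function(pruned = TRUE, standardized = TRUE,
                                    r2_threshold = 0.8, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "property_scales.csv", package = "ilamhc",
                        mustWork = TRUE)
  sc <- load_property_matrix(path)
  if (pruned) sc <- prune_correlated_scales(sc, r2_threshold)
  if (standardized) sc <- standardize_scales(sc)
  sc
}

#' @export
print.property_scales <- function(x, ...) {
  cat(sprintf("Amino-acid property scales: %d scale(s)%s\n",
              ncol(x$values),
              if (x$standardized) ", z-scored over 20 residues" else
                " (unstandardized)"))
  cat("  ", paste(x$scale_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}
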