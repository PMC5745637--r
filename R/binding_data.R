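#' Peptide binding measurement data
#'
#' Binding records are plain data frames with columns `allele`, `peptide`,
#' `measurement_kind` (`"ic50"` or `"binary"`), `inequality` (`"="`, `"<"`,
#' `">"`), `value` (IC50 in nM, or 0/1 for binary assays), optional
#' `source_ref` (free-text reference identifier), and, once
#' [assign_label()] has run, `label` (`"binder"` / `"non-binder"`).
#' Following convention, an IC50 strictly below 500 nM designates a binder.
#'
#' @name binding_data
NULL

.required_cols <- c("species", "allele", "peptide_length", "sequence",
                    "inequality", "meas")

#' Parse an IEDB-style binding measurement TSV
#'
#' Reads the tab-separated MHC-I tool-data dialect: header columns
#' `species`, `allele`, `peptide_length`, `sequence`, `inequality`, `meas`,
#' plus optional `measurement_kind` (defaults to `"ic50"`) and `reference`.
#' Rows whose measurement cannot be parsed as a number are reported with
#' their line numbers via a warning and returned in the `"bad_rows"`
#' attribute.
#'
#' @param path Path to the TSV file.
#' @return Data frame of binding records (unlabeled).
#' @export
parse_binding_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(tab) <- tolower(names(tab))
  missing <- setdiff(.required_cols, names(tab))
  if (length(missing))
    stop("binding file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  value <- suppressWarnings(as.numeric(tab$meas))
  bad <- which(is.na(value))
  if (length(bad))
    warning("unparseable measurement on line(s) ",
            paste(bad + 1L, collapse = ", "), " of ", basename(path))
  kind <- if ("measurement_kind" %in% names(tab))
    tolower(tab$measurement_kind) else rep("ic50", nrow(tab))
  out <- data.frame(
    allele = as.character(tab$allele),
    peptide = toupper(as.character(tab$sequence)),
    measurement_kind = kind,
    inequality = as.character(tab$inequality),
    value = value,
    source_ref = if ("reference" %in% names(tab))
      as.character(tab$reference) else NA_character_,
    stringsAsFactors = FALSE)
  keep <- !is.na(value)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "bad_rows") <- bad
  res
}

#' Write binding records in the TSV dialect read by [parse_binding_tsv()]
#'
#' @param records Binding-record data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_binding_tsv <- function(records, path) {
  out <- data.frame(
    species = "human",
    allele = records$allele,
    peptide_length = nchar(records$peptide),
    sequence = records$peptide,
    inequality = records$inequality,
    meas = records$value,
    measurement_kind = records$measurement_kind,
    reference = if ("source_ref" %in% names(records))
      records$source_ref else NA_character_,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Label records as binder / non-binder
#'
#' Applies the strict 500 nM rule to IC50 measurements: IC50 < `threshold_nM`
#' is a binder, IC50 >= `threshold_nM` (including exactly the threshold) a
#' non-binder.  Inequality qualifiers are honoured: `">"` with value >=
#' threshold is a non-binder and `"<"` with value <= threshold a binder;
#' qualified values that leave the binding side undetermined (e.g. `">"`
#' with a value below the threshold) are flagged ambiguous, excluded from
#' the result, and reported via a message and the `"ambiguous"` attribute.
#' Binary measurements pass through (`value != 0` is a binder).
#'
#' @param records Binding-record data frame.
#' @param threshold_nM Positive IC50 threshold in nM (default 500).
#' @return The records with a `label` column added, ambiguous rows removed.
#' @export
assign_label <- function(records, threshold_nM = 500) {
  stopifnot(is.data.frame(records), threshold_nM > 0)
  ineq <- records$inequality
  ineq[is.na(ineq) | !nzchar(ineq)] <- "="
  kind <- records$measurement_kind
  v <- records$value
  if (any(kind == "ic50" & v <= 0, na.rm = TRUE))
    stop("non-positive IC50 value(s) present", call. = FALSE)
  label <- rep(NA_character_, nrow(records))
  ambiguous <- logical(nrow(records))
  ic <- kind == "ic50"
  eq <- ic & ineq == "="
  label[eq] <- ifelse(v[eq] < threshold_nM, "binder", "non-binder")
  gt <- ic & ineq == ">"
  label[gt & v >= threshold_nM] <- "non-binder"
  ambiguous[gt & v < threshold_nM] <- TRUE
  lt <- ic & ineq == "<"
  label[lt & v <= threshold_nM] <- "binder"
  ambiguous[lt & v > threshold_nM] <- TRUE
  bin <- kind == "binary"
  label[bin] <- ifelse(v[bin] != 0, "binder", "non-binder")
  if (any(ambiguous))
    message(sum(ambiguous),
            " record(s) with qualifier contradicting the threshold side",
            " excluded as ambiguous")
  out <- records[!ambiguous, , drop = FALSE]
  out$label <- label[!ambiguous]
  rownames(out) <- NULL
  attr(out, "ambiguous") <- which(ambiguous)
  out
}

#' Filter records by peptide length and HLA locus
#'
#' Keeps records whose peptide has exactly `length` residues and whose
#' allele belongs to one of `loci`; order is preserved and the filter is
#' idempotent.  The default matches the nonapeptide HLA-A/-B study
#' condition.
#'
#' @param records Binding-record data frame.
#' @param length Peptide length to keep (default 9).
#' @param loci Character vector of locus letters (default `c("A", "B")`).
#' @return Filtered data frame.
#' @export
filter_records <- function(records, length = 9L, loci = c("A", "B")) {
  stopifnot(length >= 1L)
  keep <- nchar(records$peptide) == length &
    allele_locus(records$allele) %in% loci
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse replicate measurements
#'
#' IEDB exports contain replicate (allele, peptide) IC50 rows; these are
#' collapsed to a single record carrying the geometric-mean IC50 (computed
#' before labeling).  Replicates with differing inequality qualifiers are
#' collapsed to `"="`.  Binary replicates keep their first row.  The number
#' of collapsed groups is reported via a message.
#'
#' @param records Binding-record data frame (unlabeled or labeled; any
#'   `label` column is dropped and must be re-assigned).
#' @return Data frame with one row per (allele, peptide, measurement_kind).
#' @export
collapse_replicates <- function(records) {
  key <- paste(normalize_allele(records$allele), records$peptide,
               records$measurement_kind, sep = "\r")
  if (!anyDuplicated(key)) return(records)
  grp <- split(seq_len(nrow(records)), key)
  dup_groups <- sum(lengths(grp) > 1L)
  rows <- lapply(grp, function(ix) {
    r <- records[ix[1L], , drop = FALSE]
    if (length(ix) > 1L && r$measurement_kind == "ic50") {
      r$value <- exp(mean(log(records$value[ix])))
      if (length(unique(records$inequality[ix])) > 1L) r$inequality <- "="
    }
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(vapply(grp, `[[`, 0L, 1L),
                         seq_len(nrow(records)))), , drop = FALSE]
  out$label <- NULL
  rownames(out) <- NULL
  message(dup_groups, " replicate group(s) collapsed to geometric-mean IC50")
  out
}

#' K-fold cross-validation splits
#'
#' Uniform random partition into `k` equal-sized subsets (sizes differ by
#' at most one), each record used exactly once for validation.
#'
#' @param records Binding-record data frame, or an integer record count.
#' @param k Number of folds (>= 2, default 5).
#' @param seed Integer RNG seed (default 20171228).
#' @return List of `k` elements, each `list(train = idx, validation = idx)`.
#' @export
make_kfold_splits <- function(records, k = 5L, seed = 20171228L) {
  n <- if (is.data.frame(records)) nrow(records) else as.integer(records)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds record count n = %d", k, n),
                  call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n)
  # sizes differing by at most one, contiguous over the permutation:
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  lapply(seq_len(k), function(i) {
    val <- sort(perm[starts[i]:stops[i]])
    list(train = setdiff(seq_len(n), val), validation = val)
  })
}

#' Leave-one-allele-out cross-validation splits
#'
#' One partition per distinct allele: that allele's records form the
#' validation set and all other records the training set — the protocol
#' that tests generalization to unseen alleles.
#'
#' @param records Binding-record data frame.
#' @return Named list (by normalized allele), each element
#'   `list(train = idx, validation = idx)`.
#' @export
make_leave_one_allele_out_splits <- function(records) {
  al <- normalize_allele(records$allele)
  alleles <- sort(unique(al))
  if (length(alleles) < 2L)
    stop("leave-one-allele-out needs at least two distinct alleles",
         call. = FALSE)
  stats::setNames(lapply(alleles, function(a) {
    val <- which(al == a)
    list(train = which(al != a), validation = val)
  }), alleles)
}

#' Group records into benchmark subsets
#'
#' Splits records by the (reference, allele, measurement kind) key, the
#' grouping used by the independent benchmark protocol; subsets are
#' returned in deterministic key order.
#'
#' @param records Binding-record data frame carrying `source_ref`.
#' @return List of `benchmark_subset` objects: `reference`, `allele`,
#'   `measurement_kind`, `records`.
#' @export
group_benchmark_subsets <- function(records) {
  stopifnot("source_ref" %in% names(records))
  al <- normalize_allele(records$allele)
  key <- paste(records$source_ref, al, records$measurement_kind, sep = "\r")
  grp <- split(seq_len(nrow(records)), key)
  grp <- grp[order(names(grp))]
  lapply(grp, function(ix) {
    structure(list(reference = records$source_ref[ix[1L]],
                   allele = al[ix[1L]],
                   measurement_kind = records$measurement_kind[ix[1L]],
                   records = records[ix, , drop = FALSE]),
              class = "benchmark_subset")
  })
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
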