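#' Binary classification metrics and the benchmark protocol
#'
#' Performance is quantified with the F1 score, the harmonic mean of
#' precision (TP / (TP + FP)) and recall (TP / (TP + FN)), computed per
#' benchmark subset — records grouped by reference, allele and
#' measurement type — and summarized per HLA locus.
#'
#' @name evaluation
NULL

#' Confusion counts for binary labels
#'
#' @param truth,predicted Equal-length binary vectors (0/1, logical, or
#'   `"binder"`/`"non-binder"` character labels).
#' @return A `confusion_counts` object with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(truth, predicted) {
  as01 <- function(x) {
    if (is.character(x) || is.factor(x)) as.integer(as.character(x) == "binder")
    else as.integer(as.logical(x))
  }
  t01 <- as01(truth); p01 <- as01(predicted)
  if (length(t01) != length(p01))
    stop(sprintf("length mismatch: %d true vs %d predicted labels",
                 length(t01), length(p01)), call. = FALSE)
  structure(list(TP = sum(t01 == 1L & p01 == 1L),
                 FP = sum(t01 == 0L & p01 == 1L),
                 FN = sum(t01 == 1L & p01 == 0L),
                 TN = sum(t01 == 0L & p01 == 0L)),
            class = "confusion_counts")
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`.  Degenerate
#' denominators yield 0 with `degenerate = TRUE`, keeping the metrics
#' defined on small subsets.
#'
#' @param counts A `confusion_counts` object.
#' @return A `binding_metrics` object: `precision`, `recall`, `f1`,
#'   `degenerate`.
#' @export
f1_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  degenerate <- FALSE
  div <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- div(counts$TP, counts$TP + counts$FP)
  recall <- div(counts$TP, counts$TP + counts$FN)
  f1 <- div(2 * precision * recall, precision + recall)
  structure(list(precision = precision, recall = recall, f1 = f1,
                 degenerate = degenerate),
            class = "binding_metrics")
}

#' Binarize predicted probabilities
#'
#' A prediction is a binder iff its probability is at least `threshold`
#' (boundary inclusive).
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param threshold Operating point (default 0.5).
#' @return Integer 0/1 vector.
#' @export
binarize_predictions <- function(probabilities, threshold = 0.5) {
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  as.integer(probabilities >= threshold)
}

#' Evaluate a classifier over benchmark subsets
#'
#' For each subset, truth labels are derived from the measurements (IC50 <
#' `threshold_nM` means binder; binary values pass through), the
#' classifier's probabilities are binarized at `operating_point`, and
#' precision/recall/F1 are computed.  Subsets with alleles not covered by
#' the classifier's pseudo-sequence registry are skipped and reported.
#' F1 is summarized (mean/median/sd) per HLA locus.
#'
#' @param fit An `ila_cnn` fit (or any object with a working
#'   [predict()] accepting a `peptide`/`allele` data frame).
#' @param subsets List of benchmark subsets from
#'   [group_benchmark_subsets()].
#' @param threshold_nM IC50 binder threshold (default 500 nM).
#' @param operating_point Probability threshold for binarization
#'   (default 0.5).
#' @return A `benchmark_report`: `per_subset` data frame, `summary` data
#'   frame per locus, `skipped` character vector.
#' @export
evaluate_benchmark <- function(fit, subsets, threshold_nM = 500,
                               operating_point = 0.5) {
  rows <- list(); skipped <- character(0)
  for (s in subsets) {
    stopifnot(inherits(s, "benchmark_subset"))
    labeled <- suppressMessages(assign_label(s$records, threshold_nM))
    if (!nrow(labeled)) next
    p <- tryCatch(predict(fit, labeled[, c("peptide", "allele")]),
                  error = function(e) e)
    if (inherits(p, "error")) {
      skipped <- c(skipped, sprintf("%s/%s/%s (%s)", s$reference, s$allele,
                                    s$measurement_kind,
                                    conditionMessage(p)))
      next
    }
    cc <- confusion_counts(labeled$label,
                           binarize_predictions(p, operating_point))
    m <- f1_metrics(cc)
    rows[[length(rows) + 1L]] <- data.frame(
      reference = s$reference, allele = s$allele,
      measurement_kind = s$measurement_kind, n = nrow(labeled),
      TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
      precision = m$precision, recall = m$recall, f1 = m$f1,
      degenerate = m$degenerate, stringsAsFactors = FALSE)
  }
  per_subset <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reference = character(0), allele = character(0),
               measurement_kind = character(0), n = integer(0),
               TP = integer(0), FP = integer(0), FN = integer(0),
               TN = integer(0), precision = numeric(0), recall = numeric(0),
               f1 = numeric(0), degenerate = logical(0))
  locus <- allele_locus(per_subset$allele)
  summ <- do.call(rbind, lapply(sort(unique(locus)), function(lc) {
    f1 <- per_subset$f1[locus == lc]
    data.frame(locus = lc, n_subsets = length(f1), mean = mean(f1),
               median = stats::median(f1), sd = stats::sd(f1),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_subset = per_subset,
                 summary = summ %||% data.frame(),
                 skipped = skipped),
            class = "benchmark_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a benchmark report as TSV
#'
#' One row per subset (reference, allele, kind, n, TP, FP, FN, TN,
#' precision, recall, f1) followed by a commented per-locus summary block
#' (mean/median/sd of F1).
#'
#' @param report A `benchmark_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_benchmark_report <- function(report, path) {
  stopifnot(inherits(report, "benchmark_report"))
  utils::write.table(report$per_subset, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  con <- file(path, open = "at")
  on.exit(close(con))
  writeLines("# F1 summary by locus (mean / median / sd)", con)
  if (!is.null(report$summary) && nrow(report$summary))
    for (i in seq_len(nrow(report$summary)))
      writeLines(sprintf("# HLA-%s\t%d subsets\t%.3f\t%.3f\t%.3f",
                         report$summary$locus[i],
                         report$summary$n_subsets[i],
                         report$summary$mean[i], report$summary$median[i],
                         report$summary$sd[i]), con)
  invisible(path)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d\n", x$TP, x$FP, x$FN, x$TN))
  invisible(x)
}

#' @export
print.binding_metrics <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f%s\n", x$precision,
              x$recall, x$f1,
              if (x$degenerate) "  (degenerate denominators -> 0)" else ""))
  invisible(x)
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Benchmark report: %d subset(s), %d skipped\n",
              nrow(x$per_subset), length(x$skipped)))
  if (!is.null(x$summary) && nrow(x$summary)) print(x$summary,
                                                    row.names = FALSE)
  invisible(x)
}
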