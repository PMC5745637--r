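test_that("confusion counts match hand-worked cases", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(cc[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  all_right <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(all_right$FP, 0L)
  expect_equal(all_right$FN, 0L)
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "length mismatch")
})

test_that("confusion counts over 1000 random pairs match a per-element tally", {
  set.seed(61)
  truth <- rbinom(1000, 1, 0.45)
  pred <- rbinom(1000, 1, 0.55)
  cc <- confusion_counts(truth, pred)
  tally <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  for (i in seq_len(1000)) {
    key <- if (truth[i] == 1 && pred[i] == 1) "TP"
      else if (truth[i] == 0 && pred[i] == 1) "FP"
      else if (truth[i] == 1 && pred[i] == 0) "FN" else "TN"
    tally[key] <- tally[key] + 1L
  }
  expect_equal(unlist(cc[c("TP", "FP", "FN", "TN")]), tally)
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 1000L)
})

test_that("F1 follows the harmonic-mean formula with degenerate cases at 0", {
  perfect <- f1_metrics(structure(list(TP = 5L, FP = 0L, FN = 0L, TN = 0L),
                                  class = "confusion_counts"))
  expect_equal(perfect$f1, 1)
  worst <- f1_metrics(structure(list(TP = 0L, FP = 3L, FN = 2L, TN = 5L),
                                class = "confusion_counts"))
  expect_equal(worst$f1, 0)
  m <- f1_metrics(structure(list(TP = 3L, FP = 1L, FN = 1L, TN = 10L),
                            class = "confusion_counts"))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  none <- f1_metrics(structure(list(TP = 0L, FP = 0L, FN = 0L, TN = 4L),
                               class = "confusion_counts"))
  expect_equal(none$f1, 0)
  expect_true(none$degenerate)
})

test_that("F1 on random counts equals the closed form and stays in [0,1]", {
  set.seed(62)
  for (i in 1:50) {
    cc <- structure(as.list(setNames(rpois(4, 8), c("TP", "FP", "FN", "TN"))),
                    class = "confusion_counts")
    m <- f1_metrics(cc)
    expect_gte(m$f1, 0); expect_lte(m$f1, 1)
    if (!m$degenerate) {
      expect_equal(m$f1, 2 * m$precision * m$recall /
                     (m$precision + m$recall))
      # swapping FP and FN exchanges precision and recall but leaves F1
      # fixed (F1 = 2TP / (2TP + FP + FN))
      sw <- f1_metrics(structure(list(TP = cc$TP, FP = cc$FN, FN = cc$FP,
                                      TN = cc$TN),
                                 class = "confusion_counts"))
      expect_equal(sw$precision, m$recall)
      expect_equal(sw$recall, m$precision)
      expect_equal(sw$f1, m$f1)
    }
  }
})

test_that("binarization is boundary-inclusive and validates its input", {
  expect_equal(binarize_predictions(c(0.4, 0.5, 0.6), 0.5), c(0L, 1L, 1L))
  expect_equal(binarize_predictions(c(0.1, 0.9), 0), c(1L, 1L))
  set.seed(63)
  p <- runif(200)
  th <- runif(1)
  expect_equal(binarize_predictions(p, th), as.integer(p >= th))
  expect_error(binarize_predictions(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("benchmark evaluation computes per-subset metrics and locus summaries", {
  # deterministic mock predictor: binder iff peptide starts with K
  mock <- structure(list(), class = "mock_predictor")
  registerS3method("predict", "mock_predictor",
                   function(object, newdata, ...)
                     ifelse(substr(newdata$peptide, 1, 1) == "K", 0.9, 0.1),
                   envir = asNamespace("stats"))
  set.seed(64)
  recs <- data.frame(
    allele = rep(c("HLA-A*02:01", "HLA-A*03:01", "HLA-B*07:02"), each = 8),
    peptide = paste0(sample(c("K", "A"), 24, TRUE),
                     replicate(24, random_peptide(8))),
    measurement_kind = rep(c("ic50", "binary"), 12),
    inequality = "=", value = NA_real_,
    source_ref = rep(c("r1", "r2"), each = 4, length.out = 24))
  recs$value <- ifelse(recs$measurement_kind == "ic50",
                       ifelse(runif(24) < 0.5, 50, 5000), rbinom(24, 1, 0.5))
  subs <- group_benchmark_subsets(recs)
  rep_ <- evaluate_benchmark(mock, subs)
  expect_equal(nrow(rep_$per_subset), length(subs))
  expect_equal(sum(rep_$per_subset$n), 24L)
  # summaries recompute from the per-subset list
  locus <- allele_locus(rep_$per_subset$allele)
  for (i in seq_len(nrow(rep_$summary))) {
    lc <- rep_$summary$locus[i]
    f1s <- rep_$per_subset$f1[locus == lc]
    expect_equal(rep_$summary$mean[i], mean(f1s))
    expect_equal(rep_$summary$median[i], median(f1s))
    expect_equal(rep_$summary$sd[i], sd(f1s))
  }
  # report writer emits one row per subset plus a summary block
  f <- tempfile(fileext = ".tsv")
  write_benchmark_report(rep_, f)
  lines <- readLines(f)
  expect_equal(sum(!startsWith(lines, "#")), nrow(rep_$per_subset) + 1L)
  expect_true(any(grepl("^# HLA-A", lines)))
})

test_that("a perfect predictor scores F1 = 1 and summary means are exact", {
  truth_based <- structure(list(), class = "oracle_predictor")
  registerS3method("predict", "oracle_predictor",
                   function(object, newdata, ...)
                     ifelse(substr(newdata$peptide, 1, 1) == "K", 1, 0),
                   envir = asNamespace("stats"))
  recs <- data.frame(
    allele = "HLA-A*02:01",
    peptide = c("KLLLLLLLL", "ALLLLLLLL", "KVVVVVVVV", "AVVVVVVVV"),
    measurement_kind = "ic50", inequality = "=",
    value = c(10, 5000, 20, 9000), source_ref = "r1")
  rep_ <- evaluate_benchmark(truth_based, group_benchmark_subsets(recs))
  expect_equal(rep_$per_subset$f1, 1)
  expect_equal(rep_$summary$mean, 1)
})
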