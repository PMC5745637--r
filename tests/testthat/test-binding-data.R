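test_that("the toy IEDB-dialect fixture parses into five records", {
  recs <- parse_binding_tsv(extdata("toy_binding.tsv"))
  expect_equal(nrow(recs), 5L)
  expect_equal(recs$value[1], 25)
  expect_equal(recs$inequality, c("=", "=", "<", ">", "="))
  expect_true(all(recs$measurement_kind == "ic50"))
})

test_that("missing required columns are named in the error", {
  tab <- utils::read.delim(extdata("toy_binding.tsv"))
  tab$inequality <- NULL
  f <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(parse_binding_tsv(f), "inequality")
})

test_that("the 500 nM rule labels the boundary and qualifiers correctly", {
  recs <- suppressMessages(assign_label(parse_binding_tsv(
    extdata("toy_binding.tsv"))))
  lab <- setNames(recs$label, recs$peptide)
  expect_identical(unname(lab["KVFGPIHEL"]), "binder")      # 25 nM
  expect_identical(unname(lab["GILGFVFTL"]), "non-binder")  # exactly 500 nM
  expect_identical(unname(lab["LPQWLSANR"]), "binder")      # < 450
  expect_identical(unname(lab["APRTLVLLL"]), "non-binder")  # > 20000
})

test_that("ambiguous qualified measurements are excluded and reported", {
  recs <- data.frame(allele = "HLA-A*02:01", peptide = "AAAAAAAAA",
                     measurement_kind = "ic50",
                     inequality = c(">", "<", "="),
                     value = c(100, 10000, 50), source_ref = NA)
  expect_message(out <- assign_label(recs), "ambiguous")
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "ambiguous"), c(1L, 2L))
})

test_that("labeling 1000 random records agrees with the comparison oracle", {
  set.seed(21)
  n <- 1000
  recs <- data.frame(allele = "HLA-A*02:01",
                     peptide = replicate(n, random_peptide(9)),
                     measurement_kind = sample(c("ic50", "binary"), n, TRUE),
                     inequality = "=",
                     value = NA_real_, source_ref = NA)
  recs$value <- ifelse(recs$measurement_kind == "ic50",
                       10^runif(n, -1, 4.7), rbinom(n, 1, 0.5))
  out <- assign_label(recs)
  oracle <- ifelse(recs$measurement_kind == "ic50",
                   ifelse(recs$value < 500, "binder", "non-binder"),
                   ifelse(recs$value != 0, "binder", "non-binder"))
  expect_identical(out$label, oracle)
})

test_that("length/locus filtering keeps nonapeptide HLA-A/B records and is idempotent", {
  recs <- data.frame(
    allele = c("HLA-A*02:01", "HLA-B*07:02", "HLA-C*04:01", "HLA-A*02:01"),
    peptide = c("KVFGPIHEL", "APRTLVLLL", "QYDDAVYKL", "GILGFVFT"),
    measurement_kind = "ic50", inequality = "=", value = 10,
    source_ref = NA)
  out <- filter_records(recs, 9, c("A", "B"))
  expect_equal(out$allele, c("HLA-A*02:01", "HLA-B*07:02"))
  expect_identical(filter_records(out, 9, c("A", "B")), out)
  expect_equal(nrow(filter_records(recs, 8, "A")), 1L)
})

test_that("replicate rows collapse to the geometric-mean IC50", {
  recs <- data.frame(
    allele = c("HLA-A*02:01", "HLA-A0201", "HLA-A*02:01", "HLA-B*07:02"),
    peptide = c("KVFGPIHEL", "KVFGPIHEL", "KVFGPIHEL", "APRTLVLLL"),
    measurement_kind = "ic50", inequality = c("=", "<", "=", "="),
    value = c(10, 1000, 100, 7), source_ref = NA)
  expect_message(out <- collapse_replicates(recs), "1 replicate group")
  expect_equal(nrow(out), 2L)
  expect_equal(out$value[1], exp(mean(log(c(10, 1000, 100)))))
  expect_equal(out$inequality[1], "=")
  expect_equal(out$value[2], 7)
})

test_that("k-fold splits partition exactly with near-equal sizes", {
  sp <- make_kfold_splits(10, k = 5, seed = 1)
  expect_equal(length(sp), 5L)
  expect_true(all(vapply(sp, function(s) length(s$validation), 0L) == 2L))
  expect_identical(make_kfold_splits(10, 5, seed = 7),
                   make_kfold_splits(10, 5, seed = 7))
  expect_error(make_kfold_splits(4, k = 5), "exceeds")

  # full corpus scale: n = 118174, k = 5
  sp <- make_kfold_splits(118174, k = 5, seed = 20171228)
  sizes <- vapply(sp, function(s) length(s$validation), 0L)
  expect_true(all(sizes %in% c(23634L, 23635L)))
  vals <- unlist(lapply(sp, `[[`, "validation"))
  expect_equal(sort(vals), seq_len(118174))      # union = all, disjoint
  for (s in sp) {
    expect_equal(length(intersect(s$train, s$validation)), 0L)
    expect_equal(sort(c(s$train, s$validation)), seq_len(118174))
  }
})

test_that("leave-one-allele-out builds one round per allele, each record once", {
  recs <- small_records(60)
  sp <- make_leave_one_allele_out_splits(recs)
  expect_equal(length(sp), length(unique(recs$allele)))
  vals <- unlist(lapply(sp, `[[`, "validation"), use.names = FALSE)
  expect_equal(sort(vals), seq_len(nrow(recs)))
  for (a in names(sp))
    expect_true(all(normalize_allele(recs$allele[sp[[a]]$validation]) == a))
  one <- recs[recs$allele == recs$allele[1], ]
  expect_error(make_leave_one_allele_out_splits(one), "two distinct")
})

test_that("benchmark grouping is keyed by reference x allele x kind", {
  recs <- data.frame(
    allele = rep(c("HLA-A*02:01", "HLA-B*07:02"), each = 4),
    peptide = replicate(8, random_peptide(9)),
    measurement_kind = "ic50", inequality = "=", value = 50,
    source_ref = rep(c("ref1", "ref2"), 4))
  subs <- group_benchmark_subsets(recs)
  expect_equal(length(subs), 4L)
  expect_equal(sum(vapply(subs, function(s) nrow(s$records), 0L)), 8L)
  one <- group_benchmark_subsets(recs[recs$source_ref == "ref1" &
                                        recs$allele == "HLA-A*02:01", ])
  expect_equal(length(one), 1L)
})

test_that("records round-trip through the TSV writer", {
  recs <- small_records(30)
  f <- tempfile(fileext = ".tsv")
  write_binding_tsv(recs, f)
  back <- suppressMessages(assign_label(parse_binding_tsv(f)))
  expect_equal(back$peptide, recs$peptide)
  expect_equal(back$allele, recs$allele)
  expect_equal(back$value, recs$value, tolerance = 1e-12)
  expect_identical(back$label, recs$label)
})
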