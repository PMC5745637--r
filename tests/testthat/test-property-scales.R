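test_that("the shipped property table loads with 11 scales in file order", {
  sc <- load_property_matrix(extdata("property_scales.csv"))
  expect_s3_class(sc, "property_scales")
  expect_equal(ncol(sc$values), 11L)
  expect_false(sc$standardized)
  expect_identical(rownames(sc$values), amino_acids())
  expect_identical(sc$scale_names[1L], "hydropathy_kyte_doolittle")
})

test_that("loader validates amino-acid rows and scale names", {
  tab <- utils::read.csv(extdata("property_scales.csv"))
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(tab[tab$amino_acid != "W", ], bad, row.names = FALSE)
  expect_error(load_property_matrix(bad), "W")
  dup <- tab
  names(dup)[3] <- names(dup)[2]
  utils::write.csv(dup, bad, row.names = FALSE)
  expect_error(load_property_matrix(bad), "duplicate")
  one <- data.frame(amino_acid = amino_acids(), zero = 0)
  utils::write.csv(one, bad, row.names = FALSE)
  sc1 <- load_property_matrix(bad)
  expect_equal(ncol(sc1$values), 1L)
  expect_true(all(sc1$values == 0))
})

test_that("standardization z-scores each column and is idempotent", {
  sc <- load_property_matrix(extdata("property_scales.csv"))
  st <- standardize_scales(sc)
  expect_true(st$standardized)
  expect_lt(max(abs(colMeans(st$values))), 1e-9)
  expect_lt(max(abs(apply(st$values, 2, sd) - 1)), 1e-9)
  # direct-arithmetic oracle on one column
  v <- sc$values[, 4]
  expect_equal(st$values[, 4], (v - sum(v) / 20) /
                 sqrt(sum((v - sum(v) / 20)^2) / 19),
               tolerance = 1e-12)
  again <- standardize_scales(st)
  expect_lt(max(abs(again$values - st$values)), 1e-9)
})

test_that("zero-variance scales are rejected by name", {
  m <- cbind(a = rnorm(20), flat = rep(2, 20))
  expect_error(standardize_scales(scales_from_matrix(m)), "flat")
})

test_that("pruning the default 11-scale table retains 9 with no violating pair", {
  sc <- load_property_matrix(extdata("property_scales.csv"))
  pruned <- prune_correlated_scales(sc, 0.8)
  expect_equal(ncol(pruned$values), 9L)
  r2 <- cor(pruned$values)^2
  diag(r2) <- 0
  expect_true(all(r2 <= 0.8))
  # survivor order preserved
  expect_identical(pruned$scale_names,
                   intersect(sc$scale_names, pruned$scale_names))
})

test_that("pruning keeps uncorrelated scales and drops exact duplicates", {
  set.seed(5)
  m2 <- matrix(rnorm(40), 20, 2)
  while (cor(m2)[1, 2]^2 > 0.5) m2 <- matrix(rnorm(40), 20, 2)
  expect_equal(ncol(prune_correlated_scales(scales_from_matrix(m2),
                                            0.8)$values), 2L)

  m3 <- cbind(a = rnorm(20), b = 0, c = rnorm(20))
  m3[, "b"] <- m3[, "a"]
  pruned <- prune_correlated_scales(scales_from_matrix(m3), 0.8)
  expect_equal(ncol(pruned$values), 2L)
  # brute-force over all subsets: the survivor set must be a maximal
  # violation-free subset
  ok_subset <- function(cols) {
    if (length(cols) < 2) return(TRUE)
    r2 <- cor(m3[, cols, drop = FALSE])^2
    diag(r2) <- 0
    all(r2 <= 0.8)
  }
  subsets <- unlist(lapply(seq_len(3), function(k)
    combn(colnames(m3), k, simplify = FALSE)), recursive = FALSE)
  valid <- Filter(ok_subset, subsets)
  max_size <- max(lengths(valid))
  expect_true(list(pruned$scale_names) %in% lapply(valid, identity) ||
                any(vapply(valid, identical, TRUE, y = pruned$scale_names)))
  expect_equal(length(pruned$scale_names), max_size)
})

test_that("pruning commutes with standardization on scale-name survivors", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(rnorm(20 * 8), 20, 8)
    m[, 8] <- m[, 1] + rnorm(20, 0, 0.2)
    m[, 7] <- m[, 2] + rnorm(20, 0, 0.2)
    sc <- scales_from_matrix(m)
    a <- prune_correlated_scales(standardize_scales(sc), 0.8)$scale_names
    b <- standardize_scales(prune_correlated_scales(sc, 0.8))$scale_names
    expect_identical(a, b)
  }
})

test_that("greedy pruning of planted correlated pairs survives brute-force re-check", {
  for (seed in 1:8) {
    set.seed(seed * 100)
    m <- matrix(rnorm(20 * 11), 20, 11)
    m[, 10] <- m[, 1] + rnorm(20, 0, 0.15)
    m[, 11] <- m[, 2] + rnorm(20, 0, 0.15)
    sc <- scales_from_matrix(m)
    r2 <- cor(sc$values)^2; diag(r2) <- 0
    n_viol_pairs <- sum(r2 > 0.8) / 2
    if (n_viol_pairs != 2) next  # rare spurious correlations; skip draw
    pruned <- prune_correlated_scales(sc, 0.8)
    r2p <- cor(pruned$values)^2; diag(r2p) <- 0
    expect_true(all(r2p <= 0.8))
    expect_equal(ncol(pruned$values), 11L - 2L)
  }
})

test_that("fully correlated input collapses to one scale with a warning", {
  base <- rnorm(20)
  m <- cbind(a = base, b = 2 * base + 1, c = -base)
  expect_warning(pruned <- prune_correlated_scales(scales_from_matrix(m), 0.8),
                 "single scale")
  expect_equal(ncol(pruned$values), 1L)
})

test_that("default_property_scales returns the pruned standardized 9-scale set", {
  sc <- default_property_scales()
  expect_equal(ncol(sc$values), 9L)
  expect_true(sc$standardized)
})
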