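# Shared fixtures: all built in code or loaded from the shipped plain-text
# extdata files.

extdata <- function(...) {
  system.file("extdata", ..., package = "ilamhc", mustWork = TRUE)
}

# property_scales object from a bare 20 x S matrix (via the CSV loader, so
# tests exercise the same path users do)
scales_from_matrix <- function(m, names = NULL) {
  if (is.null(colnames(m)))
    colnames(m) <- names %||% paste0("s", seq_len(ncol(m)))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(amino_acid = amino_acids(), m,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  load_property_matrix(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random standardized scale set
random_scales <- function(S, seed = 1) {
  set.seed(seed)
  standardize_scales(scales_from_matrix(matrix(rnorm(20 * S), 20, S)))
}

pseudo_obj <- function(residues, allele = "HLA-X*00:00") {
  structure(list(allele = allele, residues = residues),
            class = "pseudosequence")
}

random_pseudo <- function(n = 34, seed = 1, allele = "HLA-X*00:00") {
  set.seed(seed)
  pseudo_obj(paste(sample(amino_acids(), n, replace = TRUE), collapse = ""),
             allele)
}

random_peptide <- function(n = 9) {
  paste(sample(amino_acids(), n, replace = TRUE), collapse = "")
}

random_ila <- function(shape, seed = 1) {
  set.seed(seed)
  structure(list(data = array(rnorm(prod(shape)), dim = shape),
                 peptide = "RANDOMILA", allele = "HLA-X*00:00"),
            class = "ila_array")
}

# a small, fast architecture for tests that need training
tiny_spec <- function(shape, dropout = 0) {
  model_spec(input_shape = shape, block_filters = c(4L, 8L),
             convs_per_block = 1L, dense_sizes = c(16L),
             dropout_rate = dropout)
}

# small synthetic world shared across tests (built once per session)
.test_env <- new.env(parent = emptyenv())
small_world <- function() {
  if (is.null(.test_env$world))
    .test_env$world <- generate_world(
      synthetic_config(n_alleles = 3, contact_count = 12), seed = 11)
  .test_env$world
}
small_records <- function(n = 240) {
  key <- paste0("rec", n)
  if (is.null(.test_env[[key]]))
    .test_env[[key]] <- sample_records(small_world(), n, seed = 12)
  .test_env[[key]]
}
small_scales <- function() {
  if (is.null(.test_env$scales)) .test_env$scales <- default_property_scales()
  .test_env$scales
}
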