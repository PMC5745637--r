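#' Fit a pan-specific peptide-MHC binding classifier
#'
#' The main modelling entry point.  Labeled binding records are encoded as
#' image-like arrays (peptide and HLA contact-residue property channels),
#' split into training and validation subsets, and used to train the
#' convolutional classifier with Adam and early stopping.  The returned
#' object supports `print`, `summary`, `predict`, `plot` (loss traces),
#' `coef`, `fitted` and `residuals`.
#'
#' @param records Binding-record data frame with a `label` column (run
#'   [assign_label()] first).
#' @param registry A `pseudoseq_registry` covering the records' alleles.
#' @param scales A standardized `property_scales`
#'   (default [default_property_scales()]).
#' @param spec An `ila_model_spec`; by default the standard architecture
#'   sized from the encoded data.
#' @param config A `train_config`.
#' @param validation_split Fraction of records held out for validation
#'   (default 0.2), sampled uniformly under `config$seed`.
#' @param verbose Print per-epoch progress?
#' @return An object of class `ila_cnn`.
#' @export
#' @examples
#' \donttest{
#' world <- generate_world(synthetic_config(n_alleles = 2), seed = 1)
#' recs <- sample_records(world, 300, seed = 2)
#' fit <- ila_cnn(recs, world$registry,
#'                spec = model_spec(block_filters = c(8, 16, 32),
#'                                  dense_sizes = c(32, 16)),
#'                config = train_config(max_epochs = 3, patience = 2))
#' print(fit)
#' }
ila_cnn <- function(records, registry, scales = default_property_scales(),
                    spec = NULL, config = train_config(),
                    validation_split = 0.2, verbose = FALSE) {
  cl <- match.call()
  if (!"label" %in% names(records))
    stop("records carry no 'label' column; run assign_label() first",
         call. = FALSE)
  stopifnot(validation_split > 0, validation_split < 1)
  enc <- encode_batch(records, registry, scales)
  if (nrow(enc$skipped))
    warning(nrow(enc$skipped), " record(s) skipped (allele not covered): ",
            paste(unique(enc$skipped$allele), collapse = ", "))
  if (!length(enc$ilas)) stop("no encodable records", call. = FALSE)
  X <- ila_stack(enc$ilas)
  y <- as.integer(enc$labels == "binder")
  if (is.null(spec)) spec <- model_spec(input_shape = attr(X, "ila_dim"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- ncol(X)
  val_ix <- sort(sample.int(n, size = max(1L, round(validation_split * n))))
  tr_ix <- setdiff(seq_len(n), val_ix)
  net <- build_model(spec, seed = config$seed)
  res <- train_network(net, X[, tr_ix, drop = FALSE], y[tr_ix],
                       X[, val_ix, drop = FALSE], y[val_ix],
                       config, verbose = verbose)
  fitted_all <- net_predict_matrix(res$net, X)
  structure(list(net = res$net, spec = spec, config = config,
                 registry = registry, scales = scales,
                 history = data.frame(epoch = seq_along(res$train_loss),
                                      train_loss = res$train_loss,
                                      val_loss = res$val_loss,
                                      val_accuracy = res$val_accuracy),
                 best_epoch = res$best_epoch,
                 stopped_epoch = res$stopped_epoch,
                 val_accuracy = res$val_accuracy_best,
                 diverged = res$diverged,
                 n_train = length(tr_ix), n_val = length(val_ix),
                 y = y, fitted_values = fitted_all,
                 skipped = enc$skipped, call = cl),
            class = "ila_cnn")
}

#' Predict method for fitted binding classifiers
#'
#' @param object An `ila_cnn` fit.
#' @param newdata A data frame with `peptide` and `allele` columns, a list
#'   of `ila_array`s, or an [ila_stack()] matrix.  Missing: returns fitted
#'   probabilities on the training data.
#' @param type `"prob"` for probabilities (default) or `"label"` for
#'   `"binder"`/`"non-binder"` at `threshold`.
#' @param threshold Operating point on the probability for `type = "label"`.
#' @param ... Unused.
#' @return Numeric probabilities or character labels, in input order.
#' @export
predict.ila_cnn <- function(object, newdata, type = c("prob", "label"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  if (missing(newdata)) {
    p <- object$fitted_values
  } else if (is.data.frame(newdata)) {
    enc <- encode_batch(newdata, object$registry, object$scales)
    if (nrow(enc$skipped))
      stop("allele(s) not covered: ",
           paste(unique(enc$skipped$allele), collapse = ", "), call. = FALSE)
    p <- net_predict_matrix(object$net, ila_stack(enc$ilas))
  } else {
    p <- net_predict_matrix(object$net, as_ila_matrix(newdata))
  }
  if (type == "prob") p
  else ifelse(p >= threshold, "binder", "non-binder")
}

#' @export
print.ila_cnn <- function(x, ...) {
  cat("Pan-specific peptide-MHC binding classifier (convolutional)\n")
  cat(sprintf("  input %s; %s filters; %s parameters\n",
              paste(x$spec$input_shape, collapse = "x"),
              paste(x$spec$block_filters, collapse = "/"),
              format(x$net$param_count, big.mark = ",")))
  cat(sprintf("  trained on %d records (%d validation); stopped at epoch %d, best epoch %d\n",
              x$n_train + x$n_val, x$n_val, x$stopped_epoch, x$best_epoch))
  cat(sprintf("  best validation loss %.4f, validation accuracy %.4f\n",
              min(x$history$val_loss), x$val_accuracy))
  invisible(x)
}

#' @export
summary.ila_cnn <- function(object, ...) {
  structure(list(fit = object), class = "summary.ila_cnn")
}

#' @export
print.summary.ila_cnn <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nCall:\n  ")
  print(f$call)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(f$history, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
coef.ila_cnn <- function(object, ...) {
  layers <- object$net$layers
  params <- list()
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (l$type == "conv")
      params[[sprintf("conv_%d", li)]] <- list(K = l$K, b = l$b)
    else if (l$type == "dense")
      params[[sprintf("dense_%d", li)]] <- list(W = l$Wt, b = l$b)
  }
  params
}

#' @export
fitted.ila_cnn <- function(object, ...) object$fitted_values

#' @export
residuals.ila_cnn <- function(object, ...)
  object$y - object$fitted_values

#' Plot training and validation loss traces
#'
#' @param x An `ila_cnn` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ila_cnn <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"),
                   lty = 1, col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a fitted classifier
#'
#' The checkpoint is R's native serialization plus a JSON sidecar
#' (`<path>.json`) describing the architecture and training configuration.
#'
#' @param object An `ila_cnn` or `ila_net`.
#' @param path Checkpoint path (conventionally `.rds`).
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   restored object.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, c("ila_cnn", "ila_net")))
  saveRDS(object, path)
  spec <- if (inherits(object, "ila_cnn")) object$spec else object$spec
  sidecar <- list(class = class(object)[1L],
                  spec = unclass(spec),
                  config = if (inherits(object, "ila_cnn"))
                    unclass(object$config) else NULL)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop("model checkpoint not found: ", path, call. = FALSE)
  readRDS(path)
}
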