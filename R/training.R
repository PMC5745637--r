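#' Training configuration
#'
#' Optimizer and schedule settings for network training: adaptive-moment
#' (Adam) gradient descent at `learning_rate` for up to `max_epochs`
#' epochs, stopping early once the validation loss has not improved for
#' `patience` consecutive epochs.  The defaults are the published
#' protocol: learning rate 0.001, 200 epochs, patience 15.
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param max_epochs Maximum training epochs (default 200).
#' @param patience Consecutive non-improving validation epochs tolerated
#'   before stopping (default 15).
#' @param batch_size Mini-batch size (default 128).
#' @param seed Integer RNG seed controlling initialization order, epoch
#'   shuffling and dropout (default 20171228).
#' @param min_delta Minimum decrease in validation loss that counts as an
#'   improvement (default 0: any strict decrease counts).
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 200L,
                         patience = 15L, batch_size = 128L,
                         seed = 20171228L, min_delta = 0) {
  stopifnot(learning_rate > 0, max_epochs >= 1L, patience >= 1L,
            batch_size >= 1L, min_delta >= 0)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), min_delta = min_delta),
            class = "train_config")
}

#' Initialize an early-stopping monitor
#'
#' @return An `early_stop_state`: `best_loss = Inf`, `best_epoch = 0`,
#'   `stale_epochs = 0`, `epoch = 0`.
#' @export
early_stop_state <- function() {
  structure(list(best_loss = Inf, best_epoch = 0L, stale_epochs = 0L,
                 epoch = 0L),
            class = "early_stop_state")
}

#' Update the early-stopping monitor with one validation loss
#'
#' An epoch improves iff `val_loss < best_loss - min_delta` (strict);
#' improvement resets the stale counter and records the new best,
#' otherwise the stale counter increments.  Training halts when
#' `stale_epochs` reaches `patience`.  A non-finite loss halts immediately
#' with `error = TRUE`.
#'
#' @param state An `early_stop_state`.
#' @param val_loss Validation loss of the epoch just finished.
#' @param patience Consecutive non-improving epochs tolerated.
#' @param min_delta Minimum improvement (default 0).
#' @return List with updated `state`, `halt` flag, and `error` flag.
#' @export
#' @examples
#' st <- early_stop_state()
#' r <- early_stop_update(st, 0.5, patience = 15)
#' r$state$best_loss
early_stop_update <- function(state, val_loss, patience, min_delta = 0) {
  stopifnot(inherits(state, "early_stop_state"))
  state$epoch <- state$epoch + 1L
  if (!is.finite(val_loss))
    return(list(state = state, halt = TRUE, error = TRUE))
  if (val_loss < state$best_loss - min_delta) {
    state$best_loss <- val_loss
    state$best_epoch <- state$epoch
    state$stale_epochs <- 0L
  } else {
    state$stale_epochs <- state$stale_epochs + 1L
  }
  list(state = state, halt = state$stale_epochs >= patience, error = FALSE)
}

#' Train a network on labeled image-like arrays
#'
#' Mini-batch Adam with per-epoch seeded reshuffling, binary cross-entropy
#' loss, per-epoch training/validation loss traces, early stopping per
#' [early_stop_update()], and restoration of the best-epoch weights before
#' returning.  With an identical configuration and seed the run is
#' reproducible.
#'
#' @param net An `ila_net` from [build_model()].
#' @param x_train,x_val Design matrices from [ila_stack()] (one flattened
#'   ILA per column); must be non-empty and disjoint.
#' @param y_train,y_val Numeric 0/1 labels (1 = binder).
#' @param config A `train_config`.
#' @param verbose Print one log line per epoch?
#' @return An `ila_train_result`: `net` (best-epoch weights),
#'   `train_loss`/`val_loss`/`val_accuracy` traces, `best_epoch`,
#'   `stopped_epoch`, `val_accuracy_best`, `diverged`.
#' @export
train_network <- function(net, x_train, y_train, x_val, y_val,
                          config = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "ila_net"), inherits(config, "train_config"))
  n <- ncol(x_train)
  if (n < 1L || ncol(x_val) < 1L)
    stop("training and validation sets must be non-empty", call. = FALSE)
  stopifnot(length(y_train) == n, length(y_val) == ncol(x_val))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  adam <- adam_init(net); t <- 0L
  state <- early_stop_state()
  tr_trace <- val_trace <- acc_trace <- numeric(0)
  best_layers <- net$layers
  diverged <- FALSE
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      ix <- perm[start:min(start + config$batch_size - 1L, n)]
      Xb <- x_train[, ix, drop = FALSE]
      yb <- y_train[ix]
      fw <- net_forward(net, Xb, training = TRUE)
      p <- as.vector(fw$out)
      epoch_loss <- epoch_loss + bce_loss(p, yb) * length(ix)
      G <- matrix((p - yb) / length(ix), nrow = 1L)
      grads <- net_backward(net, fw$caches, G)
      t <- t + 1L
      st <- adam_step(net, grads, adam, config$learning_rate, t)
      net <- st$net; adam <- st$state
    }
    tr_trace[epoch] <- epoch_loss / n
    pv <- net_predict_matrix(net, x_val)
    val_trace[epoch] <- bce_loss(pv, y_val)
    acc_trace[epoch] <- mean((pv >= 0.5) == (y_val == 1))
    if (verbose)
      message(sprintf("epoch %3d  train_loss %.4f  val_loss %.4f  stale %d",
                      epoch, tr_trace[epoch], val_trace[epoch],
                      state$stale_epochs))
    if (!is.finite(tr_trace[epoch]) || !is.finite(val_trace[epoch])) {
      diverged <- TRUE
      warning("training diverged (non-finite loss) at epoch ", epoch)
      break
    }
    es <- early_stop_update(state, val_trace[epoch], config$patience,
                            config$min_delta)
    state <- es$state
    if (state$best_epoch == epoch) best_layers <- net$layers
    if (es$halt) break
  }
  net$layers <- best_layers
  structure(list(net = net,
                 train_loss = tr_trace, val_loss = val_trace,
                 val_accuracy = acc_trace,
                 best_epoch = state$best_epoch,
                 stopped_epoch = length(val_trace),
                 val_accuracy_best = if (state$best_epoch > 0L)
                   acc_trace[state$best_epoch] else NA_real_,
                 diverged = diverged),
            class = "ila_train_result")
}

#' Cross-validate the classifier
#'
#' Runs either 5-fold (uniform random, `k` configurable) or
#' leave-one-allele-out cross-validation: each subset is used exactly once
#' for validation while the rest trains a freshly initialized network.
#' Failed rounds are marked and the remaining rounds continue.
#'
#' @param records Labeled, filtered binding-record data frame.
#' @param scheme `"five_fold"` or `"leave_one_allele_out"`.
#' @param registry A `pseudoseq_registry` covering the records' alleles.
#' @param scales A standardized `property_scales`.
#' @param spec An `ila_model_spec`; defaults to the standard architecture
#'   sized from the encoded data.
#' @param config A `train_config`.
#' @param k Number of folds for the `"five_fold"` scheme (default 5).
#' @return An `ila_cv` object: `rounds` data frame (per-round validation
#'   loss/accuracy), `mean_loss`, `mean_accuracy`, `scheme`.
#' @export
cross_validate <- function(records,
                           scheme = c("five_fold", "leave_one_allele_out"),
                           registry, scales, spec = NULL,
                           config = train_config(), k = 5L) {
  scheme <- match.arg(scheme)
  stopifnot("label" %in% names(records))
  enc <- encode_batch(records, registry, scales)
  if (nrow(enc$skipped))
    stop("records with unresolvable alleles: ",
         paste(unique(enc$skipped$allele), collapse = ", "), call. = FALSE)
  X <- ila_stack(enc$ilas)
  y <- as.integer(enc$labels == "binder")
  if (is.null(spec)) spec <- model_spec(input_shape = attr(X, "ila_dim"))
  splits <- if (scheme == "five_fold")
    make_kfold_splits(records, k = k, seed = config$seed)
  else make_leave_one_allele_out_splits(records)
  round_names <- if (is.null(names(splits)))
    paste0("fold", seq_along(splits)) else names(splits)
  rows <- vector("list", length(splits))
  for (r in seq_along(splits)) {
    sp <- splits[[r]]
    res <- tryCatch(
      train_network(build_model(spec, seed = config$seed + r),
                    X[, sp$train, drop = FALSE], y[sp$train],
                    X[, sp$validation, drop = FALSE], y[sp$validation],
                    config),
      error = function(e) e)
    failed <- inherits(res, "error") || isTRUE(res$diverged)
    rows[[r]] <- data.frame(
      round = r, name = round_names[r], n_val = length(sp$validation),
      val_loss = if (failed) NA_real_ else res$val_loss[res$best_epoch],
      val_accuracy = if (failed) NA_real_ else res$val_accuracy_best,
      failed = failed, stringsAsFactors = FALSE)
  }
  rounds <- do.call(rbind, rows)
  structure(list(scheme = scheme, rounds = rounds,
                 mean_loss = mean(rounds$val_loss, na.rm = TRUE),
                 mean_accuracy = mean(rounds$val_accuracy, na.rm = TRUE)),
            class = "ila_cv")
}

#' @export
print.ila_cv <- function(x, ...) {
  cat(sprintf("%s cross-validation: %d round(s)\n", x$scheme,
              nrow(x$rounds)))
  cat(sprintf("  mean validation loss %.4f, mean validation accuracy %.4f\n",
              x$mean_loss, x$mean_accuracy))
  if (any(x$rounds$failed))
    cat("  failed rounds:", paste(x$rounds$name[x$rounds$failed],
                                  collapse = ", "), "\n")
  invisible(x)
}
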