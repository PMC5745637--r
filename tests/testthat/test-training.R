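test_that("a strictly improving loss trace never triggers the monitor", {
  st <- early_stop_state()
  for (loss in seq(1, 0.71, by = -0.01)) {
    r <- early_stop_update(st, loss, patience = 15)
    st <- r$state
    expect_false(r$halt)
  }
  expect_equal(st$stale_epochs, 0L)
  expect_equal(st$best_epoch, st$epoch)
})

test_that("a 5-epoch improvement followed by a plateau halts after exactly the patience window", {
  trace <- c(seq(1.0, 0.6, length.out = 5), rep(0.6, 30))
  st <- early_stop_state()
  halted_at <- NA_integer_
  for (e in seq_along(trace)) {
    r <- early_stop_update(st, trace[e], patience = 15)
    st <- r$state
    if (r$halt) { halted_at <- e; break }
  }
  expect_equal(halted_at, 20L)          # 5 improving + 15 stale epochs
  expect_equal(st$stale_epochs, 15L)
  expect_equal(st$best_epoch, 5L)
})

test_that("halt epochs match a brute-force window scan on 200 random traces", {
  # oracle: halt at the first epoch e (e > p) whose trailing window of p
  # losses contains nothing below the pre-window minimum
  brute_halt <- function(trace, p) {
    for (e in seq_along(trace)) {
      if (e <= p) next
      if (min(trace[(e - p + 1):e]) >= min(trace[1:(e - p)])) return(e)
    }
    NA_integer_
  }
  set.seed(31)
  for (rep in 1:200) {
    p <- sample(2:10, 1)
    n <- sample(15:60, 1)
    trace <- round(cumsum(rnorm(n, -0.02, 0.3)) + 2, 3)
    st <- early_stop_state()
    halted_at <- NA_integer_
    for (e in seq_along(trace)) {
      r <- early_stop_update(st, trace[e], patience = p)
      st <- r$state
      if (r$halt) { halted_at <- e; break }
    }
    expect_identical(halted_at, brute_halt(trace, p))
  }
})

test_that("best loss is monotone and stale counts stay within patience", {
  set.seed(32)
  st <- early_stop_state()
  best_seen <- Inf
  for (loss in runif(60, 0, 1)) {
    r <- early_stop_update(st, loss, patience = 10)
    st <- r$state
    expect_lte(st$best_loss, best_seen)
    best_seen <- st$best_loss
    expect_lte(st$stale_epochs, 10L)
    if (r$halt) break
  }
})

test_that("non-finite validation losses halt with an error flag", {
  r <- early_stop_update(early_stop_state(), NaN, patience = 15)
  expect_true(r$halt)
  expect_true(r$error)
})

# -- training ---------------------------------------------------------------

separable_set <- function(n, seed) {
  # two well-separated Gaussian classes shaped as tiny ILAs
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(4 * 4 * 2 * n, mean = rep(ifelse(y == 1, 1.2, -1.2),
                                              each = 32)), ncol = n)
  list(X = X, y = y)
}

test_that("training recovers a separable signal and stops early", {
  tr <- separable_set(160, 41)
  va <- separable_set(60, 42)
  net <- build_model(tiny_spec(c(4L, 4L, 2L)), seed = 43)
  cfg <- train_config(max_epochs = 150, patience = 10, batch_size = 32,
                      seed = 44, min_delta = 1e-3)
  res <- train_network(net, tr$X, tr$y, va$X, va$y, cfg)
  expect_lt(res$stopped_epoch, cfg$max_epochs)
  expect_gt(res$val_accuracy_best, 0.95)
  expect_equal(length(res$train_loss), res$stopped_epoch)
  expect_equal(length(res$val_loss), res$stopped_epoch)
})

test_that("max_epochs = 1 runs exactly one epoch", {
  tr <- separable_set(60, 45)
  net <- build_model(tiny_spec(c(4L, 4L, 2L)), seed = 46)
  res <- train_network(net, tr$X, tr$y, tr$X[, 1:10], tr$y[1:10],
                       train_config(max_epochs = 1, patience = 1,
                                    batch_size = 16))
  expect_equal(res$stopped_epoch, 1L)
})

test_that("identical configuration and seed reproduce the loss traces", {
  tr <- separable_set(80, 47)
  va <- separable_set(40, 48)
  cfg <- train_config(max_epochs = 5, patience = 4, batch_size = 16,
                      seed = 49)
  run <- function() {
    net <- build_model(tiny_spec(c(4L, 4L, 2L), dropout = 0.25), seed = 50)
    train_network(net, tr$X, tr$y, va$X, va$y, cfg)
  }
  a <- run(); b <- run()
  expect_identical(a$train_loss, b$train_loss)
  expect_identical(a$val_loss, b$val_loss)
})

test_that("the returned model reproduces its best-epoch validation loss", {
  tr <- separable_set(100, 51)
  va <- separable_set(50, 52)
  net <- build_model(tiny_spec(c(4L, 4L, 2L)), seed = 53)
  res <- train_network(net, tr$X, tr$y, va$X, va$y,
                       train_config(max_epochs = 20, patience = 5,
                                    batch_size = 25, seed = 54))
  p <- predict(res$net, va$X)
  expect_equal(ilamhc:::bce_loss(p, va$y), res$val_loss[res$best_epoch],
               tolerance = 1e-6)
  expect_equal(min(res$val_loss), res$val_loss[res$best_epoch])
})

test_that("empty training or validation sets are rejected", {
  net <- build_model(tiny_spec(c(4L, 4L, 2L)), seed = 55)
  X <- matrix(0, 32, 0)
  Y <- matrix(rnorm(32), 32, 1)
  expect_error(train_network(net, X, numeric(0), Y, 1, train_config()),
               "non-empty")
})

# -- cross-validation -------------------------------------------------------

test_that("both cross-validation schemes run one round per subset", {
  world <- small_world()
  recs <- small_records(120)
  sc <- small_scales()
  spec <- tiny_spec(c(world$config$contact_count, 9L,
                      2L * ncol(sc$values)))
  cfg <- train_config(max_epochs = 2, patience = 1, batch_size = 32,
                      seed = 7)
  cv5 <- cross_validate(recs, "five_fold", world$registry, sc, spec, cfg,
                        k = 3)
  expect_equal(nrow(cv5$rounds), 3L)
  expect_false(any(cv5$rounds$failed))
  expect_equal(cv5$mean_accuracy, mean(cv5$rounds$val_accuracy))
  expect_equal(cv5$mean_loss, mean(cv5$rounds$val_loss))

  cvl <- cross_validate(recs, "leave_one_allele_out", world$registry, sc,
                        spec, cfg)
  expect_equal(nrow(cvl$rounds), length(unique(recs$allele)))
  expect_equal(sum(cvl$rounds$n_val), nrow(recs))
})
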