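# Small separable synthetic inputs for fast training-mechanics tests:
# each class shifts a different row band of the grid.
blob_input <- function(cls, seed, shape = c(32, 40)) {
  g <- withr::with_seed(seed, matrix(stats::rnorm(prod(shape), 0, 0.3),
                                     shape[1], shape[2]))
  rows <- list(1:10, 12:21, 23:32)[[cls + 1]]
  g[rows, ] <- g[rows, ] + 2
  to_model_input(g, shape)
}

blob_set <- function(n, seed0, shape = c(32, 40)) {
  y <- rep(0:2, length.out = n)
  list(inputs = lapply(seq_len(n), function(i) blob_input(y[i], seed0 + i, shape)),
       labels = y)
}

tiny_cfg2 <- model_config("cnn_lstm_mfcc", stage_widths = c(4, 6, 8, 10),
                          blocks_per_stage = 1, lstm_hidden = 8, dropout = 0.1,
                          input_shape = c(32, 40))

test_that("splits are disjoint, exhaustive, stratified, and seeded", {
  labels <- rep(c("normal", "wheeze", "fine_crackle"), times = c(60, 25, 15))
  sp <- split_spec(seed = 5)
  parts <- split_dataset(labels, spec = sp)
  expect_equal(sort(c(parts$train, parts$val, parts$test)), 1:100)
  expect_length(intersect(parts$train, parts$val), 0)
  expect_length(intersect(parts$train, parts$test), 0)
  expect_length(intersect(parts$val, parts$test), 0)
  expect_length(parts$train, 70)
  expect_length(parts$val, 15)
  expect_length(parts$test, 15)
  # per-class largest-remainder: 60 -> (42,9,9), 25 -> (17.5 -> 18,4,3|4)...
  for (cl in unique(labels)) {
    n_cl <- sum(labels == cl)
    got <- vapply(parts, function(ix) sum(labels[ix] == cl), 0L)
    want <- auscultnet:::largest_remainder(n_cl, c(0.7, 0.15, 0.15))
    expect_equal(as.vector(got), want)
  }
  expect_identical(parts, split_dataset(labels, spec = sp))
  expect_false(identical(parts, split_dataset(labels, spec = split_spec(seed = 6))))
  expect_error(split_dataset(rep(c("normal", "wheeze", "fine_crackle"),
                                 c(5, 5, 2))),
               "too small")
})

test_that("subject grouping keeps subjects and their augmented variants together", {
  labels <- rep(c("normal", "wheeze", "fine_crackle"), each = 12)
  subjects <- paste0("S", rep(1:12, 3))  # 3 recordings per subject? no: unique per row
  subjects <- sprintf("S%02d", rep(1:18, each = 2))  # 2 items per subject
  labels <- rep(rep(c("normal", "wheeze", "fine_crackle"), each = 6), each = 2)
  aug_ids <- paste0(subjects, c("", "_aug001"))
  parts <- split_dataset(labels, aug_ids, split_spec(seed = 2))
  part_of <- integer(length(labels))
  for (p in 1:3) part_of[parts[[p]]] <- p
  base <- sub("_aug[0-9]+$", "", aug_ids)
  for (s in unique(base)) {
    expect_length(unique(part_of[base == s]), 1)
  }
})

test_that("a one-epoch session trains, logs history, and follows the lr schedule", {
  tr <- blob_set(24, 100)
  vl <- blob_set(9, 900)
  tc <- train_config(epochs = 1, batch_size = 8, lr_start = 1e-3, lr_end = 5e-4,
                     n_sessions = 1)
  sess <- train_session(tiny_cfg2, tr, vl, tc, session_seed = 3)
  expect_equal(nrow(sess$history), 1)
  expect_true(all(is.finite(sess$history$train_loss)))
  expect_equal(sess$history$lr[1], 1e-3)

  tc5 <- train_config(epochs = 5, batch_size = 8, lr_start = 1e-4, lr_end = 5e-5)
  lrs <- vapply(1:5, function(e) auscultnet:::.lr_at(tc5, e), 0)
  expect_equal(lrs[1], 1e-4)
  expect_equal(lrs[5], 5e-5)
  expect_equal(diff(lrs), rep(diff(lrs)[1], 4))  # linear decay
})

test_that("training is deterministic end to end", {
  tr <- blob_set(18, 40)
  vl <- blob_set(6, 800)
  tc <- train_config(epochs = 2, batch_size = 6, lr_start = 1e-3, lr_end = 5e-4)
  s1 <- train_session(tiny_cfg2, tr, vl, tc, session_seed = 7)
  s2 <- train_session(tiny_cfg2, tr, vl, tc, session_seed = 7)
  expect_identical(s1$model$params, s2$model$params)
  expect_identical(s1$history, s2$history)
  s3 <- train_session(tiny_cfg2, tr, vl, tc, session_seed = 8)
  expect_false(identical(s1$model$params, s3$model$params))
})

test_that("ensembles aggregate metrics with sd = 0 for a single session", {
  tr <- blob_set(18, 60)
  vl <- blob_set(6, 600)
  te <- blob_set(6, 700)
  splits <- list(train = tr, val = vl, test = te)
  tc1 <- train_config(epochs = 1, batch_size = 6, lr_start = 1e-3, lr_end = 1e-3,
                      n_sessions = 1)
  ens1 <- train_ensemble(tiny_cfg2, splits, tc1)
  expect_length(ens1$models, 1)
  expect_equal(ens1$summary$sd, rep(0, 5))
  expect_true(all(ens1$summary$mean >= 0 & ens1$summary$mean <= 1))

  tc2 <- train_config(epochs = 1, batch_size = 6, lr_start = 1e-3, lr_end = 1e-3,
                      n_sessions = 2)
  ens2 <- train_ensemble(tiny_cfg2, splits, tc2, aggregate = "probs")
  expect_length(ens2$models, 2)
  expect_equal(nrow(ens2$summary), 5)
  expect_s3_class(ens2$prob_report, "eval_report")
})

test_that("training loss trends downward on a separable problem", {
  tr <- blob_set(30, 10)
  vl <- blob_set(9, 90)
  tc <- train_config(epochs = 6, batch_size = 10, lr_start = 3e-3, lr_end = 1e-3)
  sess <- train_session(tiny_cfg2, tr, vl, tc, session_seed = 5)
  drops <- diff(sess$history$train_loss) < 0
  expect_gte(mean(drops), 0.8)
  expect_lt(sess$history$train_loss[6], sess$history$train_loss[1])
})
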