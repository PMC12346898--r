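# A small configuration keeps the unit tests fast; shapes generalize.
tiny_cfg <- function(variant = "cnn_lstm_mfcc", dropout = 0) {
  model_config(variant, stage_widths = c(4, 6, 8, 10), blocks_per_stage = 1,
               lstm_hidden = 8, dropout = dropout, input_shape = c(32, 40))
}

rand_input <- function(cfg, seed = 1) {
  g <- withr::with_seed(seed, matrix(stats::rnorm(prod(cfg$input_shape)),
                                     cfg$input_shape[1], cfg$input_shape[2]))
  to_model_input(g, cfg$input_shape)
}

test_that("residual blocks with a zeroed branch return their input exactly", {
  cfg <- model_config(stage_widths = c(6, 8, 10, 12), blocks_per_stage = 2,
                      input_shape = c(32, 40))
  m <- build_model(cfg, seed = 2)
  # every identity-skip block (block 2 of each stage, and stage-1 block 1)
  identity_blocks <- list(c(1, 1), c(1, 2), c(2, 2), c(3, 2), c(4, 2))
  shapes <- list(c(8, 10), c(8, 10), c(4, 5), c(2, 3), c(1, 2))
  widths <- c(6, 6, 8, 10, 12)
  for (i in seq_along(identity_blocks)) {
    sb <- identity_blocks[[i]]
    m0 <- zero_residual_branch(m, sb[1], sb[2])
    x <- withr::with_seed(i, array(stats::rnorm(prod(shapes[[i]]) * widths[i]),
                                   c(shapes[[i]], widths[i])))
    y <- residual_block(m0, sb[1], sb[2], x)
    expect_identical(y, x)
  }
  # non-zero branch: y != x and y - F(x) == x-projection
  x <- withr::with_seed(99, array(stats::rnorm(8 * 10 * 6), c(8, 10, 6)))
  expect_false(isTRUE(all.equal(residual_block(m, 1, 2, x), x)))
  # zeroed F with x = 0 gives y = 0 (= F(0) + 0)
  z <- array(0, c(8, 10, 6))
  expect_identical(residual_block(zero_residual_branch(m, 1, 2), 1, 2, z), z)
})

test_that("convolution layer matches a hand-rolled triple-loop oracle", {
  ns <- asNamespace("auscultnet")
  set.seed(5)
  for (case in list(list(k = 3L, stride = 1L, pad = 1L),
                    list(k = 3L, stride = 2L, pad = 1L),
                    list(k = 1L, stride = 2L, pad = 0L),
                    list(k = 7L, stride = 2L, pad = 3L))) {
    H <- 9L; W <- 11L; Cin <- 2L; Cout <- 3L
    x <- array(rnorm(H * W * Cin), c(H, W, Cin))
    Wm <- matrix(rnorm(Cout * case$k^2 * Cin), Cout, case$k^2 * Cin)
    a <- ns$.act(matrix(aperm(x, c(3, 1, 2)), Cin, H * W), H, W, Cin, 1L)
    got <- ns$conv_fwd(Wm, a, case$k, case$stride, case$pad)$a
    want <- oracle_conv2d(x, Wm, case$k, case$stride, case$pad)
    got_arr <- aperm(array(got$x, c(got$C, got$H, got$W)), c(2, 3, 1))
    expect_equal(got_arr, want, tolerance = 1e-12)
  }
})

test_that("forward pass yields a softmax distribution for every variant", {
  for (variant in c("cnn_lstm_mfcc", "cnn_mfcc", "cnn_lstm_ts", "cnn_ts")) {
    cfg <- tiny_cfg(variant)
    m <- build_model(cfg, seed = 4)
    pr <- predict(m, rand_input(cfg))
    expect_equal(dim(pr$probs), c(3, 1))
    expect_true(all(pr$probs >= 0))
    expect_equal(sum(pr$probs), 1, tolerance = 1e-6)
    expect_true(pr$pred %in% 0:2)
  }
  # batch of random inputs
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 4)
  pr <- predict(m, lapply(1:7, function(s) rand_input(cfg, s)))
  expect_equal(colSums(pr$probs), rep(1, 7), tolerance = 1e-6)
})

test_that("builds and predictions are deterministic; ties break to the lowest class", {
  cfg <- tiny_cfg()
  m1 <- build_model(cfg, seed = 11)
  m2 <- build_model(cfg, seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 12)
  expect_false(identical(m1$params, m3$params))
  mi <- rand_input(cfg)
  expect_identical(predict(m1, mi)$probs, predict(m1, mi)$probs)
  # tie-break rule on the argmax reduction used by predict
  probs <- matrix(c(0.4, 0.4, 0.2), 3, 1)
  expect_equal(max.col(t(probs), ties.method = "first") - 1L, 0L)
  expect_error(predict(m1, to_model_input(matrix(rnorm(100), 10, 10), c(10, 10))),
               "shape")
})

test_that("the backward pass matches numerical gradients (smooth layers)", {
  ns <- asNamespace("auscultnet")
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 3)
  Xb <- withr::with_seed(9, matrix(rnorm(prod(cfg$input_shape) * 2),
                                   prod(cfg$input_shape), 2))
  y <- c(0L, 2L)
  loss_of <- function(model) {
    fw <- ns$nn_forward(model, Xb, training = TRUE, want_cache = FALSE)
    ns$cross_entropy(fw$probs, y)$loss
  }
  fw <- ns$nn_forward(m, Xb, training = TRUE)
  ce <- ns$cross_entropy(fw$probs, y)
  bk <- ns$nn_backward(fw$model, fw$caches, ce$dlogits)
  eps <- 1e-5
  # layers above all ReLU/pooling kinks are exactly checkable
  for (nm in c("fc.W", "fc.b", "lstm.Wx", "lstm.Wh", "lstm.b",
               "s4.b1.conv1.W", "s4.b1.bn2.gamma", "s4.b1.proj.W")) {
    p <- m$params[[nm]]
    ii <- withr::with_seed(1, sample(length(p), min(3, length(p))))
    for (i in ii) {
      m2 <- m
      m2$params[[nm]][i] <- p[i] + eps
      lp <- loss_of(m2)
      m2$params[[nm]][i] <- p[i] - eps
      lm <- loss_of(m2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(bk$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("one RAdam step on a single example reduces its loss", {
  ns <- asNamespace("auscultnet")
  cfg <- tiny_cfg()
  m <- build_model(cfg, seed = 6)
  mi <- rand_input(cfg, 2)
  Xb <- matrix(as.vector(mi$grid), ncol = 1)
  y <- 1L
  opt <- radam_init(m$params, lr = 1e-3)
  losses <- numeric(8)
  for (step in 1:8) {
    fw <- ns$nn_forward(m, Xb, training = TRUE)
    ce <- ns$cross_entropy(fw$probs, y)
    losses[step] <- ce$loss
    bk <- ns$nn_backward(fw$model, fw$caches, ce$dlogits)
    m <- fw$model
    m$params <- radam_step(opt, m$params, bk$grads)
  }
  expect_lt(losses[8], losses[1])
})

test_that("describe_model reports a stable parameter count", {
  cfg <- tiny_cfg()
  out1 <- utils::capture.output(df1 <- describe_model(build_model(cfg, seed = 1)))
  out2 <- utils::capture.output(df2 <- describe_model(build_model(cfg, seed = 99)))
  expect_identical(df1$n_params, df2$n_params)
  expect_true(any(grepl("total parameters", out1)))
  # hand count of one tensor: stem conv is widths[1] x 7*7
  expect_equal(df1$n_params[df1$tensor == "stem.conv.W"], 4 * 49)
  # default-size model parameter budget is under the reference 3.6 M
  full <- build_model(model_config(), seed = 1)
  n_full <- sum(vapply(full$params, length, 0L))
  expect_gt(n_full, 5e5)
  expect_lt(n_full, 3.6e6)
})

test_that("activation maps are normalized, input-shaped, and localize planted cues", {
  ns <- asNamespace("auscultnet")
  cfg <- tiny_cfg(dropout = 0)
  m <- build_model(cfg, seed = 8)
  mi <- rand_input(cfg, 3)
  cam <- activation_map(m, mi, 1)
  expect_equal(dim(cam), cfg$input_shape)
  expect_gte(min(cam), 0)
  expect_lte(max(cam), 1)

  # plant a discriminative cue in a known column band and train briefly:
  # class 1 inputs carry a strong block in columns 81..112, class 0 none.
  # (64 x 160 inputs give the final stage enough temporal resolution for
  # the map to localize.)
  cfg2 <- model_config("cnn_lstm_mfcc", stage_widths = c(4, 6, 8, 10),
                       blocks_per_stage = 1, lstm_hidden = 8, dropout = 0,
                       input_shape = c(64, 160))
  m2 <- build_model(cfg2, seed = 8)
  make_ex <- function(cls, seed) {
    g <- withr::with_seed(seed, matrix(stats::rnorm(64 * 160, 0, 0.2), 64, 160))
    if (cls == 1) g[16:48, 81:112] <- g[16:48, 81:112] + 3
    to_model_input(g, c(64, 160))
  }
  n <- 30
  inputs <- lapply(1:n, function(i) make_ex(i %% 2, i))
  y <- (1:n) %% 2
  opt <- radam_init(m2$params, lr = 3e-3)
  S <- prod(cfg2$input_shape)
  Xb <- vapply(inputs, function(q) as.vector(q$grid), numeric(S))
  for (ep in 1:20) {
    fw <- ns$nn_forward(m2, Xb, training = TRUE)
    ce <- ns$cross_entropy(fw$probs, as.integer(y))
    bk <- ns$nn_backward(fw$model, fw$caches, ce$dlogits)
    m2 <- fw$model
    m2$params <- radam_step(opt, m2$params, bk$grads)
  }
  cam1 <- activation_map(m2, make_ex(1, 999), 1)
  in_band <- sum(cam1[, 65:128])    # planted band plus upsampling halo
  expect_gt(in_band / sum(cam1), 0.5)
})
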