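tiny_cfg <- model_config(depth = 2, base_filters = 2)

test_that("the untrained model emits normalised, finite per-pixel probabilities", {
  m <- build_model(model_config(), seed = 1)
  px <- matrix(runif(400, -1000, 400), 20, 20)
  out <- predict_patch(m, px)
  expect_identical(dim(out$probs), c(20L, 20L, 6L))
  expect_identical(dim(out$labels), c(20L, 20L))
  sums <- apply(out$probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(is.finite(out$probs)))
  # argmax of probabilities equals the returned labels everywhere
  am <- apply(out$probs, c(1, 2), which.max) - 1L
  expect_true(all(am == out$labels))
})

test_that("uniform logits resolve ties towards the lowest class index", {
  m <- build_model(tiny_cfg, seed = 1)
  m$params <- lapply(m$params, function(p) p * 0)
  out <- predict_patch(m, matrix(rnorm(64), 8, 8))
  expect_true(all(out$labels == 0L))
  expect_true(all(abs(out$probs - 1 / 6) < 1e-12))
})

test_that("parameter count equals the layer-by-layer closed form", {
  cfg <- model_config(depth = 2, base_filters = 8)
  m <- build_model(cfg)
  # encoder: conv 4x4 (1->8) + residual (8->8); conv (8->16) + residual
  # (16->16); bottleneck (16->16); decoder (16->16), (16->8); output 1x1 (8->6)
  expected <- (16 * 1 * 8 + 8) + (16 * 8 * 8 + 8) +
    (16 * 8 * 16 + 16) + (16 * 16 * 16 + 16) +
    (16 * 16 * 16 + 16) +
    (16 * 16 * 16 + 16) + (16 * 16 * 8 + 8) +
    (8 * 6 + 6)
  expect_equal(n_parameters(m), expected)
})

test_that("backpropagated gradients match finite differences", {
  m <- build_model(tiny_cfg, seed = 3)
  set.seed(11)
  # jitter off exact-zero ReLU kinks, where the subgradient and the central
  # difference legitimately disagree
  m$params <- lapply(m$params, function(p) p + rnorm(length(p), 0, 0.05))
  set.seed(7)
  items <- lapply(1:2, function(i) list(
    pixels = matrix(runif(64, -1000, 400), 8, 8),
    labels = matrix(sample(0:5, 64, TRUE), 8, 8)))
  enc <- perlintex:::encode_batch(items, tiny_cfg)
  fw <- perlintex:::net_forward(m$params, tiny_cfg, enc$X, enc$N, enc$Hp, enc$Wp, keep = TRUE)
  ce <- perlintex:::nn_softmax_ce(fw$logits, enc$crop_rows, enc$targets)
  g <- perlintex:::net_backward(m$params, tiny_cfg, fw$cache, ce$dL)
  loss_at <- function(p) {
    fw2 <- perlintex:::net_forward(p, tiny_cfg, enc$X, enc$N, enc$Hp, enc$Wp, keep = FALSE)
    perlintex:::nn_softmax_ce(fw2$logits, enc$crop_rows, enc$targets)$loss
  }
  eps <- 1e-5
  for (nm in names(m$params)) {
    for (i in sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))) {
      p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]) / max(1e-6, abs(num) + abs(g[[nm]][i])), 1e-4)
    }
  }
})

test_that("inputs indivisible by 2^depth are reflect-padded and cropped back", {
  m <- build_model(model_config(depth = 3, base_filters = 2), seed = 2)
  out <- predict_patch(m, matrix(rnorm(400), 20, 20))  # pads to 24 internally
  expect_identical(dim(out$labels), c(20L, 20L))
  sums <- apply(out$probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
})

local({
  set.seed(4)
  pool <- patch_dataset(lapply(0:5, function(c) {
    patch(matrix(rnorm(144, mean = c * 150 - 800, sd = 40), 12, 12), c)
  }))
  tiny_split <- structure(list(train = pool, test = pool,
                               train_idx = 1:6, test_idx = 1:6,
                               test_fraction = 0.5, seed = 0L),
                          class = "dataset_split")

  test_that("max_steps = 0 returns the initial model with empty history", {
    fit <- ptex_train(tiny_split, tiny_cfg, train_config(max_steps = 0, seed = 1))
    expect_s3_class(fit, "ptex_fit")
    expect_equal(nrow(fit$history), 0)
    ref <- build_model(tiny_cfg, seed = derive_seed(1, 0))
    expect_identical(fit$model$params, ref$params)
  })

  test_that("training is reproducible from its seeds", {
    tc <- train_config(max_steps = 6, eval_interval = 3, seed = 5)
    f1 <- ptex_train(tiny_split, tiny_cfg, tc)
    f2 <- ptex_train(tiny_split, tiny_cfg, tc)
    expect_identical(f1$history, f2$history)
    expect_identical(f1$model$params, f2$model$params)
  })

  test_that("the returned model is the best evaluated checkpoint", {
    fit <- ptex_train(tiny_split, tiny_cfg,
                      train_config(max_steps = 20, eval_interval = 5, seed = 2))
    ev <- fit$history$heldout_accuracy
    expect_equal(fit$best_accuracy, max(ev, na.rm = TRUE))
    expect_equal(perlintex:::heldout_accuracy(fit$model$params, fit$model$config,
                                              tiny_split$test),
                 fit$best_accuracy)
  })
})
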