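# stub per-pixel classifier for tiling tests: scores each pixel against
# class template intensities, blending in the window mean so that (like a
# CNN) a window's context influences its predictions
stub_classifier <- function(mu, context_weight = 0.3, sharpness = 1e4) {
  structure(list(mu = mu, w = context_weight, s = sharpness), class = "stub_clf")
}

predict.stub_clf <- function(object, newdata, ...) {
  px <- as.matrix(newdata)
  eff <- (1 - object$w) * px + object$w * mean(px)
  probs <- array(0, c(nrow(px), ncol(px), length(object$mu)))
  for (k in seq_along(object$mu)) {
    probs[, , k] <- exp(-(eff - object$mu[k])^2 / object$s)
  }
  tot <- apply(probs, c(1, 2), sum)
  for (k in seq_along(object$mu)) probs[, , k] <- probs[, , k] / tot
  list(probs = probs, labels = apply(probs, c(1, 2), which.max) - 1L)
}
registerS3method("predict", "stub_clf", predict.stub_clf, envir = asNamespace("stats"))

test_that("pixel accuracy implements the per-pixel fraction times 100", {
  truth <- matrix(sample(0:5, 400, TRUE), 20, 20)
  expect_identical(pixel_accuracy(truth, truth), 100)
  half <- truth
  half[seq_len(200)] <- (half[seq_len(200)] + 1L) %% 6L
  expect_identical(pixel_accuracy(half, truth), 50)
  expect_error(pixel_accuracy(truth, matrix(0L, 10, 10)), "shape")
})

test_that("random six-class labels agree at the chance rate", {
  set.seed(123)
  pred <- matrix(sample(0:5, 1e5, TRUE), 1000, 100)
  truth <- matrix(sample(0:5, 1e5, TRUE), 1000, 100)
  acc <- pixel_accuracy(pred, truth)
  expect_lt(abs(acc - 100 / 6), 0.5)
})

test_that("per-class tables match a brute-force confusion matrix", {
  set.seed(9)
  truths <- lapply(1:12, function(i) matrix(rep(0:5, length.out = 100), 10, 10))
  preds <- lapply(truths, function(t) {
    p <- t
    flip <- runif(100) < 0.3
    p[flip] <- (p[flip] + sample(1:5, sum(flip), TRUE)) %% 6L
    p
  })
  rep <- per_class_table(preds, truths)

  pv <- unlist(preds); tv <- unlist(truths)
  cm <- table(factor(tv, 0:5), factor(pv, 0:5))
  for (c in 0:5) {
    expect_equal(unname(rep$per_class_accuracy[c + 1]),
                 100 * cm[c + 1, c + 1] / sum(cm[c + 1, ]))
  }
  # pixel-weighted per-class average equals the overall mean
  w <- rowSums(cm) / sum(cm)
  expect_equal(sum(w * rep$per_class_accuracy), rep$mean_accuracy, tolerance = 1e-9)
  # permutation invariance over patch order
  o <- sample(12)
  expect_equal(per_class_table(preds[o], truths[o])$mean_accuracy, rep$mean_accuracy)
})

test_that("classes absent from the truth are undefined, not zero", {
  truths <- list(matrix(2L, 5, 5))
  preds <- list(matrix(2L, 5, 5))
  rep <- per_class_table(preds, truths)
  expect_equal(unname(rep$per_class_accuracy["consolidation"]), 100)
  expect_true(all(is.na(rep$per_class_accuracy[setdiff(names(ptex_classes()), "consolidation")])))
  expect_equal(rep$mean_accuracy, 100)
})

test_that("paired t agrees with the closed form and flags degenerate input", {
  same <- c(80, 85, 90)
  cmp <- paired_t(same, same)
  expect_true(cmp$degenerate)
  expect_equal(cmp$t_statistic, 0)
  expect_equal(cmp$p_value, 1)

  const <- paired_t(c(81, 86, 91), same)
  expect_true(const$degenerate)
  expect_identical(const$t_statistic, Inf)

  set.seed(31)
  a <- 80 + rnorm(30)
  b <- a - rnorm(30, mean = 0.5, sd = 1)
  cmp <- paired_t(a, b)
  ref <- ref_paired_t(a, b)
  expect_equal(cmp$t_statistic, ref$t, tolerance = 1e-9)
  expect_equal(cmp$p_value, ref$p, tolerance = 1e-9)
  expect_false(cmp$degenerate)
  expect_error(paired_t(a, a[-1]), "equal length")
})

test_that("evaluating predictions against themselves yields exactly 100", {
  set.seed(2)
  preds <- lapply(1:5, function(i) matrix(sample(0:5, 400, TRUE), 20, 20))
  expect_identical(per_class_table(preds, preds)$mean_accuracy, 100)
})

test_that("tile quantification votes probabilities and respects the mask", {
  clf <- stub_classifier(mu = c(-800, -300, 200), context_weight = 0)
  img <- matrix(-800, 40, 40)
  fg <- matrix(TRUE, 40, 40)
  fg[1:5, ] <- FALSE
  lab <- tile_quantify(clf, img, fg, tile = 20, stride = 20)
  expect_true(all(is.na(lab[1:5, ])))
  expect_true(all(lab[6:40, ] == 0L))

  expect_error(tile_quantify(clf, img, matrix(FALSE, 40, 40), tile = 20), "empty")
  expect_error(tile_quantify(clf, img, fg, tile = 64), "exceeds")
})

test_that("overlapping tiles recover at least as many boundary pixels", {
  set.seed(5)
  img <- cbind(matrix(rnorm(60 * 30, -800, 60), 60, 30),
               matrix(rnorm(60 * 30, -300, 60), 60, 30))
  truth <- cbind(matrix(0L, 60, 30), matrix(1L, 60, 30))
  fg <- matrix(TRUE, 60, 60)
  clf <- stub_classifier(mu = c(-800, -300, 200), context_weight = 0.4)
  lab_coarse <- tile_quantify(clf, img, fg, tile = 20, stride = 20)
  lab_fine <- tile_quantify(clf, img, fg, tile = 20, stride = 1)
  band <- 21:40  # columns around the class boundary
  correct_coarse <- sum(lab_coarse[, band] == truth[, band])
  correct_fine <- sum(lab_fine[, band] == truth[, band])
  expect_gte(correct_fine, correct_coarse)
})
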