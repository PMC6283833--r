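make_test_patch <- function(value, label = "normal", n = 20L) {
  patch(matrix(value, n, n), label, id = paste0("p", value))
}

test_that("sign-threshold masks partition the patch, zeros going positive", {
  m_pos <- field_to_mask(fake_field(matrix(0.5, 4, 4)))
  expect_true(all(m_pos$region))
  vals <- matrix(-0.2, 4, 4)
  vals[2, 3] <- 0
  m <- field_to_mask(fake_field(vals))
  expect_true(m$region[2, 3])
  expect_equal(sum(m$region) + sum(!m$region), 16)
})

test_that("mask true-fraction is balanced across seeds", {
  fr <- vapply(1:1000, function(s) {
    mean(field_to_mask(noise_field(20, 20, scale = 0.1, seed = s))$region)
  }, numeric(1))
  expect_gte(mean(fr), 0.45)
  expect_lte(mean(fr), 0.55)
})

test_that("blending routes every pixel and label to the masked source", {
  a <- make_test_patch(100, "ggo")
  b <- make_test_patch(-500, "emphysema")
  all_true <- structure(list(region = matrix(TRUE, 20, 20), source_seed = 1L),
                        class = "binary_mask")
  out <- perlin_blend(a, b, all_true)
  expect_identical(out$pixels, a$pixels)
  expect_true(all(out$labels == a$label))

  same <- perlin_blend(a, a, field_to_mask(noise_field(20, 20, seed = 2)))
  expect_identical(same$pixels, a$pixels)
  expect_true(all(same$labels == a$label))

  # a mask with exactly 137 true pixels labels exactly 137 pixels as source a
  reg <- matrix(FALSE, 20, 20)
  reg[seq_len(137)] <- TRUE
  m137 <- structure(list(region = reg, source_seed = 9L), class = "binary_mask")
  out <- perlin_blend(a, b, m137)
  expect_equal(sum(out$labels == a$label), 137)
  expect_equal(sum(out$labels == b$label), 400 - 137)

  expect_error(perlin_blend(a, make_test_patch(0, n = 10L), m137), "shape")
})

test_that("blend provenance holds pixel by pixel for random inputs", {
  set.seed(1)
  for (s in 1:20) {
    a <- patch(matrix(rnorm(400), 20, 20), "ro", id = "a")
    b <- patch(matrix(rnorm(400), 20, 20), "consolidation", id = "b")
    mask <- field_to_mask(noise_field(20, 20, scale = 0.1, seed = s))
    out <- perlin_blend(a, b, mask)
    from_a <- out$labels == a$label
    expect_identical(out$pixels[from_a], a$pixels[from_a])
    expect_identical(out$pixels[!from_a], b$pixels[!from_a])
    expect_true(all(out$labels %in% c(a$label, b$label)))
  }
})

test_that("flips compose, invert, and occur with the right frequencies", {
  p <- patch(matrix(c(1, 3, 2, 4), 2, 2), "normal")  # [[1,2],[3,4]] by row
  both <- apply_flip(p, TRUE, TRUE)
  expect_identical(both$pixels, matrix(c(4, 2, 3, 1), 2, 2))  # [[4,3],[2,1]]
  expect_identical(apply_flip(p)$pixels, p$pixels)
  # involution
  expect_identical(apply_flip(apply_flip(p, TRUE, FALSE), TRUE, FALSE)$pixels, p$pixels)
  expect_identical(apply_flip(apply_flip(p, TRUE, TRUE), TRUE, TRUE)$pixels, p$pixels)

  # label grids flip identically
  ap <- structure(list(pixels = p$pixels, labels = matrix(0:3, 2, 2),
                       provenance = NULL), class = "aug_patch")
  f <- apply_flip(ap, TRUE, TRUE)
  expect_identical(f$labels, matrix(c(3L, 2L, 1L, 0L), 2, 2))

  combo <- vapply(1:10000, function(s) {
    out <- random_flip(p, s)$pixels
    paste(out, collapse = ",")
  }, character(1))
  freq <- as.vector(table(combo)) / 10000
  expect_equal(length(freq), 4L)
  expect_true(all(abs(freq - 0.25) <= 0.02))
})

test_that("gaussian augmentation adds noise at a tenth of the patch spread", {
  const <- make_test_patch(-800)
  expect_identical(gaussian_augment(const, 1)$pixels, const$pixels)

  set.seed(2)
  v <- rnorm(400)
  v <- (v - mean(v)) / sqrt(mean((v - mean(v))^2)) * 100  # population sd 100
  p <- patch(matrix(v, 20, 20), "ggo")
  expect_identical(gaussian_augment(p, 7)$pixels, gaussian_augment(p, 7)$pixels)
  eps <- unlist(lapply(1:1000, function(s) gaussian_augment(p, s)$pixels - p$pixels))
  expect_lt(abs(sd(eps) - 10) / 10, 0.15)
})

test_that("batches have the right size, classes and reproducibility", {
  set.seed(3)
  pool <- patch_dataset(lapply(0:5, function(c) {
    patch(matrix(rnorm(400, mean = c * 100), 20, 20), c, id = paste0("c", c))
  }))
  b <- make_batch(pool, 16, mode = "perlin", seed = 1)
  expect_length(b, 16)
  expect_true(all(vapply(b, function(x) inherits(x, "aug_patch"), logical(1))))
  # at most two classes mixed per item
  expect_true(all(vapply(b, function(x) length(unique(as.vector(x$labels))), integer(1)) <= 2))

  b2 <- make_batch(pool, 16, mode = "perlin", seed = 1)
  expect_identical(lapply(b, `[[`, "pixels"), lapply(b2, `[[`, "pixels"))

  one <- patch_dataset(list(get_patch(pool, 2)))
  bb <- make_batch(one, 8, mode = "perlin", seed = 4)
  expect_true(all(vapply(bb, function(x) all(x$labels == 1L), logical(1))))

  conv <- make_batch(pool, 1000, mode = "conventional", seed = 5)
  expect_true(all(vapply(conv, function(x) length(unique(as.vector(x$labels))), integer(1)) == 1L))
  freq <- table(factor(vapply(conv, function(x) x$labels[1, 1], integer(1)), levels = 0:5)) / 1000
  expect_true(all(abs(freq - 1 / 6) <= 0.03))

  expect_error(make_batch(patch_dataset(list()), 4, seed = 1), "non-empty")
})
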