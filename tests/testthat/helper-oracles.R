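# Independent oracles used across the suite.

# Scalar line-by-line transcription of the published reference 2D simplex
# noise algorithm (skew to the triangular lattice, pick the containing
# triangle, per-corner (0.5 - d^2)^4 * (gradient . distance), times 70),
# kept deliberately independent of the package's vectorised implementation.
ref_simplex2d <- function(x, y, perm) {
  grad3 <- list(c(1, 1), c(-1, 1), c(1, -1), c(-1, -1),
                c(1, 0), c(-1, 0), c(1, 0), c(-1, 0),
                c(0, 1), c(0, -1), c(0, 1), c(0, -1))
  F2 <- 0.5 * (sqrt(3) - 1)
  G2 <- (3 - sqrt(3)) / 6
  s <- (x + y) * F2
  i <- floor(x + s)
  j <- floor(y + s)
  t <- (i + j) * G2
  x0 <- x - (i - t)
  y0 <- y - (j - t)
  if (x0 > y0) { i1 <- 1; j1 <- 0 } else { i1 <- 0; j1 <- 1 }
  x1 <- x0 - i1 + G2
  y1 <- y0 - j1 + G2
  x2 <- x0 - 1 + 2 * G2
  y2 <- y0 - 1 + 2 * G2
  ii <- i %% 256
  jj <- j %% 256
  p <- c(perm, perm)
  gi0 <- p[ii + p[jj + 1] + 1] %% 12
  gi1 <- p[ii + i1 + p[jj + j1 + 1] + 1] %% 12
  gi2 <- p[ii + 1 + p[jj + 1 + 1] + 1] %% 12
  n <- 0
  t0 <- 0.5 - x0 * x0 - y0 * y0
  if (t0 > 0) {
    g <- grad3[[gi0 + 1]]
    n <- n + t0^4 * (g[1] * x0 + g[2] * y0)
  }
  t1 <- 0.5 - x1 * x1 - y1 * y1
  if (t1 > 0) {
    g <- grad3[[gi1 + 1]]
    n <- n + t1^4 * (g[1] * x1 + g[2] * y1)
  }
  t2 <- 0.5 - x2 * x2 - y2 * y2
  if (t2 > 0) {
    g <- grad3[[gi2 + 1]]
    n <- n + t2^4 * (g[1] * x2 + g[2] * y2)
  }
  70 * n
}

# textbook paired t statistic and two-sided p-value
ref_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1))
}

# a noise_field-shaped object wrapping explicit values, for mask unit tests
fake_field <- function(values, seed = 0L) {
  structure(list(values = values, scale = 1, seed = as.integer(seed), octaves = 1L),
            class = "noise_field")
}
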