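# 2D simplex (improved Perlin) gradient noise, implemented from scratch.
#
# The scheme is the standard one: skew the query point onto the simplex
# lattice, find the containing triangle's three corners, and sum per-corner
# contributions (r^2 - d^2)^4 * (gradient . distance) with r^2 = 0.5, scaled
# by a constant so the result stays inside [-1, 1].

# Skew/unskew constants for 2D.
.F2 <- 0.5 * (sqrt(3) - 1)
.G2 <- (3 - sqrt(3)) / 6

# The 12-direction 2D gradient set: (x, y) components of the twelve edge
# vectors of a cube, the gradient table of the reference simplex algorithm.
# Four directions appear twice, which is deliberate (uniform hashing mod 12).
.grad2 <- matrix(c(
   1,  1,  -1,  1,   1, -1,  -1, -1,
   1,  0,  -1,  0,   1,  0,  -1,  0,
   0,  1,   0, -1,   0,  1,   0, -1
), ncol = 2L, byrow = TRUE)

#' Build a seeded gradient permutation table
#'
#' A permutation of the integers 0-255 drawn by a Fisher-Yates shuffle under
#' R's Mersenne-Twister generator seeded with `seed` (i.e.
#' `sample.int(256) - 1` after `set.seed(seed)`). The table hashes lattice
#' corners to entries of the fixed 12-direction gradient set; identical seeds
#' give bit-identical tables.
#'
#' @param seed Integer seed.
#' @return An object of class `permutation_table` with fields `entries`
#'   (integer vector, a permutation of 0:255) and `seed`.
#' @examples
#' tab <- build_permutation(7)
#' stopifnot(identical(sort(tab$entries), 0:255))
#' @export
build_permutation <- function(seed) {
  entries <- with_seed(seed, sample.int(256L) - 1L)
  structure(list(entries = as.integer(entries), seed = as.integer(seed)),
            class = "permutation_table")
}

#' @export
print.permutation_table <- function(x, ...) {
  cat("<permutation_table> seed =", x$seed,
      "| first entries:", paste(utils::head(x$entries, 8L), collapse = " "),
      "...\n")
  invisible(x)
}

#' Sample 2D simplex noise at arbitrary coordinates
#'
#' Vectorised over `x` and `y`. Values lie in `[-1, 1]`; the function is
#' continuous in (x, y) and exactly zero whenever the skewed coordinates fall
#' on a lattice corner. The normalisation constant is the reference value 70:
#' the analytic maximum of the unscaled three-corner sum for this gradient
#' set is just above 1/70.14, so 70 keeps the empirical magnitude below 1
#' (verified over large samples in the test suite).
#'
#' @param x,y Numeric vectors of equal length (finite).
#' @param table A `permutation_table` from [build_permutation()].
#' @return Numeric vector of noise values in `[-1, 1]`.
#' @export
simplex2d <- function(x, y, table) {
  stopifnot(inherits(table, "permutation_table"))
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("simplex2d requires finite coordinates", call. = FALSE)
  }

  # skew onto the simplex lattice
  s <- (x + y) * .F2
  i <- floor(x + s)
  j <- floor(y + s)
  t <- (i + j) * .G2
  x0 <- x - (i - t)
  y0 <- y - (j - t)

  # which triangle of the skewed cell: lower (x0 > y0) or upper
  i1 <- as.numeric(x0 > y0)
  j1 <- 1 - i1

  x1 <- x0 - i1 + .G2
  y1 <- y0 - j1 + .G2
  x2 <- x0 - 1 + 2 * .G2
  y2 <- y0 - 1 + 2 * .G2

  # hash corner coordinates through the doubled permutation table
  p <- c(table$entries, table$entries)
  ii <- as.integer(i %% 256)
  jj <- as.integer(j %% 256)
  gi0 <- p[ii + p[jj + 1L] + 1L] %% 12L
  gi1 <- p[ii + as.integer(i1) + p[jj + as.integer(j1) + 1L] + 1L] %% 12L
  gi2 <- p[ii + 1L + p[jj + 2L] + 1L] %% 12L

  corner <- function(gi, dx, dy) {
    w <- 0.5 - dx * dx - dy * dy
    out <- numeric(length(w))
    pos <- w > 0
    if (any(pos)) {
      g <- .grad2[gi[pos] + 1L, , drop = FALSE]
      out[pos] <- (w[pos]^4) * (g[, 1L] * dx[pos] + g[, 2L] * dy[pos])
    }
    out
  }

  70 * (corner(gi0, x0, y0) + corner(gi1, x1, y1) + corner(gi2, x2, y2))
}

#' Generate a rectangular field of simplex noise
#'
#' Samples `simplex2d` on a pixel grid: element `[i, j]` (image row i from the
#' top, column j from the left) is evaluated at input coordinates
#' `((j-1) * scale, (i-1) * scale)`. With `octaves > 1`, octave `o`
#' (0-based) is sampled at frequency `2^o` with amplitude `2^-o` and the sum
#' is divided by the total amplitude, preserving the `[-1, 1]` bound.
#'
#' @param height,width Positive integers, field dimensions in pixels.
#' @param scale Positive real; input-space units per pixel. Small values give
#'   smoother, coarser fields. Default 0.1 gives roughly two feature periods
#'   across a 20-pixel patch.
#' @param seed Integer seed for the permutation table.
#' @param octaves Integer >= 1; number of fractal octaves (default 1).
#' @return An object of class `noise_field`: list with `values`
#'   (height x width numeric matrix in `[-1, 1]`), `scale`, `seed`, `octaves`.
#' @examples
#' f <- noise_field(20, 20, scale = 0.1, seed = 1)
#' range(f$values)  # within [-1, 1]
#' @export
noise_field <- function(height, width, scale = 0.1, seed = 0L, octaves = 1L) {
  if (height < 1 || width < 1) stop("height and width must be >= 1", call. = FALSE)
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0", call. = FALSE)
  if (octaves < 1) stop("octaves must be >= 1", call. = FALSE)
  tab <- build_permutation(seed)
  xs <- rep((seq_len(width) - 1) * scale, each = height)
  ys <- rep((seq_len(height) - 1) * scale, times = width)
  total <- numeric(height * width)
  amp_sum <- 0
  for (o in seq_len(octaves) - 1L) {
    freq <- 2^o
    amp <- 2^(-o)
    total <- total + amp * simplex2d(xs * freq, ys * freq, tab)
    amp_sum <- amp_sum + amp
  }
  values <- matrix(total / amp_sum, nrow = height, ncol = width)
  structure(list(values = values, scale = scale, seed = as.integer(seed),
                 octaves = as.integer(octaves)),
            class = "noise_field")
}

#' @export
print.noise_field <- function(x, ...) {
  cat(sprintf("<noise_field> %d x %d, scale = %g, seed = %d, octaves = %d, range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), x$scale, x$seed, x$octaves,
              min(x$values), max(x$values)))
  invisible(x)
}
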