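# Mask construction and patch-mixing augmentation, plus the conventional
# flip + Gaussian baseline.

#' Class labels of the six lung texture patterns
#'
#' Fixed integer encoding used everywhere in the package:
#' normal = 0, ggo = 1 (ground-glass opacity), consolidation = 2,
#' ro = 3 (reticular opacity), emphysema = 4, honeycombing = 5.
#'
#' @return Named integer vector of length six.
#' @export
ptex_classes <- function() {
  c(normal = 0L, ggo = 1L, consolidation = 2L,
    ro = 3L, emphysema = 4L, honeycombing = 5L)
}

#' Construct a labeled intensity patch
#'
#' @param pixels Numeric matrix (at least 2 x 2) of finite intensities,
#'   Hounsfield-unit-like.
#' @param label Class label: either an integer code 0-5 or a class name from
#'   [ptex_classes()].
#' @param id Optional identifier recorded for provenance.
#' @return An object of class `patch` with fields `pixels`, `label`, `id`.
#' @export
patch <- function(pixels, label, id = NA_character_) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("patch must be at least 2 x 2", call. = FALSE)
  }
  if (!all(is.finite(pixels))) stop("patch intensities must be finite", call. = FALSE)
  structure(list(pixels = pixels, label = as_class_code(label), id = id),
            class = "patch")
}

# coerce a class name or code to the canonical integer code 0-5
as_class_code <- function(label) {
  cls <- ptex_classes()
  if (is.character(label)) {
    if (!label %in% names(cls)) {
      stop(sprintf("unknown class name '%s'", label), call. = FALSE)
    }
    return(unname(cls[label]))
  }
  code <- as.integer(label)
  if (is.na(code) || !code %in% cls) {
    stop(sprintf("unknown class code '%s'", label), call. = FALSE)
  }
  code
}

class_name <- function(code) names(ptex_classes())[match(code, ptex_classes())]

#' @export
print.patch <- function(x, ...) {
  cat(sprintf("<patch> %d x %d, class %s (%d), mean %.1f\n",
              nrow(x$pixels), ncol(x$pixels), class_name(x$label), x$label,
              mean(x$pixels)))
  invisible(x)
}

#' Threshold a noise field into a two-region binary mask
#'
#' A pixel belongs to the `TRUE` region when its noise value is >= 0; exact
#' zeros (a measure-zero event, but it occurs at lattice corners) go to the
#' `TRUE` region by this documented tie rule. The two regions are exhaustive
#' and exclusive by construction.
#'
#' @param field A `noise_field`.
#' @return An object of class `binary_mask`: list with `region` (logical
#'   matrix) and `source_seed`.
#' @export
field_to_mask <- function(field) {
  stopifnot(inherits(field, "noise_field"))
  structure(list(region = field$values >= 0, source_seed = field$seed),
            class = "binary_mask")
}

#' Blend two labeled patches through a binary mask
#'
#' Where the mask is `TRUE` the output takes `patch_a`'s pixel and label,
#' elsewhere `patch_b`'s, yielding a mixed patch with a per-pixel label grid.
#'
#' @param patch_a,patch_b `patch` objects of identical shape.
#' @param mask A `binary_mask` of the same shape.
#' @return An object of class `aug_patch`: `pixels` (numeric matrix),
#'   `labels` (integer matrix of class codes), `provenance` (source ids and
#'   mask seed).
#' @export
perlin_blend <- function(patch_a, patch_b, mask) {
  stopifnot(inherits(patch_a, "patch"), inherits(patch_b, "patch"),
            inherits(mask, "binary_mask"))
  da <- dim(patch_a$pixels)
  if (!identical(da, dim(patch_b$pixels)) || !identical(da, dim(mask$region))) {
    stop("patch_a, patch_b and mask must share the same shape", call. = FALSE)
  }
  m <- mask$region
  pixels <- patch_b$pixels
  pixels[m] <- patch_a$pixels[m]
  labels <- matrix(patch_b$label, da[1L], da[2L])
  labels[m] <- patch_a$label
  structure(list(pixels = pixels, labels = labels,
                 provenance = list(a = patch_a$id, b = patch_b$id,
                                   mask_seed = mask$source_seed)),
            class = "aug_patch")
}

#' @export
print.aug_patch <- function(x, ...) {
  tab <- table(factor(class_name(x$labels), levels = names(ptex_classes())))
  tab <- tab[tab > 0]
  cat(sprintf("<aug_patch> %d x %d; labels: %s\n",
              nrow(x$pixels), ncol(x$pixels),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Apply a forced vertical/horizontal flip
#'
#' Deterministic helper behind [random_flip()]; flips a patch (and its label
#' grid, for augmented patches) up-down and/or left-right.
#'
#' @param x A `patch` or `aug_patch`.
#' @param flip_ud,flip_lr Logical flags.
#' @return Object of the same class as `x`.
#' @export
apply_flip <- function(x, flip_ud = FALSE, flip_lr = FALSE) {
  flip <- function(m) {
    if (flip_ud) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (flip_lr) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    m
  }
  x$pixels <- flip(x$pixels)
  if (!is.null(x$labels)) x$labels <- flip(x$labels)
  x
}

#' Randomly flip a patch up-down and left-right
#'
#' Each flip is applied with independent probability 0.5, driven by `seed`
#' (two uniform draws: first decides up-down, second left-right).
#'
#' @param x A `patch` or `aug_patch`.
#' @param seed Integer seed.
#' @return Object of the same class as `x`.
#' @export
random_flip <- function(x, seed) {
  u <- with_seed(seed, stats::runif(2L))
  apply_flip(x, flip_ud = u[1L] < 0.5, flip_lr = u[2L] < 0.5)
}

#' Add zero-mean Gaussian noise scaled to a tenth of the patch's spread
#'
#' The conventional-augmentation noise step: adds i.i.d. Normal(0, sigma^2)
#' noise with sigma equal to one tenth of the patch's own population standard
#' deviation (divisor n, not n-1, fixed for reproducibility). A constant
#' patch (sigma = 0) is returned unchanged, bit for bit.
#'
#' @param x A `patch`.
#' @param seed Integer seed.
#' @return A `patch` with the same label.
#' @export
gaussian_augment <- function(x, seed) {
  stopifnot(inherits(x, "patch"))
  v <- x$pixels
  sigma <- sqrt(mean((v - mean(v))^2)) / 10
  if (sigma == 0) return(x)
  eps <- with_seed(seed, stats::rnorm(length(v), mean = 0, sd = sigma))
  x$pixels <- v + matrix(eps, nrow(v), ncol(v))
  x
}

#' Assemble a seeded batch of augmented patches
#'
#' In `perlin` mode each batch item draws two distinct patches uniformly from
#' the pool (classes may coincide), flips each independently, generates a
#' fresh noise field, thresholds it to a mask and blends. In `conventional`
#' mode each item draws one patch, flips it and adds scaled Gaussian noise;
#' in `none` mode patches are drawn unmodified. All items are returned as
#' `aug_patch` objects (single-source items carry a uniform label grid).
#'
#' Item `i` uses seed `derive_seed(seed, i)`, with fixed sub-stream offsets
#' for the draw, the two flips and the mask, so a batch is fully reproducible
#' from `seed` alone.
#'
#' @param pool A `patch_dataset` (see [generate_dataset()]).
#' @param batch_size Integer >= 1.
#' @param mode One of `"perlin"`, `"conventional"`, `"none"`.
#' @param noise_params List with elements `scale` and `octaves` for the mask
#'   noise (perlin mode); default `list(scale = 0.1, octaves = 1)`.
#' @param seed Integer batch seed.
#' @param require_nonempty Logical; if `TRUE`, perlin-mode masks are redrawn
#'   (seed incremented) until both regions are non-empty. Default `FALSE`.
#' @return List of `batch_size` `aug_patch` objects.
#' @export
make_batch <- function(pool, batch_size, mode = c("perlin", "conventional", "none"),
                       noise_params = list(scale = 0.1, octaves = 1L),
                       seed = 0L, require_nonempty = FALSE) {
  mode <- match.arg(mode)
  n <- n_patches(pool)
  if (n < 1L) stop("pool must be non-empty", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  scale <- noise_params$scale %||% 0.1
  octaves <- noise_params$octaves %||% 1L

  lapply(seq_len(batch_size), function(i) {
    s <- derive_seed(seed, i)
    if (mode == "perlin") {
      idx <- if (n == 1L) c(1L, 1L) else with_seed(derive_seed(s, 1L), sample.int(n, 2L))
      pa <- random_flip(get_patch(pool, idx[1L]), derive_seed(s, 2L))
      pb <- random_flip(get_patch(pool, idx[2L]), derive_seed(s, 3L))
      mseed <- derive_seed(s, 4L)
      repeat {
        f <- noise_field(nrow(pa$pixels), ncol(pa$pixels),
                         scale = scale, seed = mseed, octaves = octaves)
        mask <- field_to_mask(f)
        if (!require_nonempty || (any(mask$region) && !all(mask$region))) break
        mseed <- derive_seed(mseed, 1L)
      }
      perlin_blend(pa, pb, mask)
    } else {
      idx <- with_seed(derive_seed(s, 1L), sample.int(n, 1L))
      p <- get_patch(pool, idx)
      if (mode == "conventional") {
        p <- random_flip(p, derive_seed(s, 2L))
        p <- gaussian_augment(p, derive_seed(s, 3L))
      }
      structure(list(pixels = p$pixels,
                     labels = matrix(p$label, nrow(p$pixels), ncol(p$pixels)),
                     provenance = list(a = p$id, b = p$id, mask_seed = NA_integer_)),
                class = "aug_patch")
    }
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
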