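# Synthetic six-class texture fixtures emulating HRCT lung patterns.
#
# Each class is parameterised by a base attenuation level, a speckle standard
# deviation, and a structural element (none, smooth blobs, fine lines, rings,
# low-attenuation holes). Structural contributions are centred to zero mean
# before being added, so a patch's expected mean equals the class's
# mean_intensity regardless of structure; intensities are clipped to the
# documented HU-like range [-1000, 400].

.hu_range <- c(-1000, 400)

#' Default texture specification for each class
#'
#' Reads the shipped configuration (`inst/extdata/texture-specs.yaml`) fixing
#' the per-class parameterisation: mean attenuation level (HU-like), speckle
#' standard deviation, structural element and its scale/amplitude. The
#' defaults caricature the radiological appearance of each pattern:
#' consolidation is a high uniform level, emphysema has low-attenuation
#' holes, honeycombing has walled rings, reticular opacity has fine bright
#' lines, ground-glass opacity is an intermediate hazy level, and normal is
#' low-level speckle.
#'
#' @param path Optional path to an alternative YAML specification.
#' @return Named list (one entry per class) of `texture_spec` objects.
#' @export
default_texture_specs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "texture-specs.yaml", package = "perlintex")
  }
  raw <- yaml::read_yaml(path)
  cls <- ptex_classes()
  missing <- setdiff(names(cls), names(raw))
  if (length(missing)) {
    stop("texture spec config missing classes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  specs <- lapply(names(cls), function(nm) {
    texture_spec(class = nm,
                 mean_intensity = raw[[nm]]$mean_intensity,
                 speckle_sd = raw[[nm]]$speckle_sd,
                 structure = raw[[nm]]$structure,
                 structure_scale = raw[[nm]]$structure_scale %||% 0,
                 structure_amp = raw[[nm]]$structure_amp %||% 0)
  })
  names(specs) <- names(cls)
  specs
}

#' Create a texture specification
#'
#' @param class Class name or code (see [ptex_classes()]).
#' @param mean_intensity Target patch mean, HU-like.
#' @param speckle_sd Standard deviation of the i.i.d. Gaussian speckle.
#' @param structure One of `"none"`, `"coarse_blobs"`, `"fine_lines"`,
#'   `"rings"`, `"low_attenuation_holes"`.
#' @param structure_scale Spatial scale of the structural element (noise
#'   scale for blobs/holes; approximate line period / ring radius otherwise).
#' @param structure_amp Amplitude (HU-like) of the structural element.
#' @return An object of class `texture_spec`.
#' @export
texture_spec <- function(class, mean_intensity, speckle_sd,
                         structure = c("none", "coarse_blobs", "fine_lines",
                                       "rings", "low_attenuation_holes"),
                         structure_scale = 0, structure_amp = 0) {
  structure_kind <- match.arg(structure)
  if (!is.finite(mean_intensity) || !is.finite(speckle_sd) || speckle_sd < 0) {
    stop("invalid texture spec: mean_intensity must be finite, speckle_sd >= 0",
         call. = FALSE)
  }
  structure(list(class = as_class_code(class),
                 mean_intensity = mean_intensity,
                 speckle_sd = speckle_sd,
                 structure = structure_kind,
                 structure_scale = structure_scale,
                 structure_amp = structure_amp),
            class = "texture_spec")
}

# zero-mean structural contribution for one patch
structure_delta <- function(spec, size, seed) {
  amp <- spec$structure_amp
  delta <- switch(spec$structure,
    none = matrix(0, size, size),
    coarse_blobs = {
      f <- noise_field(size, size, scale = spec$structure_scale,
                       seed = derive_seed(seed, 7L))
      amp * f$values
    },
    low_attenuation_holes = {
      f <- noise_field(size, size, scale = spec$structure_scale,
                       seed = derive_seed(seed, 7L))
      -amp * (f$values > 0.3)
    },
    fine_lines = {
      pars <- with_seed(derive_seed(seed, 7L), stats::runif(3L))
      theta <- pars[1L] * pi
      period <- 2.5 + pars[2L] * 2
      phase <- pars[3L] * 2 * pi
      rr <- row(matrix(0, size, size))
      cc <- col(matrix(0, size, size))
      v <- sin(2 * pi * (cc * cos(theta) + rr * sin(theta)) / period + phase)
      amp * (v > 0.5)
    },
    rings = {
      geom <- with_seed(derive_seed(seed, 7L), {
        k <- sample(3:5, 1L)
        list(cx = stats::runif(k, 1, size), cy = stats::runif(k, 1, size),
             r = stats::runif(k, 2.5, 5))
      })
      rr <- row(matrix(0, size, size))
      cc <- col(matrix(0, size, size))
      wall <- matrix(FALSE, size, size)
      inside <- matrix(FALSE, size, size)
      for (k in seq_along(geom$r)) {
        d <- sqrt((rr - geom$cy[k])^2 + (cc - geom$cx[k])^2)
        wall <- wall | (abs(d - geom$r[k]) <= 1)
        inside <- inside | (d < geom$r[k] - 1)
      }
      inside <- inside & !wall
      amp * wall - 120 * inside
    }
  )
  delta - mean(delta)
}

#' Generate one synthetic texture patch
#'
#' Deterministic in (spec, size, seed): pixels are
#' `mean_intensity + centred structure + Gaussian speckle`, clipped to
#' [-1000, 400]. With `speckle_sd = 0` and `structure = "none"` the patch is
#' exactly constant.
#'
#' @param spec A `texture_spec`.
#' @param size Patch side length in pixels (>= 8); default 20.
#' @param seed Integer seed.
#' @return A `patch` labeled with the spec's class.
#' @export
generate_patch <- function(spec, size = 20L, seed = 0L) {
  stopifnot(inherits(spec, "texture_spec"))
  if (size < 8L) stop("size must be >= 8", call. = FALSE)
  delta <- structure_delta(spec, size, seed)
  speckle <- if (spec$speckle_sd > 0) {
    matrix(with_seed(derive_seed(seed, 11L),
                     stats::rnorm(size * size, 0, spec$speckle_sd)), size, size)
  } else {
    matrix(0, size, size)
  }
  px <- clip_range(spec$mean_intensity + delta + speckle, .hu_range[1L], .hu_range[2L])
  patch(px, spec$class, id = sprintf("%s_seed%d", class_name(spec$class), seed))
}

#' Generate a stratified synthetic dataset
#'
#' `n_per_class` patches for each of the six classes (6 * n_per_class in
#' total, class-major order), with per-patch seeds derived from the master
#' seed by the documented counter scheme, so the whole dataset is
#' reproducible from `seed`.
#'
#' @param n_per_class Integer >= 1; the study-scale default is 100 patches
#'   per class (600 in total).
#' @param size Patch side length; default 20.
#' @param seed Integer master seed.
#' @param specs Optional list of `texture_spec` (default
#'   [default_texture_specs()]).
#' @return A `patch_dataset`.
#' @export
generate_dataset <- function(n_per_class = 100L, size = 20L, seed = 0L,
                             specs = default_texture_specs()) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  cls <- ptex_classes()
  patches <- vector("list", 6L * n_per_class)
  k <- 0L
  for (ci in seq_along(cls)) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      patches[[k]] <- generate_patch(specs[[names(cls)[ci]]], size = size,
                                     seed = derive_seed(seed, (ci - 1L) * 100003L + i))
      patches[[k]]$id <- sprintf("%s_%04d", names(cls)[ci], i)
    }
  }
  patch_dataset(patches, name = sprintf("synthetic_%dx%d_seed%d", 6L * n_per_class, size, seed))
}
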