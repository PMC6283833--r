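# Patch dataset container, stratified splitting, intensity normalisation,
# and plain-text patch archives.

#' Construct a patch dataset
#'
#' @param patches List of `patch` objects, all of the same shape.
#' @param name Optional dataset name.
#' @return An object of class `patch_dataset`.
#' @export
patch_dataset <- function(patches, name = "dataset") {
  stopifnot(is.list(patches))
  if (length(patches)) {
    stopifnot(all(vapply(patches, inherits, logical(1L), "patch")))
    d <- dim(patches[[1L]]$pixels)
    same <- vapply(patches, function(p) identical(dim(p$pixels), d), logical(1L))
    if (!all(same)) stop("all patches must share the same shape", call. = FALSE)
  }
  structure(list(patches = patches, name = name), class = "patch_dataset")
}

#' Number of patches in a dataset
#' @param data A `patch_dataset`.
#' @return Integer count.
#' @export
n_patches <- function(data) length(data$patches)

#' Extract one patch from a dataset
#' @param data A `patch_dataset`.
#' @param i Index.
#' @return A `patch`.
#' @export
get_patch <- function(data, i) data$patches[[i]]

#' Class labels of all patches
#' @param data A `patch_dataset`.
#' @return Integer vector of class codes.
#' @export
dataset_labels <- function(data) {
  vapply(data$patches, function(p) p$label, integer(1L))
}

#' @export
print.patch_dataset <- function(x, ...) {
  n <- n_patches(x)
  cat(sprintf("<patch_dataset> '%s': %d patches", x$name, n))
  if (n) {
    d <- dim(x$patches[[1L]]$pixels)
    tab <- table(factor(class_name(dataset_labels(x)), levels = names(ptex_classes())))
    cat(sprintf(" of %d x %d\n  per class: %s\n", d[1L], d[2L],
                paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  } else cat("\n")
  invisible(x)
}

#' Subset a patch dataset by index
#' @param x A `patch_dataset`.
#' @param i Integer or logical index vector.
#' @return A `patch_dataset`.
#' @export
`[.patch_dataset` <- function(x, i) {
  patch_dataset(x$patches[i], name = x$name)
}

#' Stratified train/test split
#'
#' Shuffles each class independently under `seed` and moves
#' `round(test_fraction * n_class)` patches per class into the test set.
#' Deterministic: the same seed always yields the same membership.
#'
#' @param data A `patch_dataset`.
#' @param test_fraction Real in (0, 1); default 0.2 (the 80/20 study split).
#' @param seed Integer seed.
#' @return An object of class `dataset_split`: `train`, `test`
#'   (`patch_dataset`s), `train_idx`, `test_idx`, `test_fraction`, `seed`.
#' @export
stratified_split <- function(data, test_fraction = 0.2, seed = 0L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  labels <- dataset_labels(data)
  test_idx <- integer(0)
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    n_test <- round(test_fraction * length(members))
    if (n_test < 1L) {
      stop(sprintf("class %s has too few patches (%d) for test_fraction %g",
                   class_name(cl), length(members), test_fraction), call. = FALSE)
    }
    shuffled <- with_seed(derive_seed(seed, cl), sample(members))
    test_idx <- c(test_idx, shuffled[seq_len(n_test)])
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n_patches(data)), test_idx)
  structure(list(train = data[train_idx], test = data[test_idx],
                 train_idx = train_idx, test_idx = test_idx,
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / test %d (test_fraction %g, seed %d)\n",
              n_patches(x$train), n_patches(x$test), x$test_fraction, x$seed))
  invisible(x)
}

#' Window-normalise intensities to [0, 1]
#'
#' Affine map of `[window_lo, window_hi]` onto `[0, 1]`, clipping outside the
#' window. The default window [-1000, 400] matches the synthetic generator's
#' HU-like range.
#'
#' @param x A `patch` or numeric matrix.
#' @param window_lo,window_hi Window bounds, `window_lo < window_hi`.
#' @return Same type as `x` with normalised intensities.
#' @export
normalize_window <- function(x, window_lo = -1000, window_hi = 400) {
  if (!is.finite(window_lo) || !is.finite(window_hi) || window_lo >= window_hi) {
    stop("require window_lo < window_hi", call. = FALSE)
  }
  f <- function(v) clip_range((v - window_lo) / (window_hi - window_lo), 0, 1)
  if (inherits(x, "patch")) {
    x$pixels <- f(x$pixels)
    x
  } else f(x)
}

# Archive layout: a directory with manifest.csv (columns file, class, and
# optionally label_file) plus one headerless CSV grid per patch. Intensities
# are quantized to 0.01 HU on write.

#' Write a patch dataset to a plain-text archive
#'
#' @param data A `patch_dataset`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_archive <- function(data, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- n_patches(data)
  files <- character(n)
  classes <- character(n)
  for (i in seq_len(n)) {
    p <- get_patch(data, i)
    files[i] <- sprintf("patch_%04d.csv", i)
    classes[i] <- class_name(p$label)
    utils::write.table(round(p$pixels, 2L), file.path(path, files[i]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(data.frame(file = files, class = classes,
                              stringsAsFactors = FALSE),
                   file.path(path, "manifest.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a patch dataset from an archive
#'
#' Inverse of [write_archive()]: reproduces intensities (to the 0.01 HU
#' quantization), class labels and patch order exactly. Malformed archives
#' are rejected with the offending record named.
#'
#' @param path Archive directory.
#' @return A `patch_dataset`.
#' @export
read_archive <- function(path) {
  mf <- file.path(path, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", path, call. = FALSE)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  if (!all(c("file", "class") %in% names(man))) {
    stop("manifest.csv must have columns 'file' and 'class'", call. = FALSE)
  }
  if (nrow(man) == 0L) return(patch_dataset(list(), name = basename(path)))
  patches <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(path, man$file[i])
    if (!file.exists(f)) {
      stop(sprintf("manifest record %d references missing file '%s'", i, man$file[i]),
           call. = FALSE)
    }
    if (!man$class[i] %in% names(ptex_classes())) {
      stop(sprintf("manifest record %d has unknown class '%s'", i, man$class[i]),
           call. = FALSE)
    }
    px <- as.matrix(utils::read.table(f, sep = ",", header = FALSE))
    dimnames(px) <- NULL
    patches[[i]] <- patch(px, man$class[i], id = man$file[i])
  }
  shapes <- vapply(patches, function(p) paste(dim(p$pixels), collapse = "x"), character(1L))
  if (length(unique(shapes)) > 1L) {
    bad <- which(shapes != shapes[1L])[1L]
    stop(sprintf("patch shape mismatch at record %d ('%s': %s, expected %s)",
                 bad, man$file[bad], shapes[bad], shapes[1L]), call. = FALSE)
  }
  patch_dataset(patches, name = basename(path))
}
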