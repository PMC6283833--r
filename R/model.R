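# Scaled-down encoder-decoder per-pixel classifier.
#
# The architecture family mirrors segmentation networks of the FusionNet /
# U-Net kind: an encoding path of 4x4 convolutions with optional residual
# blocks and 2x2 max-pooling, a convolutional bottleneck, and a symmetric
# decoding path of nearest-neighbour upsampling + 4x4 convolutions with
# additive skip connections from the encoder, ending in a 1x1 convolution to
# six per-pixel class logits with a softmax. Channel width doubles with each
# encoder level. Training is pixel-wise cross-entropy under Adam.

#' Model configuration
#'
#' @param depth Number of encoder/decoder levels (default 2). The input side
#'   length must be divisible by `2^depth`; if it is not, the input is
#'   reflect-padded to the next multiple and the output cropped back.
#' @param base_filters Channels at the first level (doubling per level);
#'   default 8, sized so that training runs comfortably on one CPU.
#' @param kernel_size Convolution kernel side; only the 4 used throughout
#'   the study is implemented.
#' @param n_classes Number of output classes (default 6).
#' @param use_residual Add a residual 4x4 conv block at each encoder level
#'   (default TRUE).
#' @param use_skip_connections Additive encoder-to-decoder skips (default
#'   TRUE).
#' @return An object of class `model_config`.
#' @export
model_config <- function(depth = 2L, base_filters = 8L, kernel_size = 4L,
                         n_classes = 6L, use_residual = TRUE,
                         use_skip_connections = TRUE) {
  if (kernel_size != 4L) {
    stop("only kernel_size = 4 is implemented", call. = FALSE)
  }
  if (depth < 1L || base_filters < 1L) stop("depth and base_filters must be >= 1", call. = FALSE)
  structure(list(depth = as.integer(depth), base_filters = as.integer(base_filters),
                 kernel_size = 4L, n_classes = as.integer(n_classes),
                 use_residual = isTRUE(use_residual),
                 use_skip = isTRUE(use_skip_connections)),
            class = "model_config")
}

#' Training configuration
#'
#' @param batch_size Patches per training step (default 16).
#' @param max_steps Maximum optimisation steps (default 600).
#' @param eval_interval Steps between held-out evaluations (default 25).
#' @param early_stop_patience Stop after this many evaluations without
#'   improvement (default 6).
#' @param learning_rate Adam step size (default 2e-3).
#' @param seed Integer seed driving initialisation, batch augmentation and
#'   everything else stochastic in the run.
#' @param augmentation_mode `"perlin"`, `"conventional"`, or `"none"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, max_steps = 600L, eval_interval = 25L,
                         early_stop_patience = 6L, learning_rate = 2e-3,
                         seed = 0L,
                         augmentation_mode = c("perlin", "conventional", "none")) {
  if (batch_size < 1L || early_stop_patience < 1L) {
    stop("batch_size and early_stop_patience must be >= 1", call. = FALSE)
  }
  structure(list(batch_size = as.integer(batch_size), max_steps = as.integer(max_steps),
                 eval_interval = as.integer(eval_interval),
                 early_stop_patience = as.integer(early_stop_patience),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 augmentation_mode = match.arg(augmentation_mode)),
            class = "train_config")
}

he_mat <- function(rows, cols, fan = rows) {
  matrix(stats::rnorm(rows * cols, 0, sqrt(2 / fan)), rows, cols)
}

init_params <- function(cfg, seed) {
  with_seed(seed, {
    p <- list()
    cin <- 1L
    for (e in seq_len(cfg$depth)) {
      ce <- cfg$base_filters * 2L^(e - 1L)
      p[[paste0("enc", e, "_W")]] <- he_mat(16L * cin, ce)
      p[[paste0("enc", e, "_b")]] <- numeric(ce)
      if (cfg$use_residual) {
        p[[paste0("enc", e, "_Wr")]] <- he_mat(16L * ce, ce)
        p[[paste0("enc", e, "_br")]] <- numeric(ce)
      }
      cin <- ce
    }
    cd <- cfg$base_filters * 2L^(cfg$depth - 1L)
    p$bott_W <- he_mat(16L * cd, cd)
    p$bott_b <- numeric(cd)
    cin <- cd
    for (e in rev(seq_len(cfg$depth))) {
      ce <- cfg$base_filters * 2L^(e - 1L)
      p[[paste0("dec", e, "_W")]] <- he_mat(16L * cin, ce)
      p[[paste0("dec", e, "_b")]] <- numeric(ce)
      cin <- ce
    }
    p$out_W <- he_mat(cfg$base_filters, cfg$n_classes, fan = cfg$base_filters)
    p$out_b <- numeric(cfg$n_classes)
    p
  })
}

#' Build an (untrained) per-pixel classifier
#'
#' @param config A [model_config()].
#' @param seed Seed for the He-normal weight initialisation.
#' @return An object of class `ptex_model` (fields `config`, `params`).
#' @export
build_model <- function(config = model_config(), seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  structure(list(config = config, params = init_params(config, seed)),
            class = "ptex_model")
}

#' Number of trainable parameters
#' @param model A `ptex_model` or `ptex_fit`.
#' @return Integer.
#' @export
n_parameters <- function(model) {
  if (inherits(model, "ptex_fit")) model <- model$model
  sum(vapply(model$params, length, integer(1L)))
}

#' @export
print.ptex_model <- function(x, ...) {
  cat(sprintf("<ptex_model> depth %d, base_filters %d, %s%s%d classes, %d parameters (untrained)\n",
              x$config$depth, x$config$base_filters,
              if (x$config$use_residual) "residual, " else "",
              if (x$config$use_skip) "skips, " else "",
              x$config$n_classes, n_parameters(x)))
  invisible(x)
}

# full forward pass over a flattened batch; keep = TRUE retains the caches
# needed for backpropagation
net_forward <- function(params, cfg, X, N, Hp, Wp, keep = FALSE) {
  cache <- list()
  cur <- X
  H <- Hp; W <- Wp
  E <- vector("list", cfg$depth)
  for (e in seq_len(cfg$depth)) {
    nm <- paste0("enc", e)
    c1 <- nn_conv_fwd(cur, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]], H, W, N)
    r1 <- nn_relu_fwd(c1$out)
    if (cfg$use_residual) {
      c2 <- nn_conv_fwd(r1$out, params[[paste0(nm, "_Wr")]], params[[paste0(nm, "_br")]], H, W, N)
      r2 <- nn_relu_fwd(c2$out + r1$out)
      Ee <- r2$out
    } else {
      c2 <- NULL; r2 <- NULL; Ee <- r1$out
    }
    E[[e]] <- Ee
    pl <- nn_pool_fwd(Ee, H, W, N)
    if (keep) cache[[nm]] <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2, pool = pl)
    cur <- pl$out
    H <- H %/% 2L; W <- W %/% 2L
  }
  cb <- nn_conv_fwd(cur, params$bott_W, params$bott_b, H, W, N)
  rb <- nn_relu_fwd(cb$out)
  if (keep) cache$bott <- list(c = cb, r = rb)
  cur <- rb$out
  for (e in rev(seq_len(cfg$depth))) {
    up <- nn_up_fwd(cur, H, W, N)
    H <- H * 2L; W <- W * 2L
    nm <- paste0("dec", e)
    cd <- nn_conv_fwd(up$out, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]], H, W, N)
    rd <- nn_relu_fwd(cd$out)
    cur <- rd$out
    if (cfg$use_skip) cur <- cur + E[[e]]
    if (keep) cache[[nm]] <- list(up = up, c = cd, r = rd)
  }
  logits <- cur %*% params$out_W +
    matrix(params$out_b, nrow(cur), cfg$n_classes, byrow = TRUE)
  if (keep) cache$D1 <- cur
  list(logits = logits, cache = if (keep) cache else NULL)
}

net_backward <- function(params, cfg, cache, dL) {
  g <- list()
  g$out_W <- crossprod(cache$D1, dL)
  g$out_b <- colSums(dL)
  dcur <- tcrossprod(dL, params$out_W)
  dE <- vector("list", cfg$depth)
  for (e in seq_len(cfg$depth)) {       # decoder ran depth..1, undo 1..depth
    nm <- paste0("dec", e)
    cc <- cache[[nm]]
    if (cfg$use_skip) dE[[e]] <- dcur
    drd <- nn_relu_bwd(dcur, cc$r)
    cb <- nn_conv_bwd(drd, params[[paste0(nm, "_W")]], cc$c)
    g[[paste0(nm, "_W")]] <- cb$dW
    g[[paste0(nm, "_b")]] <- cb$db
    dcur <- nn_up_bwd(cb$dX, cc$up)
  }
  drb <- nn_relu_bwd(dcur, cache$bott$r)
  cb <- nn_conv_bwd(drb, params$bott_W, cache$bott$c)
  g$bott_W <- cb$dW
  g$bott_b <- cb$db
  dcur <- cb$dX
  for (e in rev(seq_len(cfg$depth))) {
    nm <- paste0("enc", e)
    cc <- cache[[nm]]
    dEe <- nn_pool_bwd(dcur, cc$pool)
    if (!is.null(dE[[e]])) dEe <- dEe + dE[[e]]
    if (cfg$use_residual) {
      dz <- nn_relu_bwd(dEe, cc$r2)
      cbk <- nn_conv_bwd(dz, params[[paste0(nm, "_Wr")]], cc$c2)
      g[[paste0(nm, "_Wr")]] <- cbk$dW
      g[[paste0(nm, "_br")]] <- cbk$db
      dr1 <- cbk$dX + dz
    } else {
      dr1 <- dEe
    }
    dc1 <- nn_relu_bwd(dr1, cc$r1)
    cbk <- nn_conv_bwd(dc1, params[[paste0(nm, "_W")]], cc$c1)
    g[[paste0(nm, "_W")]] <- cbk$dW
    g[[paste0(nm, "_b")]] <- cbk$db
    dcur <- cbk$dX
  }
  g
}

# reflect-pad a matrix so both dimensions are multiples of k (no-op when
# they already are); returns the padded matrix and the crop offsets
pad_to_multiple <- function(m, k) {
  padded_axis <- function(n) {
    target <- as.integer(ceiling(n / k) * k)
    total <- target - n
    pre <- total %/% 2L
    post <- total - pre
    idx <- c(if (pre > 0L) (pre + 1L):2L, seq_len(n), if (post > 0L) (n - 1L):(n - post))
    list(idx = idx, pre = pre)
  }
  ra <- padded_axis(nrow(m))
  ca <- padded_axis(ncol(m))
  list(m = m[ra$idx, ca$idx, drop = FALSE], pre_r = ra$pre, pre_c = ca$pre,
       H = nrow(m), W = ncol(m))
}

# encode a list of aug_patch into (X, targets, crop-row indices)
encode_batch <- function(items, cfg, window = c(-1000, 400)) {
  N <- length(items)
  k <- 2L^cfg$depth
  first <- pad_to_multiple(items[[1L]]$pixels, k)
  Hp <- nrow(first$m); Wp <- ncol(first$m)
  H <- first$H; W <- first$W
  X <- matrix(0, N * Hp * Wp, 1L)
  targets <- integer(N * H * W)
  rr <- rep(seq_len(H) + first$pre_r, each = W)
  cc <- rep(seq_len(W) + first$pre_c, times = H)
  crop_one <- (rr - 1L) * Wp + cc
  crop_rows <- as.integer(rep(crop_one, times = N) +
                            rep((seq_len(N) - 1L) * Hp * Wp, each = H * W))
  for (n in seq_len(N)) {
    pd <- pad_to_multiple(normalize_window(items[[n]]$pixels, window[1L], window[2L]), k)
    X[((n - 1L) * Hp * Wp + 1L):(n * Hp * Wp), 1L] <- flatten_rm(pd$m)
    targets[((n - 1L) * H * W + 1L):(n * H * W)] <- flatten_rm(items[[n]]$labels)
  }
  list(X = X, targets = targets, crop_rows = crop_rows,
       N = N, Hp = Hp, Wp = Wp, H = H, W = W)
}

patch_as_item <- function(p) {
  list(pixels = p$pixels, labels = matrix(p$label, nrow(p$pixels), ncol(p$pixels)))
}

# predicted label grids for every patch of a dataset, in chunks
predict_dataset_labels <- function(params, cfg, data, chunk = 40L) {
  n <- n_patches(data)
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + chunk - 1L, n)
    items <- lapply(idx, function(j) patch_as_item(get_patch(data, j)))
    enc <- encode_batch(items, cfg)
    fw <- net_forward(params, cfg, enc$X, enc$N, enc$Hp, enc$Wp, keep = FALSE)
    P <- nn_softmax(fw$logits[enc$crop_rows, , drop = FALSE])
    lab <- max.col(P, ties.method = "first") - 1L
    for (k in seq_along(idx)) {
      v <- lab[((k - 1L) * enc$H * enc$W + 1L):(k * enc$H * enc$W)]
      out[[idx[k]]] <- unflatten_rm(v, enc$H, enc$W)
    }
    i <- i + chunk
  }
  out
}

heldout_accuracy <- function(params, cfg, test) {
  preds <- predict_dataset_labels(params, cfg, test)
  truths <- lapply(seq_len(n_patches(test)), function(i) {
    p <- get_patch(test, i)
    matrix(p$label, nrow(p$pixels), ncol(p$pixels))
  })
  pixel_accuracy(preds, truths)
}

#' Fit the per-pixel texture classifier
#'
#' Trains the encoder-decoder on seeded augmented batches drawn from the
#' training half of `split` (mode per `train_config`: Perlin patch-mixing,
#' conventional flip + Gaussian, or none), evaluating held-out pixel accuracy
#' on the untouched test half every `eval_interval` steps. Training stops
#' when the held-out accuracy has not improved for `early_stop_patience`
#' evaluations or at `max_steps`, and the parameters of the best evaluation
#' are returned. Fully reproducible from the seeds; a non-finite loss aborts
#' with the offending step index.
#'
#' @param split A [stratified_split()] result.
#' @param model_config A [model_config()].
#' @param train_config A [train_config()].
#' @param noise_params Mask-noise parameters for perlin mode
#'   (`list(scale, octaves)`).
#' @return An object of class `ptex_fit`: the best `model`, a `history`
#'   data frame (step, loss, and held-out accuracy at evaluation steps),
#'   `best_accuracy`, and the configurations.
#' @export
ptex_train <- function(split, model_config = perlintex::model_config(),
                       train_config = perlintex::train_config(),
                       noise_params = list(scale = 0.1, octaves = 1L)) {
  stopifnot(inherits(split, "dataset_split"))
  if (n_patches(split$train) == 0L || n_patches(split$test) == 0L) {
    stop("split must have non-empty train and test sets", call. = FALSE)
  }
  cfg <- model_config
  tc <- train_config
  params <- init_params(cfg, derive_seed(tc$seed, 0L))

  history <- data.frame(step = integer(0), loss = numeric(0),
                        heldout_accuracy = numeric(0))
  if (tc$max_steps == 0L) {
    return(structure(list(model = structure(list(config = cfg, params = params),
                                            class = "ptex_model"),
                          history = history, best_accuracy = NA_real_,
                          model_config = cfg, train_config = tc,
                          noise_params = noise_params),
                     class = "ptex_fit"))
  }

  opt_m <- lapply(params, function(p) p * 0)
  opt_v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best_acc <- -Inf
  best_params <- params
  evals_since_best <- 0L

  for (step in seq_len(tc$max_steps)) {
    batch <- make_batch(split$train, tc$batch_size, mode = tc$augmentation_mode,
                        noise_params = noise_params,
                        seed = derive_seed(tc$seed, step))
    enc <- encode_batch(batch, cfg)
    fw <- net_forward(params, cfg, enc$X, enc$N, enc$Hp, enc$Wp, keep = TRUE)
    ce <- nn_softmax_ce(fw$logits, enc$crop_rows, enc$targets)
    if (!is.finite(ce$loss)) {
      stop(sprintf("training diverged (non-finite loss) at step %d", step), call. = FALSE)
    }
    g <- net_backward(params, cfg, fw$cache, ce$dL)
    for (nm in names(params)) {
      opt_m[[nm]] <- b1 * opt_m[[nm]] + (1 - b1) * g[[nm]]
      opt_v[[nm]] <- b2 * opt_v[[nm]] + (1 - b2) * g[[nm]]^2
      mhat <- opt_m[[nm]] / (1 - b1^step)
      vhat <- opt_v[[nm]] / (1 - b2^step)
      params[[nm]] <- params[[nm]] - tc$learning_rate * mhat / (sqrt(vhat) + eps)
    }
    acc <- NA_real_
    if (step %% tc$eval_interval == 0L || step == tc$max_steps) {
      acc <- heldout_accuracy(params, cfg, split$test)
      if (acc > best_acc) {
        best_acc <- acc
        best_params <- params
        evals_since_best <- 0L
      } else {
        evals_since_best <- evals_since_best + 1L
      }
    }
    history <- rbind(history, data.frame(step = step, loss = ce$loss,
                                         heldout_accuracy = acc))
    if (evals_since_best >= tc$early_stop_patience) break
  }

  structure(list(model = structure(list(config = cfg, params = best_params),
                                   class = "ptex_model"),
                 history = history, best_accuracy = best_acc,
                 model_config = cfg, train_config = tc,
                 noise_params = noise_params),
            class = "ptex_fit")
}

#' Predict per-pixel labels and probabilities
#'
#' @param object A `ptex_fit` (or `ptex_model` via [predict_patch()]).
#' @param newdata A `patch`, numeric matrix, or `patch_dataset`.
#' @param ... Unused.
#' @return For a single patch: list with `labels` (integer matrix, argmax
#'   with ties broken towards the lowest class index) and `probs`
#'   (H x W x n_classes array, each pixel summing to 1). For a dataset: a
#'   list of such results.
#' @export
predict.ptex_fit <- function(object, newdata, ...) {
  predict_patch(object$model, newdata)
}

#' @rdname predict.ptex_fit
#' @param model A `ptex_model`.
#' @export
predict_patch <- function(model, newdata) {
  stopifnot(inherits(model, "ptex_model"))
  if (inherits(newdata, "patch_dataset")) {
    return(lapply(seq_len(n_patches(newdata)),
                  function(i) predict_patch(model, get_patch(newdata, i))))
  }
  px <- if (inherits(newdata, "patch")) newdata$pixels else as.matrix(newdata)
  cfg <- model$config
  item <- list(pixels = px, labels = matrix(0L, nrow(px), ncol(px)))
  enc <- encode_batch(list(item), cfg)
  fw <- net_forward(model$params, cfg, enc$X, 1L, enc$Hp, enc$Wp, keep = FALSE)
  P <- nn_softmax(fw$logits[enc$crop_rows, , drop = FALSE])
  H <- enc$H; W <- enc$W
  labels <- unflatten_rm(max.col(P, ties.method = "first") - 1L, H, W)
  probs <- array(0, c(H, W, cfg$n_classes))
  for (k in seq_len(cfg$n_classes)) probs[, , k] <- unflatten_rm(P[, k], H, W)
  list(labels = labels, probs = probs)
}

#' @export
print.ptex_fit <- function(x, ...) {
  cat(sprintf("<ptex_fit> %s augmentation, %d steps, best held-out pixel accuracy %.1f%%\n",
              x$train_config$augmentation_mode, nrow(x$history),
              x$best_accuracy))
  invisible(x)
}

#' @export
summary.ptex_fit <- function(object, ...) {
  ev <- object$history[!is.na(object$history$heldout_accuracy), ]
  out <- list(augmentation_mode = object$train_config$augmentation_mode,
              steps_run = nrow(object$history),
              n_parameters = n_parameters(object$model),
              best_accuracy = object$best_accuracy,
              final_loss = utils::tail(object$history$loss, 1L),
              evaluations = ev)
  class(out) <- "summary.ptex_fit"
  out
}

#' @export
print.summary.ptex_fit <- function(x, ...) {
  cat(sprintf("Per-pixel texture classifier (%s augmentation)\n", x$augmentation_mode))
  cat(sprintf("  parameters: %d | steps run: %d | final loss: %.4f\n",
              x$n_parameters, x$steps_run, x$final_loss))
  cat(sprintf("  best held-out pixel accuracy: %.2f%%\n", x$best_accuracy))
  if (nrow(x$evaluations)) {
    cat("  evaluations:\n")
    print(x$evaluations[, c("step", "loss", "heldout_accuracy")], row.names = FALSE)
  }
  invisible(x)
}

#' Plot training history
#'
#' Loss per step and held-out pixel accuracy at evaluation steps.
#'
#' @param x A `ptex_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.ptex_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$step, h$loss, type = "l", xlab = "step", ylab = "training loss", ...)
  ev <- h[!is.na(h$heldout_accuracy), ]
  plot(ev$step, ev$heldout_accuracy, type = "b", xlab = "step",
       ylab = "held-out pixel accuracy (%)", ...)
  invisible(x)
}
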