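# Minimal CNN primitives in base R matrix algebra.
#
# An activation tensor of shape (N, H, W, C) is stored as a (N*H*W) x C
# matrix whose rows are ordered batch-major, then row-major within an image:
# row = (n-1)*H*W + (r-1)*W + c. `flatten_rm()`/`unflatten_rm()` convert an
# R matrix (column-major) to and from this row-major layout.
#
# Convolutions are 4 x 4, stride 1, "same" output size with zero padding of
# 1 pixel before and 2 after in each dimension (kernel offsets -1..2).
# Gather/scatter index vectors depend only on (H, W, N) and are cached.

flatten_rm <- function(m) as.vector(t(m))
unflatten_rm <- function(v, H, W) matrix(v, H, W, byrow = TRUE)

.nn_idx_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, build) {
  if (!exists(key, envir = .nn_idx_cache, inherits = FALSE)) {
    assign(key, build(), envir = .nn_idx_cache)
  }
  get(key, envir = .nn_idx_cache, inherits = FALSE)
}

# 16 gather index vectors (one per kernel offset, dy outer over -1..2,
# dx inner); index N*H*W + 1 marks the shared zero (padding) row.
conv_indices <- function(H, W, N) {
  .cache_get(sprintf("conv_%d_%d_%d", H, W, N), function() {
    HW <- H * W
    zero_row <- N * HW + 1L
    rr <- rep(seq_len(H), each = W)
    cc <- rep(seq_len(W), times = H)
    base <- rep((seq_len(N) - 1L) * HW, each = HW)
    out <- vector("list", 16L)
    b <- 0L
    for (dy in -1:2) for (dx in -1:2) {
      b <- b + 1L
      rs <- rr + dy
      cs <- cc + dx
      valid <- rs >= 1L & rs <= H & cs >= 1L & cs <= W
      sidx <- ifelse(valid, (rs - 1L) * W + cs, NA_integer_)
      full <- rep(sidx, times = N) + base
      full[is.na(full)] <- zero_row
      out[[b]] <- as.integer(full)
    }
    out
  })
}

# 2x2 max-pool gather indices: 4 vectors mapping each output row to the
# input row of one pool-window corner.
pool_indices <- function(H, W, N) {
  .cache_get(sprintf("pool_%d_%d_%d", H, W, N), function() {
    Ho <- H %/% 2L; Wo <- W %/% 2L
    ro <- rep(seq_len(Ho), each = Wo)
    co <- rep(seq_len(Wo), times = Ho)
    base <- rep((seq_len(N) - 1L) * H * W, each = Ho * Wo)
    lapply(list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)), function(d) {
      as.integer(rep((2L * ro - 2L + d[1L]) * W + (2L * co - 1L + d[2L]), times = N) + base)
    })
  })
}

# nearest-neighbour 2x upsampling: output row -> source input row
upsample_indices <- function(H, W, N) {
  .cache_get(sprintf("up_%d_%d_%d", H, W, N), function() {
    Ho <- 2L * H; Wo <- 2L * W
    ro <- rep(seq_len(Ho), each = Wo)
    co <- rep(seq_len(Wo), times = Ho)
    base <- rep((seq_len(N) - 1L) * H * W, each = Ho * Wo)
    as.integer(rep(((ro + 1L) %/% 2L - 1L) * W + (co + 1L) %/% 2L, times = N) + base)
  })
}

nn_conv_fwd <- function(X, Wm, b, H, W, N) {
  Cin <- ncol(X)
  ix <- conv_indices(H, W, N)
  Xz <- rbind(X, 0)
  Xcol <- matrix(0, nrow(X), 16L * Cin)
  for (k in 1:16) {
    Xcol[, ((k - 1L) * Cin + 1L):(k * Cin)] <- Xz[ix[[k]], , drop = FALSE]
  }
  out <- Xcol %*% Wm
  out <- out + matrix(b, nrow(out), length(b), byrow = TRUE)
  list(out = out, Xcol = Xcol, H = H, W = W, N = N, Cin = Cin)
}

nn_conv_bwd <- function(dOut, Wm, cache) {
  Cin <- cache$Cin
  ix <- conv_indices(cache$H, cache$W, cache$N)
  dW <- crossprod(cache$Xcol, dOut)
  db <- colSums(dOut)
  dXcol <- tcrossprod(dOut, Wm)
  dXz <- matrix(0, nrow(dOut) + 1L, Cin)
  for (k in 1:16) {
    blk <- dXcol[, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
    rows <- ix[[k]]
    # within one offset the target->source map is injective except for the
    # shared padding row, whose accumulated value is discarded
    keep <- rows <= nrow(dOut)
    dXz[rows[keep], ] <- dXz[rows[keep], , drop = FALSE] + blk[keep, , drop = FALSE]
  }
  list(dX = dXz[-nrow(dXz), , drop = FALSE], dW = dW, db = db)
}

nn_pool_fwd <- function(X, H, W, N) {
  ix <- pool_indices(H, W, N)
  a <- lapply(ix, function(i) X[i, , drop = FALSE])
  m <- pmax(a[[1L]], a[[2L]], a[[3L]], a[[4L]])
  # first-corner-wins tie rule
  taken <- matrix(FALSE, nrow(m), ncol(m))
  sel <- vector("list", 4L)
  for (k in 1:4) {
    sk <- (a[[k]] == m) & !taken
    taken <- taken | sk
    sel[[k]] <- sk
  }
  list(out = m, sel = sel, ix = ix, H = H, W = W, N = N)
}

nn_pool_bwd <- function(dOut, cache) {
  dX <- matrix(0, cache$N * cache$H * cache$W, ncol(dOut))
  for (k in 1:4) {
    dX[cache$ix[[k]], ] <- dOut * cache$sel[[k]]
  }
  dX
}

nn_up_fwd <- function(X, H, W, N) {
  ix <- upsample_indices(H, W, N)
  list(out = X[ix, , drop = FALSE], ix = ix, n_in = nrow(X))
}

nn_up_bwd <- function(dOut, cache) {
  # every input row appears in the index, so rowsum's sorted groups restore
  # the original row order
  unname(rowsum(dOut, cache$ix))
}

nn_relu_fwd <- function(X) list(out = pmax(X, 0), pos = X > 0)
nn_relu_bwd <- function(dOut, cache) dOut * cache$pos

# row-wise softmax
nn_softmax <- function(L) {
  m <- L - apply(L, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# cross-entropy loss and logit gradient over a subset of rows.
# `rows` are the contributing row indices, `targets` 0-based class codes.
nn_softmax_ce <- function(L, rows, targets) {
  P <- nn_softmax(L)
  n <- length(rows)
  pick <- cbind(rows, targets + 1L)
  loss <- -mean(log(pmax(P[pick], 1e-12)))
  dL <- matrix(0, nrow(L), ncol(L))
  G <- P[rows, , drop = FALSE]
  G[cbind(seq_len(n), targets + 1L)] <- G[cbind(seq_len(n), targets + 1L)] - 1
  dL[rows, ] <- G / n
  list(loss = loss, dL = dL, P = P)
}
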