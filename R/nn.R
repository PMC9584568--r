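# Minimal 1-D convolutional network machinery on segmented sequences.
#
# Activations are dense matrices (channels x total_length) where the
# columns concatenate independent segments (epochs for the per-epoch
# encoder, subjects for the sequence stage). Convolutions are 'same',
# centered, dilation-aware, and never bleed across segment boundaries:
# out-of-segment taps read zeros. Backprop is hand-written per primitive.
# 1x1 convolutions take a copy-free fast path; wider kernels share
# shifted-input dictionaries across parallel (inception) branches.

# column map for a tap offset: idx = source column per target column,
# bad = target columns whose source falls outside the segment
.seg_shift_map <- function(seg, off) {
  L <- sum(seg)
  segid <- rep.int(seq_along(seg), seg)
  seg_start <- cumsum(c(0L, seg))[segid]
  lpos <- seq_len(L) - seg_start
  src <- lpos + off
  bad <- which(src < 1L | src > seg[segid])
  idx <- seq_len(L) + off
  idx[bad] <- 1L
  list(idx = idx, bad = bad)
}

.shift_mat <- function(X, map) {
  Y <- X[, map$idx, drop = FALSE]
  if (length(map$bad)) Y[, map$bad] <- 0
  Y
}

# build the dictionary of shifted copies of X for a set of offsets
.shift_dict <- function(X, offs, seg) {
  offs <- setdiff(unique(offs), 0L)
  d <- lapply(offs, function(o) .shift_mat(X, .seg_shift_map(seg, o)))
  names(d) <- as.character(offs)
  d
}

.get_shift <- function(X, off, seg, dict) {
  if (off == 0L) return(X)
  key <- as.character(off)
  if (!is.null(dict) && !is.null(dict[[key]])) return(dict[[key]])
  .shift_mat(X, .seg_shift_map(seg, off))
}

# W: list of k matrices (cout x cin); returns list(Y, cache)
.conv_fwd <- function(X, W, b, dil, seg, dict = NULL) {
  k <- length(W)
  if (k == 1L) {
    Y <- W[[1]] %*% X + b
    return(list(Y = Y, cache = list(X = X, W = W, offs = 0L, seg = seg)))
  }
  offs <- as.integer(dil * (seq_len(k) - (k + 1L) / 2L))
  Y <- matrix(b, nrow = length(b), ncol = ncol(X))
  for (j in seq_len(k)) {
    Y <- Y + W[[j]] %*% .get_shift(X, offs[j], seg, dict)
  }
  list(Y = Y, cache = list(X = X, W = W, offs = offs, seg = seg))
}

# dict, when given, must hold shifted copies of cache$X for cache$offs
.conv_bwd <- function(dY, cache, dict = NULL, need_dx = TRUE) {
  X <- cache$X; W <- cache$W; offs <- cache$offs
  k <- length(W)
  db <- rowSums(dY)
  if (k == 1L) {
    dW <- list(tcrossprod(dY, X))
    dX <- if (need_dx) crossprod(W[[1]], dY) else NULL
    return(list(dX = dX, dW = dW, db = db))
  }
  dW <- vector("list", k)
  dX <- if (need_dx) matrix(0, nrow(X), ncol(X)) else NULL
  for (j in seq_len(k)) {
    Xs <- .get_shift(X, offs[j], seg = cache$seg, dict = dict)
    dW[[j]] <- tcrossprod(dY, Xs)
    if (need_dx) {
      Z <- crossprod(W[[j]], dY)
      if (offs[j] == 0L) {
        dX <- dX + Z
      } else {
        dX <- dX + .shift_mat(Z, .seg_shift_map(cache$seg, -offs[j]))
      }
    }
  }
  list(dX = dX, dW = dW, db = db)
}

.relu_fwd <- function(X) {
  mask <- X > 0
  list(Y = X * mask, mask = mask)
}

.relu_bwd <- function(dY, mask) dY * mask

# mean-pool each fixed-length segment of T columns down to one column
.pool_fwd <- function(X, T_len) {
  N <- ncol(X) / T_len
  grp <- rep(seq_len(N), each = T_len)
  Y <- t(rowsum(t(X), grp)) / T_len
  list(Y = Y, T_len = T_len, N = N)
}

.pool_bwd <- function(dY, cache) {
  dY[, rep(seq_len(cache$N), each = cache$T_len), drop = FALSE] / cache$T_len
}

.softmax <- function(A) {
  A <- sweep(A, 2, apply(A, 2, max))
  E <- exp(A)
  sweep(E, 2, colSums(E), "/")
}

# backward through softmax: given s and upstream ds, return da
.softmax_bwd <- function(ds, s) {
  s * sweep(ds, 2, colSums(ds * s))
}

# weighted cross-entropy over columns; y integer class per column.
# Returns loss and dlogits (normalized by total weight).
.ce_loss <- function(logits, y, class_weights = NULL) {
  K <- nrow(logits); N <- ncol(logits)
  if (is.null(class_weights)) class_weights <- rep(1, K)
  p <- .softmax(logits)
  wy <- class_weights[y]
  pick <- cbind(y, seq_len(N))      # (row=class, col=obs) index pairs
  py <- p[pick]
  tot <- sum(wy)
  loss <- -sum(wy * log(pmax(py, 1e-12))) / tot
  G <- sweep(p, 2, wy, "*")
  G[pick] <- G[pick] - wy
  list(loss = loss, dlogits = G / tot, probs = p)
}

# ---- parameter-tree helpers ----------------------------------------------

.init_conv <- function(cin, cout, k) {
  sd <- sqrt(2 / (cin * k))
  list(W = lapply(seq_len(k), function(j) {
    matrix(stats::rnorm(cout * cin, sd = sd), cout, cin)
  }), b = rep(0, cout))
}

.par_count <- function(p) {
  if (is.list(p)) return(sum(vapply(p, .par_count, 0)))
  length(p)
}

.tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
    out <- mapply(.tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

.tree_zero <- function(p) {
  if (is.list(p)) return(lapply(p, .tree_zero))
  p * 0
}

# one Adam step over a parameter tree; state holds m, v trees and t
.adam_step <- function(par, grad, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  if (is.null(state)) {
    state <- list(m = .tree_zero(par), v = .tree_zero(par), t = 0)
  }
  state$t <- state$t + 1
  state$m <- .tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grad)
  state$v <- .tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grad)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- .tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  par <- .tree_map2(`-`, par, upd)
  list(par = par, state = state)
}
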