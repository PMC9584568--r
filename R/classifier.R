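#' Staging network configuration
#'
#' The two-stage temporal-convolutional sleep stager. Stage 1 is a
#' per-epoch encoder: parallel-kernel (inception) convolution blocks with
#' residual connections over the 4 Hz within-epoch input, mean-pooled to
#' an embedding, with an auxiliary 4-class head. Stage 2 refines the
#' sequence of epoch embeddings (concatenated with the auxiliary
#' probabilities) with dilated residual temporal convolutions whose
#' receptive field spans more than half an hour of epochs, then emits the
#' per-epoch 4-class posteriors.
#'
#' The default widths are calibrated via the closed-form parameter-count
#' formula ([staging_param_counts()], solved by
#' [calibrate_staging_widths()]) so that the two stages hold exactly
#' 492,420 and 538,796 trainable parameters (1,031,216 in total).
#'
#' @param width_multiplier Scales all widths (stem, branch, embedding,
#'   stage-2 width, head); use < 1 for desk-scale training.
#' @param stage1 List: `kernels` (inception kernel sizes, odd),
#'   `n_blocks`, `stem_width`, `branch_width`, `embedding_dim`.
#' @param stage2 List: `dilations`, `width`, `head_hidden`.
#' @param c_in Number of input channels (see [assemble_inputs()]).
#' @param seed Integer seed for weight initialization.
#' @param training List of training defaults: `iters`, `lr`,
#'   `aux_weight` (auxiliary-head loss weight), `class_weights`
#'   (`NULL` = uniform, `"balanced"` = inverse training frequency, or a
#'   4-vector).
#' @return A list of class `"staging_config"`.
#' @export
staging_config <- function(width_multiplier = 1,
                           stage1 = list(kernels = c(3, 5, 7), n_blocks = 3,
                                         stem_width = 88, branch_width = 101,
                                         embedding_dim = 111),
                           stage2 = list(dilations = c(1, 2, 4, 8, 16, 32),
                                         width = 119, head_hidden = 111),
                           c_in = 10, seed = 1,
                           training = list(iters = 60, lr = 1e-3,
                                           aux_weight = 0.3,
                                           class_weights = NULL)) {
  sc <- function(x) max(1L, as.integer(round(x * width_multiplier)))
  stage1$stem_width <- sc(stage1$stem_width)
  stage1$branch_width <- sc(stage1$branch_width)
  stage1$embedding_dim <- sc(stage1$embedding_dim)
  stage2$width <- sc(stage2$width)
  stage2$head_hidden <- sc(stage2$head_hidden)
  if (any(stage1$kernels %% 2 == 0)) stop("inception kernels must be odd")
  if (max(stage2$dilations) < 1) stop("receptive field must cover >= 1 epoch")
  structure(list(stage1 = stage1, stage2 = stage2, n_classes = 4L,
                 c_in = as.integer(c_in), seed = as.integer(seed),
                 width_multiplier = width_multiplier, training = training),
            class = "staging_config")
}

#' Closed-form trainable-parameter counts of a staging configuration
#'
#' Every layer is a biased convolution with `cout * (cin * k + 1)`
#' parameters; the formula sums them per stage. [build_model()] verifies
#' the formula against a brute-force enumeration of the instantiated
#' weight tensors.
#'
#' @param cfg A [staging_config()].
#' @return `list(stage1 =, stage2 =, total =)`.
#' @export
staging_param_counts <- function(cfg) {
  cc <- function(cin, cout, k) cout * (cin * k + 1)
  s1 <- cfg$stage1; s2 <- cfg$stage2
  w1 <- s1$stem_width; b <- s1$branch_width; E <- s1$embedding_dim
  nk <- length(s1$kernels)
  block1 <- sum(vapply(s1$kernels, function(k) cc(w1, b, k), 0)) +
    cc(nk * b, w1, 1)
  n1 <- cc(cfg$c_in, w1, 1) + s1$n_blocks * block1 + cc(w1, E, 1) +
    cc(E, cfg$n_classes, 1)
  w2 <- s2$width; h <- s2$head_hidden
  n2 <- cc(E + cfg$n_classes, w2, 1) +
    length(s2$dilations) * 2 * cc(w2, w2, 3) +
    cc(w2, h, 1) + cc(h, cfg$n_classes, 1)
  list(stage1 = n1, stage2 = n2, total = n1 + n2)
}

#' Solve layer widths for target parameter counts
#'
#' Integer search over (stem width, branch width, embedding dim) and
#' (stage-2 width, head hidden) so that [staging_param_counts()] hits the
#' two stage targets exactly. Errors, reporting the nearest achievable
#' counts, when no exact solution exists in the search ranges.
#'
#' @param target_stage1,target_stage2 Target trainable-parameter counts.
#' @param c_in Input channels.
#' @param kernels,n_blocks Stage-1 structure.
#' @param n_dilations Number of stage-2 residual blocks.
#' @return A [staging_config()] whose counts match the targets.
#' @export
calibrate_staging_widths <- function(target_stage1 = 492420,
                                     target_stage2 = 538796,
                                     c_in = 10, kernels = c(3, 5, 7),
                                     n_blocks = 3, n_dilations = 6) {
  nk <- length(kernels); sk <- sum(kernels)
  best <- NULL; best_gap <- Inf
  for (w2 in 60:150) {
    base2 <- n_dilations * 2 * (3 * w2^2 + w2) + 4
    for (E in 8:256) {
      r <- target_stage2 - base2 - w2 * (E + 5)
      if (r < 4 * (w2 + 5)) next
      h <- r / (w2 + 5)
      gap2 <- abs(r - round(h) * (w2 + 5))
      for (w1 in 16:256) {
        A <- w1 * (c_in + 1) + n_blocks * w1 + E * (w1 + 1) + 4 * E + 4
        B <- n_blocks * (w1 * sk + nk + nk * w1)
        num <- target_stage1 - A
        if (num < 4 * B) next
        b <- num / B
        gap1 <- abs(num - round(b) * B)
        gap <- gap1 + gap2
        if (gap < best_gap) {
          best_gap <- gap
          best <- list(w1 = w1, b = as.integer(round(b)), E = E,
                       w2 = w2, h = as.integer(round(h)))
        }
        if (gap == 0 && h == round(h) && b == round(b)) {
          cfg <- staging_config(
            stage1 = list(kernels = kernels, n_blocks = n_blocks,
                          stem_width = w1, branch_width = as.integer(b),
                          embedding_dim = E),
            stage2 = list(dilations = 2^(seq_len(n_dilations) - 1),
                          width = w2, head_hidden = as.integer(h)),
            c_in = c_in)
          return(cfg)
        }
      }
    }
  }
  near <- staging_param_counts(staging_config(
    stage1 = list(kernels = kernels, n_blocks = n_blocks,
                  stem_width = best$w1, branch_width = best$b,
                  embedding_dim = best$E),
    stage2 = list(dilations = 2^(seq_len(n_dilations) - 1),
                  width = best$w2, head_hidden = best$h),
    c_in = c_in))
  stop("no exact width calibration found; nearest achievable counts: ",
       "stage1 = ", near$stage1, ", stage2 = ", near$stage2)
}

#' Build (initialize) the staging network
#'
#' Weight initialization is deterministic given `cfg$seed`. The reported
#' parameter counts are computed both by the closed-form formula and by
#' enumerating the instantiated weight tensors; the two must agree.
#'
#' @param cfg A [staging_config()].
#' @return A list of class `"staging_model"` with `par` (weights),
#'   `config`, `param_count_stage1`, `param_count_stage2`,
#'   `param_count_total`, `trained`.
#' @export
build_model <- function(cfg = staging_config()) {
  stopifnot(inherits(cfg, "staging_config"))
  set.seed(cfg$seed)
  s1 <- cfg$stage1; s2 <- cfg$stage2
  w1 <- s1$stem_width; bw <- s1$branch_width; E <- s1$embedding_dim
  par <- list(
    s1 = list(
      stem = .init_conv(cfg$c_in, w1, 1),
      blocks = lapply(seq_len(s1$n_blocks), function(i) {
        list(br = lapply(s1$kernels, function(k) .init_conv(w1, bw, k)),
             proj = .init_conv(length(s1$kernels) * bw, w1, 1))
      }),
      emb = .init_conv(w1, E, 1),
      aux = .init_conv(E, cfg$n_classes, 1)
    ),
    s2 = list(
      stem = .init_conv(E + cfg$n_classes, s2$width, 1),
      blocks = lapply(s2$dilations, function(d) {
        list(c1 = .init_conv(s2$width, s2$width, 3),
             c2 = .init_conv(s2$width, s2$width, 3))
      }),
      head = .init_conv(s2$width, s2$head_hidden, 1),
      out = .init_conv(s2$head_hidden, cfg$n_classes, 1)
    )
  )
  counts <- staging_param_counts(cfg)
  n1 <- .par_count(par$s1); n2 <- .par_count(par$s2)
  if (n1 != counts$stage1 || n2 != counts$stage2) {
    stop("parameter-count formula does not match instantiated weights (",
         n1, "/", counts$stage1, ", ", n2, "/", counts$stage2, ")")
  }
  structure(list(par = par, config = cfg,
                 param_count_stage1 = counts$stage1,
                 param_count_stage2 = counts$stage2,
                 param_count_total = counts$total,
                 trained = FALSE, history = NULL),
            class = "staging_model")
}

#' @export
print.staging_model <- function(x, ...) {
  cat(sprintf(
    "<staging_model> stage1 %s params, stage2 %s params, total %s (%s)\n",
    format(x$param_count_stage1, big.mark = ","),
    format(x$param_count_stage2, big.mark = ","),
    format(x$param_count_total, big.mark = ","),
    if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- forward / backward ---------------------------------------------------

# X: c_in x (T_len * n_epochs); seg2: epochs per subject (sums to n_epochs)
.model_forward <- function(par, cfg, X, T_len, seg2) {
  N <- ncol(X) / T_len
  seg1 <- rep(T_len, N)
  cache <- list()
  cv <- .conv_fwd(X, par$s1$stem$W, par$s1$stem$b, 1, seg1)
  r <- .relu_fwd(cv$Y)
  cache$stem <- list(conv = cv$cache, mask = r$mask)
  h <- r$Y
  max_k <- max(vapply(par$s1$blocks[[1]]$br, function(x) length(x$W), 0L))
  br_offs <- seq_len(max_k) - (max_k + 1L) %/% 2L
  cache$blocks1 <- vector("list", length(par$s1$blocks))
  for (i in seq_along(par$s1$blocks)) {
    blk <- par$s1$blocks[[i]]
    dict <- .shift_dict(h, br_offs, seg1)
    brs <- lapply(seq_along(blk$br), function(j) {
      .conv_fwd(h, blk$br[[j]]$W, blk$br[[j]]$b, 1, seg1, dict = dict)
    })
    Z <- do.call(rbind, lapply(brs, `[[`, "Y"))
    zr <- .relu_fwd(Z)
    pj <- .conv_fwd(zr$Y, blk$proj$W, blk$proj$b, 1, seg1)
    out <- .relu_fwd(h + pj$Y)
    cache$blocks1[[i]] <- list(brs = lapply(brs, `[[`, "cache"),
                               zmask = zr$mask, proj = pj$cache,
                               omask = out$mask,
                               rows = nrow(brs[[1]]$Y))
    h <- out$Y
  }
  pool <- .pool_fwd(h, T_len)
  segN <- rep(1L, N)
  emb <- .conv_fwd(pool$Y, par$s1$emb$W, par$s1$emb$b, 1, segN)
  er <- .relu_fwd(emb$Y)
  aux <- .conv_fwd(er$Y, par$s1$aux$W, par$s1$aux$b, 1, segN)
  auxp <- .softmax(aux$Y)
  cache$pool <- pool; cache$emb <- emb$cache; cache$emask <- er$mask
  cache$aux <- aux$cache; cache$auxp <- auxp

  X2 <- rbind(er$Y, auxp)
  cv2 <- .conv_fwd(X2, par$s2$stem$W, par$s2$stem$b, 1, seg2)
  r2 <- .relu_fwd(cv2$Y)
  cache$stem2 <- list(conv = cv2$cache, mask = r2$mask)
  g <- r2$Y
  cache$blocks2 <- vector("list", length(par$s2$blocks))
  for (i in seq_along(par$s2$blocks)) {
    blk <- par$s2$blocks[[i]]
    d <- cfg$stage2$dilations[i]
    c1 <- .conv_fwd(g, blk$c1$W, blk$c1$b, d, seg2)
    u1 <- .relu_fwd(c1$Y)
    c2 <- .conv_fwd(u1$Y, blk$c2$W, blk$c2$b, d, seg2)
    out <- .relu_fwd(g + c2$Y)
    cache$blocks2[[i]] <- list(c1 = c1$cache, m1 = u1$mask, c2 = c2$cache,
                               omask = out$mask)
    g <- out$Y
  }
  hh <- .conv_fwd(g, par$s2$head$W, par$s2$head$b, 1, seg2)
  hr <- .relu_fwd(hh$Y)
  logits <- .conv_fwd(hr$Y, par$s2$out$W, par$s2$out$b, 1, seg2)
  cache$head <- hh$cache; cache$hmask <- hr$mask; cache$out <- logits$cache
  list(logits = logits$Y, aux_logits = aux$Y, cache = cache)
}

# full backward pass; returns gradient tree mirroring par
.model_backward <- function(par, cfg, fwd, dlogits, daux_ce) {
  ca <- fwd$cache
  g <- list(s1 = list(), s2 = list())

  bo <- .conv_bwd(dlogits, ca$out)
  g$s2$out <- list(W = bo$dW, b = bo$db)
  dhr <- .relu_bwd(bo$dX, ca$hmask)
  bh <- .conv_bwd(dhr, ca$head)
  g$s2$head <- list(W = bh$dW, b = bh$db)
  dg <- bh$dX
  g$s2$blocks <- vector("list", length(ca$blocks2))
  for (i in rev(seq_along(ca$blocks2))) {
    bc <- ca$blocks2[[i]]
    ds <- .relu_bwd(dg, bc$omask)
    b2 <- .conv_bwd(ds, bc$c2)
    du1 <- .relu_bwd(b2$dX, bc$m1)
    b1 <- .conv_bwd(du1, bc$c1)
    g$s2$blocks[[i]] <- list(c1 = list(W = b1$dW, b = b1$db),
                             c2 = list(W = b2$dW, b = b2$db))
    dg <- ds + b1$dX
  }
  ds2 <- .relu_bwd(dg, ca$stem2$mask)
  bs2 <- .conv_bwd(ds2, ca$stem2$conv)
  g$s2$stem <- list(W = bs2$dW, b = bs2$db)

  E <- cfg$stage1$embedding_dim
  dX2 <- bs2$dX
  der <- dX2[seq_len(E), , drop = FALSE]
  dsm <- dX2[E + seq_len(cfg$n_classes), , drop = FALSE]
  daux <- .softmax_bwd(dsm, ca$auxp) + daux_ce
  ba <- .conv_bwd(daux, ca$aux)
  g$s1$aux <- list(W = ba$dW, b = ba$db)
  der <- der + ba$dX
  demb <- .relu_bwd(der, ca$emask)
  be <- .conv_bwd(demb, ca$emb)
  g$s1$emb <- list(W = be$dW, b = be$db)
  dh <- .pool_bwd(be$dX, ca$pool)

  g$s1$blocks <- vector("list", length(ca$blocks1))
  for (i in rev(seq_along(ca$blocks1))) {
    bc <- ca$blocks1[[i]]
    ds <- .relu_bwd(dh, bc$omask)
    bp <- .conv_bwd(ds, bc$proj)
    dz <- .relu_bwd(bp$dX, bc$zmask)
    nb <- length(bc$brs)
    gb <- vector("list", nb)
    dh_in <- ds
    max_k <- max(vapply(bc$brs, function(x) length(x$W), 0L))
    br_offs <- seq_len(max_k) - (max_k + 1L) %/% 2L
    dict <- .shift_dict(bc$brs[[1]]$X, br_offs, bc$brs[[1]]$seg)
    for (j in seq_len(nb)) {
      rows <- (j - 1) * bc$rows + seq_len(bc$rows)
      bj <- .conv_bwd(dz[rows, , drop = FALSE], bc$brs[[j]], dict = dict)
      gb[[j]] <- list(W = bj$dW, b = bj$db)
      dh_in <- dh_in + bj$dX
    }
    g$s1$blocks[[i]] <- list(br = gb, proj = list(W = bp$dW, b = bp$db))
    dh <- dh_in
  }
  ds1 <- .relu_bwd(dh, ca$stem$mask)
  bs1 <- .conv_bwd(ds1, ca$stem$conv, need_dx = FALSE)
  g$s1$stem <- list(W = bs1$dW, b = bs1$db)
  g
}

# loss + gradient for one batch
.model_loss_grad <- function(par, cfg, X, T_len, seg2, y, class_weights,
                             aux_weight) {
  fwd <- .model_forward(par, cfg, X, T_len, seg2)
  main <- .ce_loss(fwd$logits, y, class_weights)
  aux <- .ce_loss(fwd$aux_logits, y, class_weights)
  grad <- .model_backward(par, cfg, fwd, main$dlogits,
                          aux_weight * aux$dlogits)
  list(loss = main$loss + aux_weight * aux$loss,
       main_loss = main$loss, grad = grad, probs = main$probs)
}

# ---- training / inference -------------------------------------------------

#' Convert a feature tensor + reference hypnogram into training arrays
#'
#' @param tensor A `feature_tensor` from [assemble_inputs()].
#' @param h The reference [hypnogram()] (5-class labels; collapsed to the
#'   4-level space internally). Truncated/padded mismatches are an error.
#' @return `list(X, T_len, n_epochs, y)` with `y` as integers in the
#'   (W, Light, Deep, R) order.
#' @export
prepare_subject <- function(tensor, h) {
  stopifnot(inherits(tensor, "feature_tensor"))
  n_ep <- dim(tensor$x)[1]
  if (length(h$labels) != n_ep) {
    stop("feature tensor (", n_ep, " epochs) does not match hypnogram (",
         length(h$labels), " epochs)")
  }
  Cc <- dim(tensor$x)[2]; Tw <- dim(tensor$x)[3]
  X <- matrix(aperm(tensor$x, c(2, 3, 1)), nrow = Cc)
  y <- match(collapse_stages(h$labels, "aasm5", 4), STAGES_L4)
  list(X = X, T_len = Tw, n_epochs = n_ep, y = y)
}

#' Train the staging network on a cohort
#'
#' Subjects are split 80/20 at the participant level (deterministically,
#' given `split_seed`); the network is trained full-batch with Adam on the
#' training participants, the train/test accuracy curve is logged every
#' iteration, and the weights achieving the smallest held-out loss are
#' retained.
#'
#' @param model A [build_model()] result.
#' @param subjects List of prepared subjects ([prepare_subject()]).
#' @param split_seed Seed for the participant split.
#' @param iters,lr Override the config's training defaults.
#' @param verbose Print the loss curve.
#' @return The trained `staging_model`, with `history` (data.frame of
#'   per-iteration train/test loss and accuracy) and `split` attached.
#' @export
train_model <- function(model, subjects, split_seed = 1, iters = NULL,
                        lr = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "staging_model"))
  n <- length(subjects)
  if (n < 5) stop("need >= 5 subjects for a non-degenerate 80/20 split")
  cfg <- model$config
  tr <- cfg$training
  if (is.null(iters)) iters <- tr$iters
  if (is.null(lr)) lr <- tr$lr
  set.seed(.as_seed(split_seed))
  n_test <- max(1L, round(0.2 * n))
  test_idx <- sort(sample.int(n, n_test))
  train_idx <- setdiff(seq_len(n), test_idx)
  if (length(intersect(train_idx, test_idx))) {
    stop("internal error: subject present in both splits")
  }
  pack <- function(idx) {
    list(X = do.call(cbind, lapply(subjects[idx], `[[`, "X")),
         seg2 = as.integer(vapply(subjects[idx],
                                  function(s) as.numeric(s$n_epochs), 0)),
         y = unlist(lapply(subjects[idx], `[[`, "y")))
  }
  trn <- pack(train_idx); tst <- pack(test_idx)
  T_len <- subjects[[1]]$T_len
  cw <- tr$class_weights
  if (identical(cw, "balanced")) {
    freq <- tabulate(trn$y, nbins = cfg$n_classes)
    cw <- sum(freq) / pmax(freq, 1) / cfg$n_classes
  }
  par <- model$par
  state <- NULL
  best <- list(loss = Inf, par = par)
  hist <- data.frame(iter = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), test_loss = numeric(0),
                     test_acc = numeric(0))
  for (it in seq_len(iters)) {
    lg <- .model_loss_grad(par, cfg, trn$X, T_len, trn$seg2, trn$y, cw,
                           tr$aux_weight)
    st <- .adam_step(par, lg$grad, state, lr = lr)
    par <- st$par; state <- st$state
    tr_acc <- mean(apply(lg$probs, 2, which.max) == trn$y)
    tfwd <- .model_forward(par, cfg, tst$X, T_len, tst$seg2)
    tce <- .ce_loss(tfwd$logits, tst$y, cw)
    te_acc <- mean(apply(tce$probs, 2, which.max) == tst$y)
    hist <- rbind(hist, data.frame(iter = it, train_loss = lg$main_loss,
                                   train_acc = tr_acc, test_loss = tce$loss,
                                   test_acc = te_acc))
    if (tce$loss < best$loss) best <- list(loss = tce$loss, par = par)
    if (verbose) {
      message(sprintf("iter %3d  train %.4f/%.3f  test %.4f/%.3f", it,
                      lg$main_loss, tr_acc, tce$loss, te_acc))
    }
  }
  model$par <- best$par
  model$trained <- TRUE
  model$history <- hist
  model$split <- list(train = train_idx, test = test_idx)
  model
}

#' Predict sleep stages for one or more subjects
#'
#' Produces one prediction per epoch of the input grid, including
#' QC-rejected epochs: quality flags are carried alongside the
#' predictions, never used to mask them.
#'
#' @param model A `staging_model` (trained, unless
#'   `allow_untrained = TRUE`).
#' @param inputs A `feature_tensor`, a prepared subject
#'   ([prepare_subject()]), or a list of prepared subjects.
#' @param qc Optional `quality_report`; its epoch flags are attached.
#' @param allow_untrained Permit inference with freshly initialized
#'   weights.
#' @return A list of class `"stage_prediction"`: `probs4`
#'   (epochs x 4 matrix, columns W/Light/Deep/R), `label4`, `label3`,
#'   `label2`, `qc_rejected`.
#' @export
predict_stages <- function(model, inputs, qc = NULL,
                           allow_untrained = FALSE) {
  stopifnot(inherits(model, "staging_model"))
  if (!model$trained && !allow_untrained) {
    stop("model is untrained; pass allow_untrained = TRUE to score anyway")
  }
  if (inherits(inputs, "feature_tensor")) {
    n_ep <- dim(inputs$x)[1]
    Cc <- dim(inputs$x)[2]; Tw <- dim(inputs$x)[3]
    subj <- list(list(X = matrix(aperm(inputs$x, c(2, 3, 1)), nrow = Cc),
                      T_len = Tw, n_epochs = n_ep))
  } else if (!is.null(inputs$X)) {
    subj <- list(inputs)
  } else {
    subj <- inputs
  }
  X <- do.call(cbind, lapply(subj, `[[`, "X"))
  seg2 <- as.integer(vapply(subj, function(s) as.numeric(s$n_epochs), 0))
  if (ncol(X) %% subj[[1]]$T_len != 0) stop("input shape mismatch")
  fwd <- .model_forward(model$par, model$config, X, subj[[1]]$T_len, seg2)
  probs4 <- t(fwd$logits)
  probs4 <- t(apply(probs4, 1, function(a) {
    e <- exp(a - max(a)); e / sum(e)
  }))
  colnames(probs4) <- STAGES_L4
  label4 <- STAGES_L4[apply(probs4, 1, which.max)]
  rej <- if (!is.null(qc)) qc$epoch_rejected else rep(NA, nrow(probs4))
  if (length(rej) != nrow(probs4)) rej <- rep(NA, nrow(probs4))
  structure(list(probs4 = probs4, label4 = label4,
                 label3 = collapse_stages(label4, "level4", 3),
                 label2 = collapse_stages(label4, "level4", 2),
                 qc_rejected = rej),
            class = "stage_prediction")
}

#' Collapse 4-level predictions to a coarser level
#'
#' Probabilities are summed within the collapse groups
#' (Light+Deep -> NREM for 3-level; Light+Deep+R -> Sleep for 2-level;
#' Wake always maps to Wake) and labels recomputed as the argmax of the
#' collapsed probabilities, ties broken toward the earlier class.
#'
#' @param p A `stage_prediction` or an epochs x 4 probability matrix with
#'   columns in (W, Light, Deep, R) order.
#' @param level 2, 3 or 4.
#' @return `list(labels =, probs =)` at the requested level.
#' @export
collapse_predictions <- function(p, level) {
  classes <- stage_levels(level)     # errors on unknown level
  probs4 <- if (inherits(p, "stage_prediction")) p$probs4 else as.matrix(p)
  stopifnot(ncol(probs4) == 4)
  map <- collapse_map(level)
  probs <- vapply(classes, function(cl) {
    rowSums(probs4[, which(map == cl), drop = FALSE])
  }, numeric(nrow(probs4)))
  probs <- matrix(probs, ncol = length(classes),
                  dimnames = list(NULL, classes))
  labels <- classes[apply(probs, 1, which.max)]
  list(labels = labels, probs = probs)
}
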