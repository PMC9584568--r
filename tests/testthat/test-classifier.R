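small_cfg <- function(seed = 1) {
  staging_config(
    stage1 = list(kernels = c(3, 5), n_blocks = 2, stem_width = 6,
                  branch_width = 5, embedding_dim = 7),
    stage2 = list(dilations = c(1, 2, 4), width = 8, head_hidden = 6),
    c_in = 10, seed = seed,
    training = list(iters = 3, lr = 1e-3, aux_weight = 0.3,
                    class_weights = NULL))
}

rand_inputs <- function(cfg, n_ep = 12, T_len = 20, seed = 2) {
  set.seed(seed)
  list(X = matrix(rnorm(cfg$c_in * T_len * n_ep), cfg$c_in),
       T_len = T_len, n_epochs = n_ep,
       y = sample(1:4, n_ep, replace = TRUE))
}

test_that("default configuration reproduces the published capacities", {
  m <- build_model(staging_config())
  expect_identical(m$param_count_stage1, 492420)
  expect_identical(m$param_count_stage2, 538796)
  expect_identical(m$param_count_total, 1031216)
  expect_identical(m$param_count_total,
                   m$param_count_stage1 + m$param_count_stage2)
})

test_that("count formula matches brute-force enumeration on random configs", {
  set.seed(42)
  for (i in 1:20) {
    cfg <- staging_config(
      width_multiplier = runif(1, 0.5, 2),
      stage1 = list(kernels = sort(sample(c(3, 5, 7, 9), 2)),
                    n_blocks = sample(1:3, 1),
                    stem_width = sample(4:20, 1),
                    branch_width = sample(4:20, 1),
                    embedding_dim = sample(4:20, 1)),
      stage2 = list(dilations = 2^(0:sample(1:4, 1)),
                    width = sample(4:20, 1),
                    head_hidden = sample(4:20, 1)),
      c_in = sample(3:12, 1), seed = i)
    m <- build_model(cfg)     # build_model itself cross-checks the formula
    brute <- somnohr:::.par_count(m$par$s1) + somnohr:::.par_count(m$par$s2)
    expect_identical(brute, m$param_count_total)
  }
})

test_that("width calibration solves the count formula for the targets", {
  cfg <- calibrate_staging_widths(492420, 538796)
  counts <- staging_param_counts(cfg)
  expect_identical(counts$stage1, 492420)
  expect_identical(counts$stage2, 538796)
  # a doubled width multiplier changes counts but keeps formula exact
  cfg2 <- staging_config(width_multiplier = 2)
  m2_counts <- staging_param_counts(cfg2)
  m2 <- build_model(cfg2)
  expect_identical(m2$param_count_total, m2_counts$total)
  expect_error(calibrate_staging_widths(100, 100), "no exact width")
})

test_that("initialization and inference are deterministic", {
  cfg <- small_cfg(seed = 7)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$par, m2$par)
  inp <- rand_inputs(cfg)
  p1 <- predict_stages(m1, inp, allow_untrained = TRUE)
  p2 <- predict_stages(m1, inp, allow_untrained = TRUE)
  expect_identical(p1$probs4, p2$probs4)
})

test_that("predictions cover every epoch and posteriors sum to one", {
  cfg <- small_cfg()
  m <- build_model(cfg)
  inp <- rand_inputs(cfg, n_ep = 17)
  qc <- structure(list(epoch_rejected = c(rep(TRUE, 5), rep(FALSE, 12)),
                       fraction_rejected = 5 / 17,
                       recording_excluded = FALSE, config = qc_config()),
                  class = "quality_report")
  p <- predict_stages(m, inp, qc = qc, allow_untrained = TRUE)
  expect_equal(nrow(p$probs4), 17)               # rejected epochs included
  expect_lt(max(abs(rowSums(p$probs4) - 1)), 1e-6)
  expect_identical(p$qc_rejected, qc$epoch_rejected)
  expect_error(predict_stages(m, inp), "untrained")
})

test_that("hierarchical collapse maps and tie-breaking", {
  # Deep -> NREM -> Sleep
  expect_identical(collapse_stages("Deep", "level4", 3), "NREM")
  expect_identical(collapse_stages("Deep", "level4", 2), "Sleep")
  # probability mass pooling can flip the argmax
  probs <- matrix(c(0.1, 0.3, 0.25, 0.35), 1,
                  dimnames = list(NULL, STAGES_L4))
  c3 <- collapse_predictions(probs, 3)
  expect_equal(unname(c3$probs[1, ]), c(0.1, 0.55, 0.35))
  expect_identical(c3$labels, "NREM")            # even though R won at 4-level
  # Wake epochs are invariant under every collapse
  pw <- matrix(c(0.7, 0.1, 0.1, 0.1), 1)
  for (lv in c(4, 3, 2)) {
    expect_identical(collapse_predictions(pw, lv)$labels, "W")
  }
  # argmax ties break toward the earlier class
  tie <- matrix(c(0.3, 0.3, 0.2, 0.2), 1)
  expect_identical(collapse_predictions(tie, 4)$labels, "W")
  expect_error(collapse_predictions(pw, 5), "unknown")
})

test_that("collapse commutes with confusion aggregation on random pairs", {
  cfg <- small_cfg()
  m <- build_model(cfg)
  set.seed(66)
  for (i in 1:25) {
    n <- sample(30:80, 1)
    ref <- sample(STAGES_AASM5, n, replace = TRUE)
    probs <- matrix(rexp(4 * n), n)
    probs <- probs / rowSums(probs)
    lab4 <- STAGES_L4[apply(probs, 1, which.max)]
    for (lv in c(3, 2)) {
      via_probs <- collapse_predictions(probs, lv)$labels
      via_labels <- collapse_stages(lab4, "level4", lv)
      # when no probability regrouping flips the argmax these coincide;
      # the confusion-matrix homomorphism must hold for label collapsing
      cm4 <- confusion(ref, lab4, 4)
      expect_identical(collapse_confusion(cm4, lv)$counts,
                       confusion(ref, via_labels, lv)$counts)
    }
  }
})

test_that("training splits subjects 80/20 and improves on the training set", {
  cfg <- small_cfg()
  m <- build_model(cfg)
  subs <- lapply(1:10, function(s) rand_inputs(cfg, n_ep = 10, seed = s))
  tm <- train_model(m, subs, split_seed = 4, iters = 3)
  expect_equal(length(tm$split$train), 8)
  expect_equal(length(tm$split$test), 2)
  expect_length(intersect(tm$split$train, tm$split$test), 0)
  expect_true(tm$trained)
  expect_equal(nrow(tm$history), 3)
  expect_error(train_model(m, subs[1:3]), ">= 5 subjects")
})

test_that("analytic gradients match finite differences", {
  cfg <- staging_config(
    stage1 = list(kernels = c(3, 5), n_blocks = 2, stem_width = 4,
                  branch_width = 3, embedding_dim = 5),
    stage2 = list(dilations = c(1, 2), width = 6, head_hidden = 4),
    c_in = 3, seed = 11)
  m <- build_model(cfg)
  set.seed(5)
  T_len <- 8; N <- 6
  X <- matrix(rnorm(3 * T_len * N), 3)
  seg2 <- c(4L, 2L)
  y <- sample(1:4, N, replace = TRUE)
  lg <- somnohr:::.model_loss_grad(m$par, cfg, X, T_len, seg2, y, NULL, 0.3)
  eps <- 1e-6
  spots <- list(
    list(g = lg$grad$s1$blocks[[1]]$br[[2]]$W[[4]][2, 3],
         get = function(p) p$s1$blocks[[1]]$br[[2]]$W[[4]],
         set = function(p, v) { p$s1$blocks[[1]]$br[[2]]$W[[4]] <- v; p },
         idx = 2 + (3 - 1) * 3),
    list(g = lg$grad$s2$blocks[[2]]$c1$W[[1]][5, 2],
         get = function(p) p$s2$blocks[[2]]$c1$W[[1]],
         set = function(p, v) { p$s2$blocks[[2]]$c1$W[[1]] <- v; p },
         idx = 5 + (2 - 1) * 6),
    list(g = lg$grad$s1$emb$b[3],
         get = function(p) p$s1$emb$b,
         set = function(p, v) { p$s1$emb$b <- v; p },
         idx = 3)
  )
  for (sp in spots) {
    p0 <- m$par
    v <- sp$get(p0)
    v[sp$idx] <- v[sp$idx] + eps
    l1 <- somnohr:::.model_loss_grad(sp$set(p0, v), cfg, X, T_len, seg2, y,
                                     NULL, 0.3)$loss
    v[sp$idx] <- v[sp$idx] - 2 * eps
    l2 <- somnohr:::.model_loss_grad(sp$set(p0, v), cfg, X, T_len, seg2, y,
                                     NULL, 0.3)$loss
    num <- (l1 - l2) / (2 * eps)
    expect_lt(abs(sp$g - num), 1e-5 * max(1, abs(num)))
  }
})

test_that("convolutions never bleed across segment boundaries", {
  # two segments; perturbing segment 1 must not change segment 2 output
  cfg <- small_cfg()
  m <- build_model(cfg)
  inp <- rand_inputs(cfg, n_ep = 8)
  seg2 <- c(4L, 4L)
  f1 <- somnohr:::.model_forward(m$par, cfg, inp$X, inp$T_len, seg2)
  X2 <- inp$X
  X2[, 1:(4 * inp$T_len)] <- 0                   # wipe the first subject
  f2 <- somnohr:::.model_forward(m$par, cfg, X2, inp$T_len, seg2)
  expect_equal(f1$logits[, 5:8], f2$logits[, 5:8], tolerance = 1e-10)
})
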