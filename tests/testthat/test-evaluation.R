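test_that("confusion matrices tally every epoch exactly once", {
  ref <- hypnogram(rep(c("W", "N1", "N2", "N3", "R"), each = 20))
  cm <- confusion(ref, collapse_stages(ref$labels, "aasm5", 4), 4)
  expect_equal(sum(diag(cm$counts)), 100)
  expect_equal(sum(cm$counts), 100)

  cm2 <- confusion(hypnogram(rep("W", 40)), rep("Sleep", 40), 2)
  expect_equal(cm2$counts["W", "Sleep"], 40L)
  expect_equal(sum(cm2$counts) - cm2$counts["W", "Sleep"], 0L)

  expect_error(confusion(ref, rep("W", 5), 4), "lengths differ")
})

test_that("collapsing the matrix commutes with collapsing the labels", {
  set.seed(77)
  ok <- TRUE
  for (i in 1:1000) {
    n <- sample(20:60, 1)
    ref <- sample(STAGES_AASM5, n, replace = TRUE)
    pred <- sample(STAGES_L4, n, replace = TRUE)
    cm4 <- confusion(ref, pred, 4)
    for (lv in c(3, 2)) {
      direct <- confusion(ref, pred, lv)
      collapsed <- collapse_confusion(cm4, lv)
      ok <- ok && identical(collapsed$counts, direct$counts)
    }
    if (!ok) break
  }
  expect_true(ok)
})

test_that("metrics agree with a brute-force oracle to 1e-12", {
  set.seed(123)
  worst <- 0
  na_mismatch <- FALSE
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    M <- matrix(rpois(k * k, lambda = sample(c(2, 20, 200), 1)), k)
    if (sum(M) == 0) M[1, 1] <- 1
    lv <- c(2, 3, 4)[k - 1]
    cm <- structure(list(counts = M, level = lv,
                         classes = stage_levels(lv)),
                    class = "confusion_matrix")
    ms <- metrics(cm)
    bf <- brute_force_metrics(M)
    worst <- max(worst, abs(ms$accuracy - bf$accuracy),
                 abs(ms$kappa - bf$kappa), na.rm = TRUE)
    for (j in seq_len(k)) {
      got <- unlist(ms$per_class[j, c("se", "sp", "ppv", "npv")])
      want <- bf$per_class[[j]]
      na_mismatch <- na_mismatch || any(is.na(got) != is.na(want))
      d <- abs(got - want)
      worst <- max(worst, d[!is.na(d)], 0)
    }
  }
  expect_false(na_mismatch)
  expect_lt(worst, 1e-12)
})

test_that("binary complement identities hold exactly", {
  set.seed(5)
  for (i in 1:50) {
    M <- matrix(rpois(4, 50) + 1, 2)
    cm <- structure(list(counts = M, level = 2, classes = STAGES_L2),
                    class = "confusion_matrix")
    ms <- metrics(cm)
    w <- ms$per_class[ms$per_class$class == "W", ]
    s <- ms$per_class[ms$per_class$class == "Sleep", ]
    expect_identical(s$se, w$sp)
    expect_identical(s$sp, w$se)
    expect_identical(s$ppv, w$npv)
    expect_identical(s$npv, w$ppv)
  }
})

test_that("Wake one-vs-rest metrics are identical across 2/3/4 levels", {
  set.seed(9)
  for (i in 1:50) {
    n <- 300
    ref <- sample(STAGES_AASM5, n, replace = TRUE)
    pred <- sample(STAGES_L4, n, replace = TRUE,
                   prob = c(0.3, 0.4, 0.15, 0.15))
    wake <- lapply(c(2, 3, 4), function(lv) {
      ms <- metrics(confusion(ref, pred, lv))
      unlist(ms$per_class[ms$per_class$class == "W",
                          c("se", "sp", "ppv", "npv")])
    })
    expect_identical(wake[[1]], wake[[2]])
    expect_identical(wake[[2]], wake[[3]])
  }
})

test_that("accuracy equals prevalence-weighted sensitivity; kappa bounds", {
  set.seed(31)
  for (i in 1:200) {
    M <- matrix(rpois(16, 30), 4)
    if (any(rowSums(M) == 0)) next
    cm <- structure(list(counts = M, level = 4, classes = STAGES_L4),
                    class = "confusion_matrix")
    ms <- metrics(cm)
    prev <- rowSums(M) / sum(M)
    expect_equal(ms$accuracy, sum(prev * ms$per_class$se), tolerance = 1e-12)
    expect_lte(ms$kappa, ms$accuracy + 1e-12)
  }
  # rows proportional to column marginals -> kappa = 0
  col <- c(10, 20, 30, 40)
  M0 <- outer(c(1, 2, 3, 4), col)
  cm0 <- structure(list(counts = M0, level = 4, classes = STAGES_L4),
                   class = "confusion_matrix")
  expect_equal(metrics(cm0)$kappa, 0, tolerance = 1e-12)
})

test_that("identity matrix gives perfect metrics; zero cells give NA", {
  cm <- structure(list(counts = diag(4) * 25L, level = 4,
                       classes = STAGES_L4),
                  class = "confusion_matrix")
  ms <- metrics(cm)
  expect_equal(ms$accuracy, 1)
  expect_equal(ms$kappa, 1)
  expect_true(all(unlist(ms$per_class[, c("se", "sp", "ppv", "npv")]) == 1))

  # a class never predicted and never present: ppv and se undefined
  M <- diag(c(10L, 10L, 0L, 10L))
  cmz <- structure(list(counts = M, level = 4, classes = STAGES_L4),
                   class = "confusion_matrix")
  msz <- metrics(cmz)
  deep <- msz$per_class[msz$per_class$class == "Deep", ]
  expect_true(is.na(deep$se))
  expect_true(is.na(deep$ppv))
})

test_that("cohort aggregation: means, degenerate CI, pooled-vs-mean", {
  mk <- function(M, lv = 2) {
    metrics(structure(list(counts = M, level = lv,
                           classes = stage_levels(lv)),
                      class = "confusion_matrix"))
  }
  a <- mk(matrix(c(40L, 10L, 5L, 45L), 2, byrow = TRUE))
  b <- mk(matrix(c(45L, 5L, 5L, 45L), 2, byrow = TRUE))
  agg <- aggregate_metrics(list(a, b))
  acc <- agg[agg$metric == "accuracy", ]
  expect_equal(acc$mean, (0.85 + 0.90) / 2)
  agg_same <- aggregate_metrics(list(a, a, a))
  acc_same <- agg_same[agg_same$metric == "accuracy", ]
  expect_equal(acc_same$ci95_low, acc_same$ci95_high)
  expect_equal(acc_same$ci95_low, acc_same$mean)

  # unequal epoch counts: pooled and cohort-mean accuracy differ;
  # equal counts: they coincide
  big <- matrix(c(400L, 100L, 50L, 450L), 2, byrow = TRUE)
  small <- matrix(c(10L, 0L, 0L, 10L), 2, byrow = TRUE)
  pooled_acc <- metrics(structure(list(counts = big + small, level = 2,
                                       classes = STAGES_L2),
                                  class = "confusion_matrix"))$accuracy
  mean_acc <- mean(c(mk(big)$accuracy, mk(small)$accuracy))
  expect_false(isTRUE(all.equal(pooled_acc, mean_acc)))
  pooled_eq <- metrics(structure(list(counts = big + big, level = 2,
                                      classes = STAGES_L2),
                                 class = "confusion_matrix"))$accuracy
  expect_equal(pooled_eq, mk(big)$accuracy)
})

test_that("single-factor OLS beta equals the difference of group means", {
  accs <- c(0.9, 0.88, 0.92, 0.70, 0.72, 0.74)
  per_subject <- lapply(accs, function(a) {
    n <- 100
    M <- matrix(c(round(a * n), n - round(a * n), 0L, 0L), 2, byrow = TRUE)
    metrics(structure(list(counts = M, level = 2, classes = STAGES_L2),
                      class = "confusion_matrix"))
  })
  meta <- data.frame(subject_id = sprintf("S%d", 1:6),
                     age_group = rep(c("<=40", ">60"), each = 3),
                     ahi_group = "none/minimal",
                     sex = rep(c("F", "M"), 3))
  eff <- stratified_regression(per_subject, meta,
                               metrics_to_test = "accuracy")
  b_old <- eff[eff$factor == "age" & eff$level == ">60", ]
  expect_equal(b_old$beta, mean(accs[4:6]) - mean(accs[1:3]),
               tolerance = 1e-12)
  expect_equal(b_old$reference, "<=40")
})
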