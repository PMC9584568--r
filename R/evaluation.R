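#' Confusion matrix between a reference hypnogram and predicted labels
#'
#' The reference is collapsed from the 5-class AASM alphabet to the
#' requested level (N1, N2 -> Light, N3 -> Deep, and onward); predictions
#' may be given in the 4-level or the target alphabet. Rows are reference,
#' columns are predicted, in the canonical class order; every epoch is
#' tallied exactly once.
#'
#' @param ref A [hypnogram()] or character vector of 5-class labels.
#' @param pred Character vector of predicted labels (4-level or target
#'   level), same length as the reference.
#' @param level 2, 3 or 4.
#' @return A list of class `"confusion_matrix"`: `counts` (square integer
#'   table), `level`, `classes`.
#' @export
confusion <- function(ref, pred, level = 4) {
  ref_l <- if (inherits(ref, "hypnogram")) ref$labels else as.character(ref)
  pred <- as.character(pred)
  if (length(ref_l) != length(pred)) {
    stop("reference (", length(ref_l), ") and prediction (", length(pred),
         ") lengths differ")
  }
  classes <- stage_levels(level)
  ref_c <- collapse_stages(ref_l, "aasm5", level)
  pred_c <- if (all(pred %in% classes)) {
    pred
  } else {
    collapse_stages(pred, "level4", level)
  }
  counts <- table(factor(ref_c, levels = classes),
                  factor(pred_c, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(reference = classes, predicted = classes))
  structure(list(counts = counts, level = level, classes = classes),
            class = "confusion_matrix")
}

#' Build a confusion matrix directly from labels at a level
#'
#' Lower-level constructor when both sequences are already in the target
#' alphabet.
#'
#' @param ref_labels,pred_labels Label vectors in the level's alphabet.
#' @param level 2, 3 or 4.
#' @return A `confusion_matrix`.
#' @export
confusion_from_labels <- function(ref_labels, pred_labels, level) {
  classes <- stage_levels(level)
  stopifnot(all(ref_labels %in% classes), all(pred_labels %in% classes),
            length(ref_labels) == length(pred_labels))
  counts <- table(factor(ref_labels, levels = classes),
                  factor(pred_labels, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(reference = classes, predicted = classes))
  structure(list(counts = counts, level = level, classes = classes),
            class = "confusion_matrix")
}

#' Collapse a 4-level confusion matrix to a coarser level
#'
#' Aggregates rows and columns by the collapse groups. Collapsing the
#' matrix commutes with collapsing the label sequences first.
#'
#' @param cm A level-4 `confusion_matrix`.
#' @param level Target level (2 or 3).
#' @return A `confusion_matrix` at the target level.
#' @export
collapse_confusion <- function(cm, level) {
  stopifnot(inherits(cm, "confusion_matrix"), cm$level == 4)
  classes <- stage_levels(level)
  map <- collapse_map(level)
  grp <- factor(unname(map[cm$classes]), levels = classes)
  agg <- rowsum(t(rowsum(cm$counts, grp)), grp)
  counts <- matrix(as.integer(t(agg)), nrow = length(classes),
                   dimnames = list(reference = classes, predicted = classes))
  structure(list(counts = counts, level = level, classes = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d-level, %d epochs\n", x$level,
              sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Agreement metrics from a confusion matrix
#'
#' Accuracy, Cohen's kappa, and one-vs-rest sensitivity, specificity,
#' positive and negative predictive value per class. Zero-denominator
#' cells yield `NA` (undefined), never 0.
#'
#' @param cm A `confusion_matrix`.
#' @return A list of class `"metric_set"`: `accuracy`, `kappa`,
#'   `per_class` (data.frame with class, se, sp, ppv, npv), `n`.
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  M <- cm$counts
  n <- sum(M)
  if (n == 0) stop("empty confusion matrix")
  acc <- sum(diag(M)) / n
  pe <- sum(rowSums(M) * colSums(M)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps) NA_real_ else
    (acc - pe) / (1 - pe)
  per <- do.call(rbind, lapply(seq_along(cm$classes), function(i) {
    tp <- M[i, i]
    fn <- sum(M[i, -i])
    fp <- sum(M[-i, i])
    tn <- n - tp - fn - fp
    dv <- function(num, den) if (den == 0) NA_real_ else num / den
    data.frame(class = cm$classes[i],
               se = dv(tp, tp + fn), sp = dv(tn, tn + fp),
               ppv = dv(tp, tp + fp), npv = dv(tn, tn + fn),
               stringsAsFactors = FALSE)
  }))
  structure(list(accuracy = acc, kappa = kappa, per_class = per, n = n,
                 level = cm$level),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> %d-level: accuracy %.4f, kappa %.4f (n = %d)\n",
              x$level, x$accuracy, x$kappa, x$n))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

# flatten a metric_set into a named numeric vector
.metric_vector <- function(ms) {
  v <- c(accuracy = ms$accuracy, kappa = ms$kappa)
  for (i in seq_len(nrow(ms$per_class))) {
    cl <- ms$per_class$class[i]
    v[paste0(c("se_", "sp_", "ppv_", "npv_"), cl)] <-
      unlist(ms$per_class[i, c("se", "sp", "ppv", "npv")])
  }
  v
}

#' Aggregate per-subject metrics to a cohort summary
#'
#' Subject-level metrics (each computed from that subject's own confusion
#' matrix) are averaged across participants; 95% confidence intervals use
#' the normal approximation `mean +/- 1.96 * sd / sqrt(n)`. Undefined
#' per-subject values are excluded with `n` adjusted accordingly.
#'
#' @param per_subject List of `metric_set` objects (>= 2).
#' @return A data.frame of class `"cohort_summary"`: one row per metric
#'   with `mean`, `ci95_low`, `ci95_high`, `n_subjects`.
#' @export
aggregate_metrics <- function(per_subject) {
  if (length(per_subject) < 2) stop("need >= 2 subjects to aggregate")
  mat <- do.call(rbind, lapply(per_subject, .metric_vector))
  out <- do.call(rbind, lapply(colnames(mat), function(nm) {
    v <- mat[, nm]
    v <- v[!is.na(v)]
    if (!length(v)) {
      return(data.frame(metric = nm, mean = NA_real_, ci95_low = NA_real_,
                        ci95_high = NA_real_, n_subjects = 0L))
    }
    m <- mean(v)
    sem <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    data.frame(metric = nm, mean = m, ci95_low = m - 1.96 * sem,
               ci95_high = m + 1.96 * sem, n_subjects = length(v))
  }))
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Covariate regressions of per-subject performance
#'
#' For each metric and each factor (age group, AHI group, sex), an
#' ordinary least-squares fit of the per-subject metric on that factor
#' alone, dummy-coded against the reference levels age <= 40,
#' AHI none/minimal, and female. Betas, normal-approximation 95%
#' confidence intervals, two-sided p-values, and significance stars at
#' 0.05 / 0.01 / 0.001.
#'
#' @param per_subject List of `metric_set` objects, one per subject.
#' @param meta Data.frame with `subject_id`, `age_group`, `ahi_group`,
#'   `sex` (one row per subject, same order).
#' @param metrics_to_test Metric names (columns of the flattened metric
#'   vector); default accuracy and kappa.
#' @return A data.frame of class `"strata_effects"`: `metric`, `factor`,
#'   `level`, `reference`, `beta`, `ci95_low`, `ci95_high`, `p_value`,
#'   `stars`.
#' @export
stratified_regression <- function(per_subject, meta,
                                  metrics_to_test = c("accuracy", "kappa")) {
  if (length(per_subject) != nrow(meta)) {
    stop("metadata rows must match the number of subjects")
  }
  mat <- do.call(rbind, lapply(per_subject, .metric_vector))
  factors <- list(
    age = factor(meta$age_group, levels = AGE_GROUPS),
    ahi = factor(meta$ahi_group, levels = AHI_GROUPS),
    sex = factor(meta$sex, levels = SEX_GROUPS)
  )
  out <- NULL
  for (mname in metrics_to_test) {
    if (!mname %in% colnames(mat)) stop("unknown metric: ", mname)
    y <- mat[, mname]
    for (fname in names(factors)) {
      f <- factors[[fname]]
      keep <- !is.na(y) & !is.na(f)
      lv_present <- table(f[keep])
      if (sum(lv_present > 0) < 2) next
      fit <- stats::lm(y[keep] ~ f[keep])
      sm <- summary(fit)$coefficients
      cf <- rownames(sm)[-1]
      for (k in seq_along(cf)) {
        lev <- sub("^f\\[keep\\]", "", cf[k])
        row <- sm[cf[k], ]
        beta <- row["Estimate"]; se <- row["Std. Error"]
        p <- row["Pr(>|t|)"]
        stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
          if (p < 0.05) "*" else "n.s."
        out <- rbind(out, data.frame(
          metric = mname, factor = fname, level = lev,
          reference = levels(f)[1], beta = unname(beta),
          ci95_low = unname(beta - 1.96 * se),
          ci95_high = unname(beta + 1.96 * se),
          p_value = unname(p), stars = stars,
          stringsAsFactors = FALSE))
      }
    }
  }
  class(out) <- c("strata_effects", "data.frame")
  out
}

#' Full evaluation of a prediction set against references
#'
#' Epoch-level (pooled) and subject-level metrics at the requested
#' levels, with optional covariate regressions when metadata is supplied.
#' Subject-level kappa is the mean of per-subject kappas; the pooled
#' block reports kappa of the pooled counts.
#'
#' @param refs List of reference [hypnogram()]s.
#' @param preds List of predicted 4-level label vectors (or
#'   `stage_prediction` objects), one per subject.
#' @param levels Classification levels to evaluate.
#' @param meta Optional metadata data.frame for [stratified_regression()].
#' @return A list of class `"evaluation_report"`, one entry per level
#'   with `pooled` (a `metric_set`), `cohort` (a `cohort_summary`), and
#'   optionally `strata`.
#' @export
evaluate_predictions <- function(refs, preds, levels = c(2, 3, 4),
                                 meta = NULL) {
  stopifnot(length(refs) == length(preds))
  lab4 <- lapply(preds, function(p) {
    if (inherits(p, "stage_prediction")) p$label4 else as.character(p)
  })
  report <- list()
  for (lv in levels) {
    cms <- mapply(function(r, p) confusion(r, p, lv), refs, lab4,
                  SIMPLIFY = FALSE)
    pooled_counts <- Reduce(`+`, lapply(cms, `[[`, "counts"))
    pooled <- structure(list(counts = pooled_counts, level = lv,
                             classes = stage_levels(lv)),
                        class = "confusion_matrix")
    per_subject <- lapply(cms, metrics)
    entry <- list(pooled = metrics(pooled),
                  cohort = if (length(per_subject) >= 2) {
                    aggregate_metrics(per_subject)
                  })
    if (!is.null(meta)) {
      entry$strata <- stratified_regression(per_subject, meta)
    }
    report[[paste0("level", lv)]] <- entry
  }
  class(report) <- "evaluation_report"
  report
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_evaluation_report <- function(report, path) {
  ser <- lapply(report, function(entry) {
    out <- list(
      pooled = list(accuracy = entry$pooled$accuracy,
                    kappa = entry$pooled$kappa,
                    per_class = entry$pooled$per_class,
                    n_epochs = entry$pooled$n),
      cohort = as.data.frame(entry$cohort)
    )
    if (!is.null(entry$strata)) out$strata <- as.data.frame(entry$strata)
    out
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
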