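# Open-set evaluation. One-vs-rest ROC with "unknown" as the positive class,
# trapezoid AUC, vertical fold-averaging of curves, the closest-to-(0,1)
# operating point, support-weighted F1, and the leave-one-class-out (LOCO)
# protocol: for every class, models trained with that class excluded are
# scored on held-out knowns plus the excluded class relabeled "unknown".

#' One-vs-rest ROC curve for unknown detection
#'
#' Scores are oriented so that higher means "more unknown". TPR and FPR are
#' swept over every distinct score value; AUC by the trapezoid rule.
#'
#' @param scores numeric unknown scores.
#' @param is_unknown logical (or 0/1) labels, TRUE = truly unknown (positive).
#' @return A `roc_curve`: list with `fpr`, `tpr` (non-decreasing, endpoints
#'   (0,0) and (1,1)), `thresholds` (decision rule: score >= threshold is
#'   called unknown; the (0,0) point carries `Inf`), and `auc`.
#' @export
roc_curve <- function(scores, is_unknown) {
  is_unknown <- as.logical(is_unknown)
  stopifnot(length(scores) == length(is_unknown), !anyNA(scores))
  P <- sum(is_unknown); N <- sum(!is_unknown)
  if (P == 0L || N == 0L)
    stop("ROC needs both positive (unknown) and negative (known) labels",
         call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; lab <- is_unknown[o]
  # group tied scores: one operating point per distinct score
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(lab)[last]
  fp <- cumsum(!lab)[last]
  structure(list(fpr = c(0, fp / N), tpr = c(0, tp / P),
                 thresholds = c(Inf, s[last]),
                 auc = sum(diff(c(0, fp / N)) *
                             (utils::head(c(0, tp / P), -1) +
                                utils::tail(c(0, tp / P), -1)) / 2)),
            class = "roc_curve")
}

#' Vertically average ROC curves over folds
#'
#' Interpolates each curve's TPR (and threshold) onto a common FPR grid and
#' averages pointwise; the AUC is recomputed on the averaged curve.
#'
#' @param curves list of `roc_curve` objects (>= 1).
#' @param grid_size number of FPR grid points (default 101).
#' @return A `roc_curve` on the common grid.
#' @export
average_roc_over_folds <- function(curves, grid_size = 101L) {
  stopifnot(length(curves) >= 1L)
  grid <- seq(0, 1, length.out = grid_size)
  interp <- function(curve) {
    # staircase semantics: at each grid FPR take the achieved TPR of the
    # largest curve FPR not exceeding it (constant, right-continuous)
    f <- curve$fpr; tp <- curve$tpr; th <- curve$thresholds
    keep <- !duplicated(f, fromLast = TRUE)   # max tpr per fpr level
    f2 <- f[keep]; tp2 <- tp[keep]; th2 <- th[keep]
    list(tpr = stats::approx(f2, tp2, xout = grid, method = "constant",
                             f = 0, rule = 2)$y,
         thr = stats::approx(f2, pmin(th2, .Machine$double.xmax),
                             xout = grid, method = "constant", f = 0,
                             rule = 2)$y)
  }
  res <- lapply(curves, interp)
  tpr <- rowMeans(vapply(res, `[[`, numeric(length(grid)), "tpr"))
  thr <- rowMeans(vapply(res, `[[`, numeric(length(grid)), "thr"))
  structure(list(fpr = grid, tpr = tpr, thresholds = thr,
                 auc = sum(diff(grid) * (utils::head(tpr, -1) +
                                           utils::tail(tpr, -1)) / 2)),
            class = "roc_curve")
}

#' Optimal operating threshold of a ROC curve
#'
#' The threshold of the curve point closest (Euclidean) to the ideal corner
#' (FPR 0, TPR 1); ties break toward the lower threshold, favoring recall of
#' unknowns.
#'
#' @param curve a `roc_curve`.
#' @return Scalar threshold.
#' @export
optimal_threshold <- function(curve) {
  d2 <- curve$fpr^2 + (1 - curve$tpr)^2
  best <- which(d2 <= min(d2) + 1e-12)
  min(curve$thresholds[best])
}

#' Support-weighted F1 score
#'
#' Per-class F1 averaged with weights proportional to true-class support;
#' `"unknown"` is an ordinary label. Classes with zero true and zero predicted
#' instances are excluded; classes with true support but an undefined F1
#' contribute 0.
#'
#' @param truth true labels (character), possibly including `"unknown"`.
#' @param predicted predicted labels (character), same length.
#' @return Scalar in `[0, 1]`.
#' @export
weighted_f1 <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) > 0L)
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- sort(unique(c(truth, predicted)))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  use <- support > 0
  if (!any(use)) return(0)
  f1[is.na(f1)] <- 0
  sum(f1[use] * support[use]) / sum(support[use])
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve %d points auc=%.4f>\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Plot one or more ROC curves
#'
#' @param x a `roc_curve`.
#' @param add logical; add to an existing plot.
#' @param col line color.
#' @param ... passed to [graphics::lines()].
#' @return `x`, invisibly.
#' @export
plot.roc_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  if (!add) {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "FPR",
                   ylab = "TPR", main = "Unknown-vs-known ROC")
    graphics::abline(0, 1, col = "black", lty = 2)
  }
  graphics::lines(x$fpr, x$tpr, col = col, ...)
  invisible(x)
}

# ---- leave-one-class-out harness --------------------------------------------

# score one model's predictions with both methods on a prediction matrix
openset_scores <- function(P, t) {
  list(formula = unknown_probability_matrix(P, t),
       max_prob = 1 - apply(P, 1L, max))
}

# decisions at a threshold on the (higher = more unknown) score scale: a crop
# is called unknown iff its score reaches the threshold, else argmax class
openset_decisions <- function(P, class_names, scores, thr) {
  amax <- class_names[max.col(P, ties.method = "first")]
  ifelse(scores >= thr, "unknown", amax)
}

#' Leave-one-class-out open-set evaluation
#'
#' For every class `c` and fold `f`: a model is trained on the training folds
#' (all but `f`) with class `c` excluded, then scored on fold `f`'s known
#' crops plus every crop of class `c` (true label `"unknown"`). Both scoring
#' methods (unknown-class probability formula, max-probability baseline) share
#' the same cached prediction matrix; per cell the report carries each
#' method's ROC AUC, closest-to-corner optimal threshold, and the weighted F1
#' of the decisions at that threshold. Fold-averaged curves are returned per
#' excluded class and overall.
#'
#' @param images list of crop arrays.
#' @param manifest data.frame with one row per crop: `label`, `group_id`, and
#'   `split` (values `fold_1..fold_k`; rows with other splits are ignored).
#' @param cfg a [train_config()].
#' @param t transform threshold for the formula method (default 0.8).
#' @param classes optional subset of classes to exclude in turn (default all).
#' @return An `openset_eval_report`: list with `report` (data.frame), `curves`
#'   (nested per excluded class and method), `average_curves` (per method,
#'   over all cells), and `audit` (training-set sizes per cell).
#' @export
loco_evaluate <- function(images, manifest, cfg, t = 0.8, classes = NULL) {
  stopifnot(length(images) == nrow(manifest))
  all_classes <- sort(unique(manifest$label))
  if (length(all_classes) < 3L)
    stop("leave-one-class-out needs >= 3 classes", call. = FALSE)
  folds <- sort(unique(manifest$split[grepl("^fold_", manifest$split)]))
  if (length(folds) < 2L) stop("need >= 2 folds in manifest$split", call. = FALSE)
  if (is.null(classes)) classes <- all_classes
  rows <- list(); curves <- list(); audit <- list()
  all_curves <- list(formula = list(), max_prob = list())
  for (excl in classes) {
    curves[[excl]] <- list(formula = list(), max_prob = list())
    for (f in folds) {
      train_idx <- which(manifest$split %in% setdiff(folds, f) &
                           manifest$label != excl)
      val_known_idx <- which(manifest$split == f & manifest$label != excl)
      unknown_idx <- which(manifest$label == excl)
      stopifnot(length(intersect(train_idx, unknown_idx)) == 0L)
      model <- suppressWarnings(train_classifier(
        images[train_idx], manifest$label[train_idx], cfg,
        val_images = images[val_known_idx],
        val_labels = manifest$label[val_known_idx]))
      eval_idx <- c(val_known_idx, unknown_idx)
      P <- predict(model, images[eval_idx])
      truth <- ifelse(manifest$label[eval_idx] == excl, "unknown",
                      manifest$label[eval_idx])
      is_unknown <- truth == "unknown"
      sc <- openset_scores(P, t)
      cell <- list(excluded_class = excl, fold = f)
      for (m in c("formula", "max_prob")) {
        curve <- roc_curve(sc[[m]], is_unknown)
        thr <- optimal_threshold(curve)
        dec <- openset_decisions(P, model$class_names, sc[[m]], thr)
        cell[[paste0("auc_", m)]] <- curve$auc
        cell[[paste0("opt_t_", m)]] <- thr
        cell[[paste0("weighted_f1_", m)]] <- weighted_f1(truth, dec)
        curves[[excl]][[m]][[f]] <- curve
        all_curves[[m]][[length(all_curves[[m]]) + 1L]] <- curve
      }
      rows[[length(rows) + 1L]] <- as.data.frame(cell)
      audit[[length(audit) + 1L]] <- data.frame(
        excluded_class = excl, fold = f, n_train = length(train_idx),
        n_excluded_in_train = sum(manifest$label[train_idx] == excl))
    }
    for (m in c("formula", "max_prob"))
      curves[[excl]][[paste0(m, "_avg")]] <-
        average_roc_over_folds(curves[[excl]][[m]])
  }
  structure(list(report = do.call(rbind, rows),
                 curves = curves,
                 average_curves = lapply(all_curves, average_roc_over_folds),
                 audit = do.call(rbind, audit)),
            class = "openset_eval_report")
}

#' @export
print.openset_eval_report <- function(x, ...) {
  cat(sprintf("<openset_eval_report %d cells | mean AUC formula=%.3f max_prob=%.3f>\n",
              nrow(x$report), mean(x$report$auc_formula),
              mean(x$report$auc_max_prob)))
  invisible(x)
}
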