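# Evaluation: ROC/AUC, precision-recall, k-fold cross-validation.

#' Area under the ROC curve
#'
#' Probability that a random positive outranks a random negative, with ties
#' counted 1/2 (midrank convention; equals the normalized Wilcoxon rank-sum
#' statistic).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Vector in `{+1, -1}` (or logical).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1 | labels == TRUE
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Precision-recall curve
#'
#' Standard sweep over score thresholds (tied scores grouped), suitable for
#' negative sets much larger than the positive set.
#'
#' @inheritParams roc_auc
#' @return A tibble of class `gkm_pr` with columns `threshold`, `precision`,
#'   `recall`.
#' @export
precision_recall <- function(scores, labels) {
  pos <- labels == 1 | labels == TRUE
  np <- sum(pos)
  if (np == 0 || np == length(labels)) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  tp <- cumsum(p)
  n_pred <- seq_along(s)
  keep <- c(s[-1] != s[-length(s)], TRUE) # last index of each tied block
  out <- tibble::tibble(threshold = s[keep],
                        precision = (tp / n_pred)[keep],
                        recall = (tp / np)[keep])
  class(out) <- c("gkm_pr", class(out))
  out
}

#' Precision at a given recall
#'
#' @param pr A `gkm_pr` curve.
#' @param recall Target recall level (default 0.5).
#' @return Precision at the first threshold reaching the target recall.
#' @export
precision_at_recall <- function(pr, recall = 0.5) {
  i <- which(pr$recall >= recall)
  if (!length(i)) return(NA_real_)
  pr$precision[i[1]]
}

#' @export
autoplot.gkm_pr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' k-fold cross-validation harness
#'
#' Positives and negatives are split independently into `folds` segments by
#' a seeded shuffle; each fold is held out in turn, the trainer is fit on
#' the remainder and the held-out sequences scored; AUC is computed per
#' fold on the pooled held-out scores and summarized by mean, SD and SE.
#'
#' @param pos,neg Sequence tibbles (columns `id`, `seq`), each with at least
#'   `folds` members.
#' @param trainer `function(train, test)` receiving tibbles with columns
#'   `id`, `seq`, `label` (train) and `id`, `seq` (test), returning a
#'   numeric score per test sequence (in test order).
#' @param folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return A `gkm_cv` object: tibble with per-fold AUCs, summary in
#'   [glance()].
#' @export
cross_validate <- function(pos, neg, trainer, folds = 5L, seed = 1L) {
  folds <- as.integer(folds)
  if (nrow(pos) < folds || nrow(neg) < folds) {
    stop("each class needs at least `folds` sequences")
  }
  pos$label <- 1L
  neg$label <- -1L
  assign_folds <- function(n) {
    sample(rep_len(seq_len(folds), n))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fp <- assign_folds(nrow(pos))
  fn <- assign_folds(nrow(neg))
  res <- lapply(seq_len(folds), function(f) {
    train <- dplyr::bind_rows(pos[fp != f, ], neg[fn != f, ])
    test <- dplyr::bind_rows(pos[fp == f, ], neg[fn == f, ])
    sc <- trainer(train, test[, c("id", "seq")])
    tibble::tibble(fold = f, auc = roc_auc(sc, test$label),
                   n_train = nrow(train), n_test = nrow(test))
  })
  out <- dplyr::bind_rows(res)
  attr(out, "fold_pos") <- fp
  attr(out, "fold_neg") <- fn
  attr(out, "seed") <- seed
  class(out) <- c("gkm_cv", class(out))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
glance.gkm_cv <- function(x, ...) {
  tibble::tibble(folds = nrow(x), mean_auc = mean(x$auc), sd_auc = sd(x$auc),
                 se_auc = sd(x$auc) / sqrt(nrow(x)))
}

#' @export
autoplot.gkm_cv <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$fold), y = .data$auc)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = g$mean_auc, linetype = 2) +
    ggplot2::labs(x = "Fold", y = "AUC",
                  subtitle = sprintf("mean %.3f +/- %.3f (SD)", g$mean_auc, g$sd_auc)) +
    ggplot2::theme_minimal()
}

#' SVM cross-validation on a precomputed kernel
#'
#' Efficient CV for kernel SVMs: the full normalized kernel is computed
#' once and folds are trained/scored on submatrices (kernel entries use no
#' label information, so there is no leakage).
#'
#' @param K Full `gkm_kernel` over all sequences.
#' @param labels Vector in `{+1,-1}` matching `K` rows.
#' @param folds,seed As in [cross_validate()].
#' @param C Soft-margin cost.
#' @return A `gkm_cv` object.
#' @export
cv_svm_kernel <- function(K, labels, folds = 5L, seed = 1L, C = 1) {
  folds <- as.integer(folds)
  pos_i <- which(labels == 1)
  neg_i <- which(labels == -1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fp <- sample(rep_len(seq_len(folds), length(pos_i)))
  fn <- sample(rep_len(seq_len(folds), length(neg_i)))
  fold_of <- integer(length(labels))
  fold_of[pos_i] <- fp
  fold_of[neg_i] <- fn
  res <- lapply(seq_len(folds), function(f) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    Ktr <- new_gkm_kernel(unclass(K)[tr, tr, drop = FALSE], attr(K, "config"),
                          attr(K, "raw_diag")[tr])
    m <- train_svm(Ktr, labels[tr], C = C)
    sc <- unclass(K)[te, tr[m$sv_index], drop = FALSE] %*% m$coefs + m$offset
    tibble::tibble(fold = f, auc = roc_auc(as.numeric(sc), labels[te]),
                   n_train = length(tr), n_test = length(te))
  })
  out <- dplyr::bind_rows(res)
  attr(out, "seed") <- seed
  class(out) <- c("gkm_cv", class(out))
  out
}
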