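# Classifiers on gapped k-mer features: a soft-margin SVM on the
# precomputed kernel, and a Naive-Bayes classifier on (smoothed) l-mer
# counts.

#' Train an SVM on a precomputed kernel
#'
#' Solves the standard soft-margin dual on the normalized kernel matrix
#' (kernlab's SMO solver). The decision score of a sequence is the
#' support-vector expansion `sum_sv coef_sv * K(seq, sv) + offset`, positive
#' for the +1 class. If the solver rejects a non-PSD matrix (possible for
#' truncated configurations), the smallest ridge `1e-8 * I` is added and a
#' message logged.
#'
#' @param K Training `gkm_kernel` (square, normalized).
#' @param labels Vector in `{+1, -1}`, both classes present.
#' @param C Soft-margin cost (default 1; the benchmark setting).
#' @param tol Solver tolerance (default 1e-6).
#' @param lmers Optional training `lmer_set`; required later by
#'   [decision_scores()] / [score_all_kmers()] on new sequences.
#' @return A `gkm_svm` object.
#' @export
train_svm <- function(K, labels, C = 1, tol = 1e-6, lmers = NULL) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be +1/-1")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (nrow(K) != ncol(K) || nrow(K) != length(labels)) stop("K/labels size mismatch")
  y <- factor(labels, levels = c(-1L, 1L))
  fit <- tryCatch(
    kernlab::ksvm(kernlab::as.kernelMatrix(unclass(K)), y,
                  type = "C-svc", C = C, tol = tol),
    error = function(e) {
      message("kernel rejected by solver (", conditionMessage(e),
              "); retrying with ridge 1e-8")
      Kr <- unclass(K) + diag(1e-8, nrow(K))
      kernlab::ksvm(kernlab::as.kernelMatrix(Kr), y, type = "C-svc",
                    C = C, tol = tol)
    }
  )
  sv <- kernlab::SVindex(fit)
  structure(
    list(sv_index = sv,
         sv_ids = rownames(K)[sv],
         coefs = as.numeric(unlist(kernlab::coef(fit))),
         offset = -kernlab::b(fit),
         C = C, tol = tol,
         labels = labels,
         config = attr(K, "config"),
         train_diag = attr(K, "raw_diag"),
         fitted_decision = as.numeric(
           unclass(K)[, sv, drop = FALSE] %*% as.numeric(unlist(kernlab::coef(fit)))
           - kernlab::b(fit)),
         lmers = lmers),
    class = "gkm_svm"
  )
}

#' @exportS3Method base::print
print.gkm_svm <- function(x, ...) {
  cat(sprintf("<gkm_svm> %d support vectors of %d sequences, C=%g\n",
              length(x$sv_index), length(x$labels), x$C))
  invisible(x)
}

#' @export
tidy.gkm_svm <- function(x, ...) {
  tibble::tibble(id = x$sv_ids %||% as.character(x$sv_index),
                 index = x$sv_index, coef = x$coefs)
}

#' @export
glance.gkm_svm <- function(x, ...) {
  acc <- mean(sign(x$fitted_decision) == x$labels)
  tibble::tibble(n = length(x$labels), n_sv = length(x$sv_index),
                 C = x$C, train_accuracy = acc,
                 train_auc = roc_auc(x$fitted_decision, x$labels))
}

#' SVM decision scores for new sequences
#'
#' Support-vector expansion via the test-by-train cross kernel under the
#' training feature configuration.
#'
#' @param model A `gkm_svm` trained with `lmers` retained.
#' @param test Sequence tibble or `lmer_set`.
#' @return Tibble with columns `id`, `score`.
#' @export
decision_scores <- function(model, test) {
  stopifnot(inherits(model, "gkm_svm"))
  if (is.null(model$lmers)) stop("model was trained without lmers; retrain ",
                                 "with train_svm(..., lmers = )")
  cfg <- model$config
  ts <- if (inherits(test, "lmer_set")) test else
    lmer_set(test, l = cfg$weights$l, include_revcomp = cfg$include_revcomp %||%
               attr(model$lmers, "include_revcomp"))
  sv_set <- structure(model$lmers[model$sv_index],
                      ids = attr(model$lmers, "ids")[model$sv_index],
                      l = attr(model$lmers, "l"), t = attr(model$lmers, "t"),
                      include_revcomp = attr(model$lmers, "include_revcomp"),
                      class = "lmer_set")
  Kc <- cross_kernel(ts, sv_set, cfg$weights, m_max = cfg$m_max,
                     train_diag = model$train_diag[model$sv_index])
  tibble::tibble(id = attr(ts, "ids"),
                 score = as.numeric(unclass(Kc) %*% model$coefs + model$offset))
}

#' Score all w-mers with a trained SVM
#'
#' Each w-mer is treated as a standalone sequence (both strands, per the
#' l-mer convention) and given its SVM decision score; the table is sorted
#' by decreasing weight (ties broken lexicographically). When `w` equals
#' the kernel word length the scores are computed by scattering the
#' support-vector l-mer weights over the full l-mer space, which is exact
#' and fast; otherwise the w-mers are scored through the generic cross
#' kernel.
#'
#' @param model A `gkm_svm` with `lmers` retained.
#' @param w Word length to score (default 10, guarded to `w <= 12`).
#' @return Tibble with columns `kmer`, `weight`, sorted descending.
#' @export
score_all_kmers <- function(model, w = 10L) {
  stopifnot(inherits(model, "gkm_svm"))
  w <- as.integer(w)
  if (w > 12) stop("scoring all w-mers guarded to w <= 12")
  if (is.null(model$lmers)) stop("model was trained without lmers")
  cfg <- model$config
  l <- cfg$weights$l
  if (w == l) {
    sv <- model$lmers[model$sv_index]
    tr <- cpp_pool_lmers(lapply(sv, `[[`, "keys"), lapply(sv, `[[`, "counts"))
    Csv <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                                dims = c(length(tr$keys), length(sv)))
    per_lmer <- as.numeric(Csv %*% (model$coefs / sqrt(model$train_diag[model$sv_index])))
    m_eff <- min(cfg$m_max, l)
    h <- cfg$weights$coef[seq_len(m_eff + 1L)]
    W <- cpp_scatter_lmer_weights(tr$keys, per_lmer, l, m_eff, h)
    rc <- cpp_rc_info(l)
    raw <- W + W[rc$rc + 1]
    self_raw <- 2 * h[1] + ifelse(rc$dist <= m_eff, 2 * h[rc$dist + 1], 0)
    score <- raw / sqrt(self_raw) + model$offset
    kmers <- cpp_keys_to_strings(as.numeric(0:(4^w - 1)), w)
  } else {
    if (w >= 2^26) stop("w too large")
    kmers <- cpp_keys_to_strings(as.numeric(0:(4^w - 1)), w)
    sc <- decision_scores(model, tibble::tibble(id = kmers, seq = kmers))
    score <- sc$score
  }
  out <- tibble::tibble(kmer = kmers, weight = score)
  out[order(-out$weight, out$kmer), ]
}

# ----------------------------------------------------------- Naive Bayes

# pooled l-mer table (keys sorted, aggregated counts) for a sequence set
pool_lmer_table <- function(seqs, l, include_revcomp = TRUE) {
  ls <- if (inherits(seqs, "lmer_set")) seqs else
    lmer_set(seqs, l = l, include_revcomp = include_revcomp)
  keys <- unlist(lapply(ls, `[[`, "keys"))
  cnts <- unlist(lapply(ls, `[[`, "counts"))
  o <- order(keys)
  keys <- keys[o]; cnts <- cnts[o]
  grp <- cumsum(!duplicated(keys))
  list(keys = keys[!duplicated(keys)],
       counts = as.numeric(rowsum(cnts, grp)))
}

#' Train the Naive-Bayes l-mer classifier
#'
#' Stores the positive and negative training l-mer tables (both strands).
#' In filter mode the queried l-mer counts `N_P`, `N_N` are the truncated
#' gkm-filter estimates `sum_m g(m) N_tr(u, m)` with pseudo-count half the
#' smallest positive filter coefficient; in raw mode they are exact counts
#' with pseudo-count 0.5.
#'
#' @param pos,neg Sequence tibbles (columns `id`, `seq`), non-empty.
#' @param l Word length.
#' @param k Informative positions for the filter (default 6, capped at `l`).
#' @param use_filter Use the truncated gkm-filter estimates (default
#'   `TRUE`); `FALSE` gives the raw-count classifier.
#' @return A `gkm_nb` object.
#' @export
nb_train <- function(pos, neg, l, k = min(6L, l), use_filter = TRUE) {
  if (NROW(pos) == 0 || NROW(neg) == 0) stop("both training sets must be non-empty")
  l <- as.integer(l)
  if (use_filter) {
    filt <- truncate_filter(filter_weights(l, k))
    pseudo <- min(filt$g[filt$g > 0]) / 2
    m_sup <- max(which(filt$g != 0)) - 1L
  } else {
    filt <- NULL
    pseudo <- 0.5
    m_sup <- 0L
  }
  structure(
    list(l = l, k = as.integer(k), filter = filt, use_filter = use_filter,
         pseudo = pseudo, m_sup = m_sup,
         pos = pool_lmer_table(pos, l), neg = pool_lmer_table(neg, l)),
    class = "gkm_nb"
  )
}

#' @exportS3Method base::print
print.gkm_nb <- function(x, ...) {
  cat(sprintf("<gkm_nb> l=%d k=%d, %s mode, %d/%d pos/neg table l-mers\n",
              x$l, x$k, if (x$use_filter) "truncated-filter" else "raw-count",
              length(x$pos$keys), length(x$neg$keys)))
  invisible(x)
}

# smoothed (or raw) table counts for a set of query keys
nb_table_counts <- function(model, tab, qkeys) {
  if (!model$use_filter || model$m_sup == 0) {
    idx <- match(qkeys, tab$keys)
    cnt <- ifelse(is.na(idx), 0, tab$counts[idx])
    if (model$use_filter) cnt <- cnt * model$filter$g[1]
    return(cnt + model$pseudo)
  }
  nc <- cpp_neighbor_counts(qkeys, tab$keys, tab$counts, model$l, model$m_sup)
  as.numeric(nc %*% model$filter$g[seq_len(model$m_sup + 1L)]) + model$pseudo
}

# per-key log-likelihood ratios for a batch of query keys
nb_log_ratios <- function(model, qkeys) {
  log(nb_table_counts(model, model$pos, qkeys)) -
    log(nb_table_counts(model, model$neg, qkeys))
}

#' Naive-Bayes sequence scores
#'
#' Without a window, the score of a sequence is the sum over its (forward
#' strand) l-mers of `log(N_P / N_N)`; because the training tables hold both
#' strands, the score is strand-symmetric. With `window = w`, every
#' substring containing `w` consecutive l-mers (length `w + l - 1`) is
#' scored and the maximum taken, which targets single localized binding
#' sites.
#'
#' @param model A `gkm_nb`.
#' @param seqs Sequence tibble (columns `id`, `seq`).
#' @param window Optional window size in l-mers (e.g. 15).
#' @return Tibble with columns `id`, `score`.
#' @export
nb_score <- function(model, seqs, window = NULL) {
  stopifnot(inherits(model, "gkm_nb"))
  l <- model$l
  short <- nchar(seqs$seq) < l + if (is.null(window)) 0L else window - 1L
  if (any(short)) stop("sequence(s) too short to score: ",
                       paste(head(seqs$id[short], 5), collapse = ", "))
  ls <- lmer_set(seqs, l = l, include_revcomp = FALSE)
  qkeys <- sort(unique(unlist(lapply(ls, `[[`, "keys"))))
  ratio <- nb_log_ratios(model, qkeys)
  if (is.null(window)) {
    score <- vapply(ls, function(x) {
      sum(x$counts * ratio[match(x$keys, qkeys)])
    }, numeric(1))
  } else {
    score <- vapply(seq_len(nrow(seqs)), function(i) {
      s <- toupper(seqs$seq[i])
      npos <- nchar(s) - l + 1L
      starts <- seq_len(npos)
      wm <- substring(s, starts, starts + l - 1L)
      ok <- grepl("^[ACGT]+$", wm)
      v <- numeric(npos)
      v[ok] <- ratio[match(cpp_strings_to_keys(wm[ok], l), qkeys)]
      if (npos < window) return(sum(v))
      ws <- stats::filter(v, rep(1, window), sides = 1)
      max(ws[!is.na(ws)])
    }, numeric(1))
  }
  tibble::tibble(id = seqs$id, score = score)
}
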