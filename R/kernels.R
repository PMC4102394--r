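# Kernel assembly.
#
# raw(i, j) = sum_m coef[m] * N_m(S_i, S_j); the kernel is the normalized
# form raw(i,j)/sqrt(raw(i,i) raw(j,j)), so K(S, S) = 1. Feature-space
# oracles (explicit gapped k-mer vectors and l-mer estimate vectors) are
# guarded to small l and exist as test arbiters; production paths never
# materialize feature vectors.

new_gkm_kernel <- function(values, config, raw_diag_a, raw_diag_b = raw_diag_a) {
  structure(values, config = config, raw_diag = raw_diag_a,
            raw_diag_cols = raw_diag_b, class = c("gkm_kernel", "matrix"))
}

#' @exportS3Method base::print
print.gkm_kernel <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<gkm_kernel> %d x %d, variant=%s l=%d%s m_max=%s\n",
              nrow(x), ncol(x), cfg$weights$variant, cfg$weights$l,
              if (!is.null(cfg$weights$k)) paste0(" k=", cfg$weights$k) else "",
              cfg$m_max))
  invisible(x)
}

#' Assemble a kernel matrix from mismatch profiles
#'
#' @param profiles A `gkm_profiles` object.
#' @param weights A `gkm_weights` coefficient family with matching `l`.
#' @param normalize Normalize to unit diagonal (the kernel proper); raw
#'   values are kept for diagnostics in `attr(, "raw_diag")`.
#' @return A `gkm_kernel` matrix (ids as dimnames).
#' @export
kernel_from_profiles <- function(profiles, weights, normalize = TRUE) {
  stopifnot(inherits(profiles, "gkm_profiles"), inherits(weights, "gkm_weights"))
  if (weights$l != profiles$l) stop("weights l does not match profiles l")
  nm <- profiles$m_max + 1L
  coef <- weights$coef[seq_len(nm)]
  dn <- dim(profiles$counts)
  raw <- matrix(0, dn[1], dn[2], dimnames = list(profiles$ids_a, profiles$ids_b))
  for (m in seq_len(nm)) {
    if (coef[m] != 0) raw <- raw + coef[m] * profiles$counts[, , m]
  }
  cfg <- list(weights = weights, m_max = profiles$m_max)
  if (!normalize) return(new_gkm_kernel(raw, cfg, diag(raw)))
  if (!identical(profiles$ids_a, profiles$ids_b)) {
    stop("normalization requires a square profile set; use cross_kernel() ",
         "for test x train similarity")
  }
  d <- diag(raw)
  if (any(d <= 0)) {
    stop("zero raw self-similarity for sequence(s): ",
         paste(profiles$ids_a[d <= 0], collapse = ", "),
         " (no valid l-mers?)")
  }
  new_gkm_kernel(raw / sqrt(d %o% d), cfg, d)
}

# raw self-similarity of each sequence in an lmer_set under a coefficient
# family (and mismatch cap); needed for cross-kernel normalization.
raw_self_similarity <- function(ls, weights, m_max) {
  vapply(seq_along(ls), function(i) {
    pr <- cpp_profiles_direct(list(ls[[i]]$keys), list(ls[[i]]$counts),
                              list(ls[[i]]$keys), list(ls[[i]]$counts),
                              attr(ls, "l"), as.integer(m_max), TRUE)
    sum(weights$coef[seq_len(m_max + 1L)] * pr[1, 1, ])
  }, numeric(1))
}

#' Training kernel for a sequence set
#'
#' One-call pipeline: l-mer extraction, mismatch profiles and normalized
#' kernel. `algorithm = "auto"` uses the pooled exact-match path when
#' `l = k` or `m_max = 0` (spectrum kernel: a sparse count-matrix cross
#' product), the tree traversal for long words (sparse leaves), and direct
#' comparison otherwise; both profile algorithms are available explicitly.
#'
#' @param seqs Sequence tibble (`id`, `seq`) or an `lmer_set`.
#' @param l,k Word length and informative positions (defaults l=10, k=6).
#' @param weights Optional `gkm_weights` to use instead of the gkm family
#'   (e.g. wildcard/mismatch/estimate coefficients).
#' @param m_max Mismatch cap; default `l - k` for the gkm family (exact,
#'   since `coef[m] = 0` beyond), otherwise `l`.
#' @param include_revcomp Use both strands (default `TRUE`).
#' @param algorithm `"auto"`, `"tree"`, `"direct"` or `"spectrum"`.
#' @param normalize Normalize to unit diagonal (default `TRUE`).
#' @return A `gkm_kernel` matrix.
#' @export
gkm_kernel <- function(seqs, l = 10L, k = 6L, weights = NULL, m_max = NULL,
                       include_revcomp = TRUE,
                       algorithm = c("auto", "tree", "direct", "spectrum"),
                       normalize = TRUE) {
  algorithm <- match.arg(algorithm)
  ls <- if (inherits(seqs, "lmer_set")) seqs else {
    if (!is.null(weights)) l <- weights$l
    lmer_set(seqs, l = l, include_revcomp = include_revcomp)
  }
  l <- attr(ls, "l")
  if (is.null(weights)) weights <- gkm_coefficients(l, k)
  if (weights$l != l) stop("weights l does not match the l-mer set")
  if (is.null(m_max)) {
    nz <- which(weights$coef != 0)
    m_max <- if (length(nz)) max(nz) - 1L else 0L
  }
  m_max <- as.integer(min(m_max, l))
  if (algorithm == "auto") {
    algorithm <- if (m_max == 0) "spectrum" else if (l >= 8) "tree" else "direct"
  }
  if (algorithm == "spectrum" && m_max > 0 && any(weights$coef[-1] != 0)) {
    stop("spectrum path only valid when coefficients vanish for m > 0")
  }
  cfg <- list(weights = weights, m_max = m_max,
              include_revcomp = attr(ls, "include_revcomp"))
  if (algorithm == "spectrum") {
    C <- lmer_count_matrix(ls)
    raw <- weights$coef[1] * as.matrix(Matrix::crossprod(C))
    dimnames(raw) <- list(attr(ls, "ids"), attr(ls, "ids"))
    if (!normalize) return(new_gkm_kernel(raw, cfg, diag(raw)))
    d <- diag(raw)
    if (any(d <= 0)) stop("zero raw self-similarity for sequence(s): ",
                          paste(attr(ls, "ids")[d <= 0], collapse = ", "))
    return(new_gkm_kernel(raw / sqrt(d %o% d), cfg, d))
  }
  pr <- if (algorithm == "tree") profiles_tree(ls, m_max = m_max)
        else profiles_direct(ls, m_max = m_max)
  kernel_from_profiles(pr, weights, normalize = normalize)
}

# sparse (pooled unique l-mer) x sequence count matrix
lmer_count_matrix <- function(ls) {
  tr <- cpp_pool_lmers(lapply(ls, `[[`, "keys"), lapply(ls, `[[`, "counts"))
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(length(tr$keys), length(ls)))
}

#' Test-by-train cross kernel
#'
#' Normalized similarity of each test sequence to each training sequence,
#' using the test sequences' own raw self-similarity and the supplied (or
#' recomputed) training diagonal, under the same feature configuration as
#' training.
#'
#' @param test,train `lmer_set` objects sharing `l` and strand convention.
#' @param weights `gkm_weights` family.
#' @param m_max Mismatch cap (must match training).
#' @param train_diag Precomputed raw training self-similarities (optional).
#' @return A `gkm_kernel` matrix, rows = test, columns = train.
#' @export
cross_kernel <- function(test, train, weights, m_max = NULL, train_diag = NULL) {
  stopifnot(inherits(test, "lmer_set"), inherits(train, "lmer_set"))
  l <- attr(train, "l")
  if (attr(test, "l") != l) stop("config mismatch: test l != train l")
  if (attr(test, "include_revcomp") != attr(train, "include_revcomp")) {
    stop("config mismatch: strand conventions differ")
  }
  if (weights$l != l) stop("config mismatch: weights l != train l")
  if (is.null(m_max)) {
    nz <- which(weights$coef != 0)
    m_max <- if (length(nz)) max(nz) - 1L else 0L
  }
  m_max <- as.integer(min(m_max, l))
  pr <- profiles_direct(test, train, m_max = m_max)
  raw <- kernel_from_profiles(pr, weights, normalize = FALSE)
  d_test <- raw_self_similarity(test, weights, m_max)
  if (is.null(train_diag)) train_diag <- raw_self_similarity(train, weights, m_max)
  if (length(train_diag) != length(train)) stop("train_diag length mismatch")
  vals <- unclass(raw) / sqrt(d_test %o% train_diag)
  new_gkm_kernel(vals, list(weights = weights, m_max = m_max), d_test, train_diag)
}

#' Explicit gapped k-mer feature vector (oracle)
#'
#' For each l-mer and each of the `choose(l, k)` position subsets, the
#' (subset, letters) feature is incremented by the l-mer's occurrence
#' count; total mass is `n * choose(l, k)`. Materialized only for small l;
#' used to verify the profile-based kernels against normalized feature-space
#' dot products.
#'
#' @param lmers An `lmer_list`.
#' @param k Informative positions.
#' @return Named numeric vector of length `choose(l,k) * 4^k`.
#' @export
gapped_kmer_vector <- function(lmers, k) {
  stopifnot(inherits(lmers, "lmer_list"))
  l <- lmers$l
  if (l > 8) stop("explicit gapped k-mer vectors guarded to l <= 8")
  if (k < 1 || k > l) stop("need 1 <= k <= l")
  strs <- cpp_keys_to_strings(lmers$keys, l)
  codes <- matrix(match(unlist(strsplit(strs, "")), c("A", "C", "G", "T")) - 1L,
                  ncol = l, byrow = TRUE)
  subsets <- utils::combn(l, k, simplify = FALSE)
  v <- numeric(length(subsets) * 4^k)
  pow <- 4^((k - 1):0)
  for (si in seq_along(subsets)) {
    sub <- codes[, subsets[[si]], drop = FALSE]
    idx <- as.integer(sub %*% pow) + 1L + (si - 1L) * 4^k
    for (r in seq_along(idx)) v[idx[r]] <- v[idx[r]] + lmers$counts[r]
  }
  names(v) <- paste0(
    rep(vapply(subsets, function(p) paste0("pos{", paste(p, collapse = ","), "}"),
               character(1)), each = 4^k),
    ":", rep(cpp_keys_to_strings(as.numeric(0:(4^k - 1)), k), length(subsets))
  )
  v
}

#' Smoothed l-mer count-estimate vector (oracle)
#'
#' The estimate for every l-mer `u` is `sum_m g(m) * N(u, m)` with
#' `N(u, m)` the number of observed l-mers at distance `m`. With the full
#' filter, applying the incidence matrix `A` to this vector reproduces the
#' sequence's gapped k-mer counts exactly (projection property). Dense over
#' all `4^l` l-mers, guarded to small l.
#'
#' @param lmers An `lmer_list`.
#' @param filter A `gkm_filter` with matching `l`.
#' @return Numeric vector of length `4^l`, named by l-mer.
#' @export
lmer_estimate_vector <- function(lmers, filter) {
  stopifnot(inherits(lmers, "lmer_list"), inherits(filter, "gkm_filter"))
  l <- lmers$l
  if (filter$l != l) stop("filter l does not match")
  if (l > 8) stop("dense estimate vectors guarded to l <= 8")
  all_keys <- as.numeric(0:(4^l - 1))
  # distances of every l-mer to each observed l-mer, via 2-bit XOR popcount
  est <- numeric(4^l)
  for (j in seq_along(lmers$keys)) {
    d <- cpp_hamming_keys(all_keys, rep(lmers$keys[j], 4^l))
    est <- est + lmers$counts[j] * filter$g[d + 1]
  }
  names(est) <- cpp_keys_to_strings(all_keys, l)
  est
}

#' @export
autoplot.gkm_kernel <- function(object, ...) {
  df <- tibble::tibble(
    i = factor(rep(rownames(object), ncol(object)), levels = rev(rownames(object))),
    j = factor(rep(colnames(object), each = nrow(object)), levels = colnames(object)),
    K = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$K)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "K") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
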