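# Distance-indexed kernel coefficient families.
#
# Every kernel in this framework is a weighted sum over the mismatch profile:
# raw K(S1,S2) = sum_m coef[m] * N_m(S1,S2). The families differ only in
# coef[m]: shared gapped k-mer counts (gkm), shared wildcard patterns,
# Hamming-ball intersections (mismatch kernel), or inner products of
# smoothed l-mer count estimates. All coefficient sums are evaluated in
# exact integer arithmetic (binomials with out-of-range arguments are 0, so
# sums self-truncate) and divided by a power of the alphabet size only at
# the end.

new_gkm_weights <- function(variant, l, coef, k = NULL, M = NULL,
                            lambda = NULL, b = 4L) {
  structure(
    list(variant = variant, l = as.integer(l), k = k, M = M,
         lambda = lambda, b = as.integer(b), coef = as.numeric(coef)),
    class = "gkm_weights"
  )
}

#' @exportS3Method base::print
print.gkm_weights <- function(x, ...) {
  cat(sprintf("<gkm_weights> variant=%s l=%d%s%s\n", x$variant, x$l,
              if (!is.null(x$k)) paste0(" k=", x$k) else "",
              if (!is.null(x$M)) paste0(" M=", x$M) else ""))
  print(setNames(x$coef, paste0("m=", seq_along(x$coef) - 1L)))
  invisible(x)
}

#' @export
tidy.gkm_weights <- function(x, ...) {
  tibble::tibble(m = seq_along(x$coef) - 1L, coef = x$coef)
}

#' Gapped k-mer kernel coefficients
#'
#' Two l-mers at Hamming distance `m` share exactly `choose(l - m, k)`
#' gapped k-mers (`k` informative positions chosen among the `l - m`
#' matching ones), which is the weight an l-mer pair at distance `m`
#' contributes to the kernel. `l = k` reduces to the ungapped spectrum
#' (k-mer) kernel.
#'
#' @param l Word length.
#' @param k Number of informative (non-gap) positions, `1 <= k <= l`.
#' @return A `gkm_weights` object with `coef[m + 1] = choose(l - m, k)`.
#' @export
gkm_coefficients <- function(l, k) {
  l <- as.integer(l); k <- as.integer(k)
  if (k < 1 || k > l) stop("need 1 <= k <= l (got k=", k, ", l=", l, ")")
  new_gkm_weights("gkm", l, choose(l - 0:l, k), k = k)
}

#' Wildcard kernel coefficients
#'
#' Features are l-mers with up to `M` wildcard positions, a pattern with `j`
#' wildcards weighted `lambda^j`. A pattern matches both l-mers of a pair at
#' distance `m` iff its wildcards cover all `m` mismatch positions, so there
#' are `choose(l - m, j - m)` such patterns with `j` wildcards. The weight
#' enters once per shared pattern (`lambda^j`, not squared); at the
#' benchmark setting `lambda = 1` the convention is immaterial.
#'
#' @param l Word length.
#' @param M Maximum number of wildcards, `0 <= M <= l`.
#' @param lambda Wildcard penalty base (> 0), default 1.
#' @return A `gkm_weights` object.
#' @export
wildcard_coefficients <- function(l, M, lambda = 1) {
  l <- as.integer(l); M <- as.integer(M)
  if (M < 0 || M > l) stop("need 0 <= M <= l")
  if (lambda <= 0) stop("lambda must be positive")
  coef <- vapply(0:l, function(m) {
    j <- seq.int(m, M)
    if (m > M) 0 else sum(lambda^j * choose(l - m, j - m))
  }, numeric(1))
  new_gkm_weights("wildcard", l, coef, M = M, lambda = lambda)
}

# Number of l-mers u at distance m1 from x1 and m2 from x2, where x1 and x2
# differ at m positions and t of u's mismatches with x1 fall among the l - m
# common positions; r = m1 + m2 - 2t - m of the mismatch positions carry a
# letter differing from both. Out-of-range binomials vanish.
pair_ball_count <- function(l, m, m1, m2, t, b) {
  r <- m1 + m2 - 2 * t - m
  if (r < 0) return(0)
  choose(l - m, t) * (b - 1)^t * choose(m, m1 - t) * choose(m1 - t, r) * (b - 2)^r
}

#' Mismatch kernel coefficients
#'
#' Features are all l-mers within Hamming distance `M` of an observed l-mer,
#' so the pair weight at distance `m` is the size of the intersection of the
#' two radius-`M` Hamming balls, evaluated by the closed-form triple sum
#' over `(m1, m2, t)`.
#'
#' @param l Word length.
#' @param M Maximum mismatches, `0 <= M <= l`.
#' @param b Alphabet size (4 for DNA).
#' @return A `gkm_weights` object.
#' @export
mismatch_coefficients <- function(l, M, b = 4L) {
  l <- as.integer(l); M <- as.integer(M)
  if (M < 0 || M > l) stop("need 0 <= M <= l")
  if (b < 2) stop("alphabet size b must be >= 2")
  coef <- vapply(0:l, function(m) {
    tot <- 0
    for (m1 in 0:M) for (m2 in 0:M) for (t in 0:m1)
      tot <- tot + pair_ball_count(l, m, m1, m2, t, b)
    tot
  }, numeric(1))
  new_gkm_weights("mismatch", l, coef, M = M, b = b)
}

#' Incidence matrix between gapped k-mers and l-mers
#'
#' Binary matrix `A` with one row per gapped k-mer (a size-`k` position
#' subset together with `k` letters) and one column per l-mer;
#' `A[i, j] = 1` iff gapped k-mer `i` matches l-mer `j`. Row sums are
#' `b^(l-k)` and column sums `choose(l, k)`. Materialized only for small
#' `l` (the closed forms below cover the general case).
#'
#' @param l Word length (guarded to `l <= 6`).
#' @param k Informative positions.
#' @param b Alphabet size.
#' @return Binary matrix of dimension `choose(l,k) * b^k` by `b^l`.
#' @export
incidence_matrix <- function(l, k, b = 4L) {
  l <- as.integer(l); k <- as.integer(k); b <- as.integer(b)
  if (k < 1 || k > l) stop("need 1 <= k <= l")
  if (l > 6) stop("incidence matrix guarded to l <= 6; use filter_weights() ",
                  "for the closed-form coefficients")
  lmers <- as.matrix(expand.grid(rep(list(seq_len(b)), l)))[, l:1, drop = FALSE]
  subsets <- utils::combn(l, k, simplify = FALSE)
  letters_grid <- as.matrix(expand.grid(rep(list(seq_len(b)), k)))[, k:1, drop = FALSE]
  A <- matrix(0L, nrow = length(subsets) * b^k, ncol = b^l)
  row <- 0L
  for (P in subsets) {
    sub <- lmers[, P, drop = FALSE]
    for (z in seq_len(nrow(letters_grid))) {
      row <- row + 1L
      A[row, ] <- as.integer(colSums(t(sub) == letters_grid[z, ]) == k)
    }
  }
  if (b == 4) {
    colnames(A) <- apply(lmers, 1, function(r) paste(c("A", "C", "G", "T")[r], collapse = ""))
  }
  A
}

# Projection kernel onto the span of gapped k-mer indicator functions
# (equivalently, functions of polynomial degree <= k on the Hamming scheme):
# g_lk(m) = b^-l * sum_{i=0..k} K_i(m), with K_i the Krawtchouk polynomial
# K_i(m) = sum_j (-1)^j (b-1)^(i-j) C(m,j) C(l-m,i-j). This is the distance
# profile of G = pinv(A) %*% A; the numerical pseudo-inverse is the test
# oracle at small (l,k). The integer numerator is formed exactly before the
# single division by b^l.
krawtchouk_sum <- function(l, k, m, b) {
  tot <- 0
  for (i in 0:k) {
    j <- 0:i
    tot <- tot + sum((-1)^j * (b - 1)^(i - j) * choose(m, j) * choose(l - m, i - j))
  }
  tot
}

#' Gapped k-mer filter weights
#'
#' The filter `g_lk(m)` maps observed l-mer counts to minimum-norm l-mer
#' count estimates: the estimate for l-mer `u` is
#' `sum_m g(m) * N_tr(u, m)` with `N_tr(u, m)` the number of observed
#' l-mers at distance `m`. `g` is the distance profile of
#' `G = pinv(A) %*% A` (orthogonal projection onto the gapped k-mer count
#' space) and equals `sum_t choose(m,t) choose(l-m,k-t) w(t)` with `w(t)`
#' the pseudo-inverse weight; both `g` and `w` are returned. `l = k` gives
#' the identity filter.
#'
#' @param l Word length.
#' @param k Informative positions.
#' @param b Alphabet size.
#' @return A `gkm_filter` object: fields `g` (length `l + 1`), `w`
#'   (pseudo-inverse weights, length `k + 1`), `truncated`, `m0`.
#' @export
filter_weights <- function(l, k, b = 4L) {
  l <- as.integer(l); k <- as.integer(k)
  if (k < 1 || k > l) stop("need 1 <= k <= l")
  g <- vapply(0:l, function(m) krawtchouk_sum(l, k, m, b), numeric(1)) / b^l
  # recover w(t) from g(m) = sum_t C(m,t) C(l-m,k-t) w(t), m = 0..k
  # (lower-triangular in (m, t) since C(m,t) = 0 for t > m)
  Mmat <- outer(0:k, 0:k, function(m, t) choose(m, t) * choose(l - m, k - t))
  w <- backsolve(t(Mmat), g[1:(k + 1)], upper.tri = TRUE, transpose = TRUE)
  structure(
    list(l = l, k = k, b = as.integer(b), g = g, w = as.numeric(w),
         truncated = FALSE, m0 = NA_integer_),
    class = "gkm_filter"
  )
}

#' @exportS3Method base::print
print.gkm_filter <- function(x, ...) {
  cat(sprintf("<gkm_filter> l=%d k=%d%s\n", x$l, x$k,
              if (x$truncated) sprintf(" truncated (m0=%d)", x$m0) else " (full)"))
  print(setNames(signif(x$g, 4), paste0("m=", 0:x$l)))
  invisible(x)
}

#' @export
tidy.gkm_filter <- function(x, ...) {
  tibble::tibble(m = 0:x$l, g = x$g)
}

#' Truncate a gkm-filter at its first negative weight
#'
#' The minimum-norm estimates are not sign-constrained and `g(m)` can go
#' slightly negative at large `m`; for uses that need strictly non-negative
#' estimates (log-likelihoods), all weights at and beyond the first negative
#' entry `m0` are zeroed. Idempotent; if no entry is negative, `m0` is the
#' sentinel `l + 1`.
#'
#' @param filter A `gkm_filter`.
#' @return The truncated `gkm_filter`.
#' @export
truncate_filter <- function(filter) {
  stopifnot(inherits(filter, "gkm_filter"))
  if (filter$truncated) return(filter)
  neg <- which(filter$g < 0)
  m0 <- if (length(neg)) neg[1] - 1L else filter$l + 1L
  g <- filter$g
  if (m0 <= filter$l) g[(m0 + 1):(filter$l + 1)] <- 0
  filter$g <- g
  filter$truncated <- TRUE
  filter$m0 <- m0
  filter
}

#' Kernel coefficients for l-mer count estimates
#'
#' The linear kernel on smoothed l-mer count-estimate vectors is again a
#' weighted sum over the mismatch profile, with weights
#' `c_m = sum_u g(d(u, u1)) g(d(u, u2))` over all l-mers `u`, for any pair
#' `(u1, u2)` at distance `m`. Evaluated by the closed-form sum over
#' `(m1, m2, t)` with the pair-ball multiplicities; for the full filter
#' `c_m` equals `g(m)` itself (projection idempotence), while the truncated
#' filter requires the explicit sum.
#'
#' @param filter A `gkm_filter` (full or truncated).
#' @return A `gkm_weights` object, variant `estimate_full` or
#'   `estimate_truncated`.
#' @export
estimate_kernel_coefficients <- function(filter) {
  stopifnot(inherits(filter, "gkm_filter"))
  l <- filter$l; b <- filter$b; g <- filter$g
  coef <- vapply(0:l, function(m) {
    tot <- 0
    for (m1 in 0:l) {
      if (g[m1 + 1] == 0) next
      for (m2 in 0:l) {
        if (g[m2 + 1] == 0) next
        for (t in 0:m1) {
          cnt <- pair_ball_count(l, m, m1, m2, t, b)
          if (cnt > 0) tot <- tot + g[m1 + 1] * g[m2 + 1] * cnt
        }
      }
    }
    tot
  }, numeric(1))
  new_gkm_weights(if (filter$truncated) "estimate_truncated" else "estimate_full",
                  l, coef, k = filter$k, b = b)
}
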