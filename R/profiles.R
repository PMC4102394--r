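# Mismatch profiles.
#
# N_m(S_i, S_j) counts the l-mer pairs (one from each sequence) at Hamming
# distance m; it is the sufficient statistic for every kernel in this
# framework. Two algorithms compute it: direct all-pairs comparison over the
# deduplicated l-mer lists (bitwise XOR distance, occurrence counts
# multiplied), and a depth-first traversal of a k-mer tree holding the
# pooled l-mers, which computes all pairs simultaneously and prunes at
# m_max. The two agree exactly (integer counts).

new_gkm_profiles <- function(counts, ids_a, ids_b, l, m_max, truncated) {
  structure(
    list(counts = counts, ids_a = ids_a, ids_b = ids_b, l = l,
         m_max = m_max, truncated = truncated),
    class = "gkm_profiles"
  )
}

#' @exportS3Method base::print
print.gkm_profiles <- function(x, ...) {
  cat(sprintf("<gkm_profiles> %d x %d sequence pairs, l=%d, m = 0..%d%s\n",
              length(x$ids_a), length(x$ids_b), x$l, x$m_max,
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' @export
tidy.gkm_profiles <- function(x, ...) {
  dn <- dim(x$counts)
  tibble::tibble(
    i = rep(x$ids_a, times = dn[2] * dn[3]),
    j = rep(rep(x$ids_b, each = dn[1]), times = dn[3]),
    m = rep(0:(dn[3] - 1L), each = dn[1] * dn[2]),
    count = as.vector(x$counts)
  )
}

#' Mismatch profiles by direct all-pairs comparison
#'
#' Compares every pair of distinct l-mers once and multiplies occurrence
#' counts. With `setB = NULL` all pairs within `setA` (including self-pairs,
#' needed for diagonal normalization) are computed.
#'
#' @param setA,setB `lmer_set` objects sharing `l` (or `setB = NULL`).
#' @param m_max Optional cap on counted mismatches; counts are reported for
#'   `m <= m_max` only. Default `l` (exact).
#' @return A `gkm_profiles` object whose `counts` is an
#'   `nA x nB x (m_max+1)` array.
#' @export
profiles_direct <- function(setA, setB = NULL, m_max = NULL) {
  stopifnot(inherits(setA, "lmer_set"))
  l <- attr(setA, "l")
  symmetric <- is.null(setB)
  if (symmetric) setB <- setA
  stopifnot(inherits(setB, "lmer_set"))
  if (attr(setB, "l") != l) stop("l mismatch between sets")
  if (is.null(m_max)) m_max <- l
  if (m_max > l) stop("m_max cannot exceed l")
  ka <- lapply(setA, `[[`, "keys"); ca <- lapply(setA, `[[`, "counts")
  kb <- lapply(setB, `[[`, "keys"); cb <- lapply(setB, `[[`, "counts")
  counts <- cpp_profiles_direct(ka, ca, kb, cb, l, as.integer(m_max), symmetric)
  new_gkm_profiles(counts, attr(setA, "ids"), attr(setB, "ids"),
                   l, as.integer(m_max), m_max < l)
}

#' Mismatch profiles via the k-mer tree traversal
#'
#' Builds one tree over the pooled l-mers of all sequences (a leaf stores
#' each l-mer's per-sequence occurrence list) and accumulates all pairwise
#' profiles, including self-pairs, in a single depth-first traversal that
#' carries same-depth partner lists with running distances and prunes
#' branches exceeding `m_max`. Identical to [profiles_direct()] restricted
#' to `m <= m_max`.
#'
#' @param seqs An `lmer_set`.
#' @param m_max Mismatch cap (default `l`, exact).
#' @return A `gkm_profiles` object (square array).
#' @export
profiles_tree <- function(seqs, m_max = NULL) {
  stopifnot(inherits(seqs, "lmer_set"))
  l <- attr(seqs, "l")
  if (is.null(m_max)) m_max <- l
  if (m_max > l) stop("m_max cannot exceed l")
  counts <- cpp_profiles_tree(lapply(seqs, `[[`, "keys"),
                              lapply(seqs, `[[`, "counts"),
                              l, as.integer(m_max))
  new_gkm_profiles(counts, attr(seqs, "ids"), attr(seqs, "ids"),
                   l, as.integer(m_max), m_max < l)
}
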