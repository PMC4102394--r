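# Brute-force oracles and small fixtures shared across tests. Everything
# here enumerates explicitly and stays independent of the closed-form /
# bitwise production paths it arbitrates.

DNA <- c("A", "C", "G", "T")

random_dna <- function(len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA, len, replace = TRUE, prob = p), collapse = "")
}

seq_tbl <- function(seqs, prefix = "s") {
  tibble::tibble(id = paste0(prefix, seq_along(seqs)), seq = seqs)
}

# naive per-position Hamming distance on strings
naive_mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all strings over DNA of length l (lexicographic)
all_words <- function(l) {
  if (l == 0) return("")
  do.call(paste0, rev(expand.grid(rep(list(DNA), l))[, l:1, drop = FALSE]))
}

# oracle: number of gapped k-mers (position subset + letters) matching both
# l-mers, by explicit enumeration of subsets
oracle_gkm_coef <- function(x1, x2, k) {
  a <- strsplit(x1, "")[[1]]
  b <- strsplit(x2, "")[[1]]
  subs <- utils::combn(length(a), k, simplify = FALSE)
  sum(vapply(subs, function(P) all(a[P] == b[P]), logical(1)))
}

# oracle: wildcard patterns with <= M wildcards matching both l-mers,
# weighted lambda^(number of wildcards)
oracle_wildcard_coef <- function(x1, x2, M, lambda = 1) {
  a <- strsplit(x1, "")[[1]]
  b <- strsplit(x2, "")[[1]]
  l <- length(a)
  tot <- 0
  for (j in 0:M) {
    if (j == 0) {
      tot <- tot + all(a == b) * lambda^0
    } else {
      for (W in utils::combn(l, j, simplify = FALSE)) {
        if (all(a[-W] == b[-W]) || j == l) tot <- tot + lambda^j
      }
    }
  }
  tot
}

# oracle: size of the intersection of radius-M Hamming balls
oracle_mismatch_coef <- function(x1, x2, M) {
  words <- all_words(nchar(x1))
  sum(vapply(words, function(u) {
    naive_mismatches(u, x1) <= M && naive_mismatches(u, x2) <= M
  }, logical(1)))
}

# oracle: mismatch profile of two l-mer string multisets by direct counting
oracle_profile <- function(lmers1, lmers2, l) {
  counts <- numeric(l + 1)
  for (a in lmers1) for (b in lmers2) {
    m <- naive_mismatches(a, b)
    counts[m + 1] <- counts[m + 1] + 1
  }
  counts
}

# forward-strand l-mer strings of a sequence (valid windows only)
string_lmers <- function(seq, l, revcomp = TRUE) {
  s <- toupper(seq)
  n <- nchar(s)
  out <- character(0)
  strands <- if (revcomp) c(s, as.character(reverse_complement(s))) else s
  for (str in strands) {
    for (i in seq_len(n - l + 1)) {
      w <- substr(str, i, i + l - 1)
      if (grepl("^[ACGT]+$", w)) out <- c(out, w)
    }
  }
  out
}
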