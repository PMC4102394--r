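test_that("profile kernel equals the normalized gapped k-mer dot product", {
  set.seed(21)
  for (rep in 1:10) {
    seqs <- seq_tbl(vapply(1:5, function(i) random_dna(sample(10:40, 1)),
                           character(1)))
    for (l in 2:4) for (k in 1:(l - 1)) {
      ls <- lmer_set(seqs, l = l)
      K <- gkm_kernel(ls, k = k, algorithm = "direct")
      V <- vapply(seq_along(ls), function(i) gapped_kmer_vector(ls[[i]], k),
                  numeric(choose(l, k) * 4^k))
      Ko <- crossprod(V)
      Ko <- Ko / sqrt(diag(Ko) %o% diag(Ko))
      expect_lt(max(abs(unclass(K) - Ko)), 1e-10)
    }
  }
})

test_that("kernel normalization: identical sequences score 1, disjoint 0", {
  ls <- lmer_set(seq_tbl(c("ACGTACGT", "ACGTACGT")), l = 3)
  K <- gkm_kernel(ls, k = 2)
  expect_equal(unclass(K), matrix(1, 2, 2), ignore_attr = TRUE)

  ls2 <- lmer_set(seq_tbl(c("AAAA", "CCCC")), l = 2, include_revcomp = FALSE)
  K2 <- gkm_kernel(ls2, k = 1, algorithm = "direct")
  expect_equal(K2[1, 2], 0)
  expect_equal(diag(unclass(K2)), c(1, 1), ignore_attr = TRUE)
})

test_that("a sequence with no valid l-mers is reported by name", {
  ls <- lmer_set(seq_tbl(c("ACGTAC", "NNNNNN")), l = 3)
  expect_error(gkm_kernel(ls, k = 2, algorithm = "direct"), "s2")
})

test_that("gapped k-mer vectors: mass, guards and hand counts", {
  x <- extract_lmers("AAAA", 2, include_revcomp = FALSE)
  v <- gapped_kmer_vector(x, 1)
  expect_equal(sum(v), x$n * choose(2, 1))
  expect_equal(unname(v[v != 0]), c(3, 3))
  expect_equal(names(v[v != 0]), c("pos{1}:A", "pos{2}:A"))

  # l = k reduces to the plain l-mer count vector
  y <- extract_lmers("ACGTT", 2, include_revcomp = FALSE)
  vk <- gapped_kmer_vector(y, 2)
  expect_equal(unname(vk[c("pos{1,2}:AC", "pos{1,2}:CG", "pos{1,2}:GT", "pos{1,2}:TT")]),
               c(1, 1, 1, 1))
})

test_that("estimate vectors satisfy the projection property A c = y", {
  set.seed(23)
  for (lk in list(c(2, 1), c(3, 2), c(4, 2))) {
    l <- lk[1]; k <- lk[2]
    x <- extract_lmers(random_dna(20), l)
    f <- filter_weights(l, k)
    est <- lmer_estimate_vector(x, f)
    A <- incidence_matrix(l, k)
    y <- gapped_kmer_vector(x, k)
    expect_lt(max(abs(as.numeric(A %*% est) - unname(y))), 1e-8)
  }
})

test_that("estimate vectors smooth into unseen neighbours; identity at l = k", {
  x <- extract_lmers("AAAA", 3, include_revcomp = FALSE) # only AAA observed
  f <- filter_weights(3, 2)
  est <- lmer_estimate_vector(x, f)
  expect_equal(unname(est["AAC"]), 2 * f$g[2]) # one mismatch from AAA (count 2)
  expect_true(est["AAC"] != 0)

  fI <- filter_weights(3, 3)
  estI <- lmer_estimate_vector(x, fI)
  expect_equal(unname(estI["AAA"]), 2)
  expect_equal(sum(estI != 0), 1)
})

test_that("estimate-kernel coefficients reproduce the estimate-vector Gram", {
  set.seed(25)
  seqs <- seq_tbl(vapply(1:4, function(i) random_dna(15), character(1)))
  for (truncated in c(FALSE, TRUE)) {
    f <- filter_weights(3, 2)
    if (truncated) f <- truncate_filter(f)
    ls <- lmer_set(seqs, l = 3)
    K <- gkm_kernel(ls, weights = estimate_kernel_coefficients(f),
                    algorithm = "direct", normalize = FALSE)
    V <- vapply(seq_along(ls), function(i) lmer_estimate_vector(ls[[i]], f),
                numeric(64))
    expect_lt(max(abs(unclass(K) - crossprod(V))), 1e-8)
  }
})

test_that("l = k reproduces the spectrum kernel on every path", {
  set.seed(27)
  seqs <- seq_tbl(vapply(1:8, function(i) random_dna(30), character(1)))
  ls <- lmer_set(seqs, l = 4)
  Kd <- gkm_kernel(ls, k = 4, algorithm = "direct")
  Ks <- gkm_kernel(ls, k = 4, algorithm = "spectrum")
  expect_equal(unclass(Kd), unclass(Ks), tolerance = 1e-12, ignore_attr = TRUE)
  # explicit l-mer count dot product
  V <- vapply(seq_along(ls), function(i) gapped_kmer_vector(ls[[i]], 4),
              numeric(256))
  Ko <- crossprod(V)
  Ko <- Ko / sqrt(diag(Ko) %o% diag(Ko))
  expect_lt(max(abs(unclass(Kd) - Ko)), 1e-12)
})

test_that("raw kernel entries are monotone non-decreasing in m_max", {
  set.seed(29)
  ls <- lmer_set(seq_tbl(vapply(1:6, function(i) random_dna(40), character(1))),
                 l = 6)
  w <- gkm_coefficients(6, 3)
  prev <- NULL
  for (m_max in 0:3) {
    pr <- profiles_direct(ls, m_max = m_max)
    raw <- kernel_from_profiles(pr, w, normalize = FALSE)
    if (!is.null(prev)) expect_true(all(unclass(raw) - prev >= -1e-12))
    prev <- unclass(raw)
  }
  # m_max = l - k equals the exact kernel
  exact <- gkm_kernel(ls, k = 3, m_max = 6, algorithm = "direct")
  capped <- gkm_kernel(ls, k = 3, m_max = 3, algorithm = "direct")
  expect_equal(unclass(exact), unclass(capped), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the exact gkm kernel is positive semidefinite", {
  set.seed(31)
  ls <- lmer_set(seq_tbl(vapply(1:10, function(i) random_dna(35), character(1))),
                 l = 5)
  K <- gkm_kernel(ls, k = 3, algorithm = "direct")
  ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("cross kernel is consistent with the training kernel", {
  set.seed(33)
  seqs <- seq_tbl(vapply(1:6, function(i) random_dna(30), character(1)))
  ls <- lmer_set(seqs, l = 4)
  w <- gkm_coefficients(4, 2)
  K <- gkm_kernel(ls, k = 2, algorithm = "direct")
  Kc <- cross_kernel(ls, ls, w, train_diag = attr(K, "raw_diag"))
  expect_equal(unclass(Kc), unclass(K), tolerance = 1e-12, ignore_attr = TRUE)

  # a test sequence identical to a training one scores 1 against it
  single <- lmer_set(seqs[3, ], l = 4)
  Kc1 <- cross_kernel(single, ls, w)
  expect_equal(Kc1[1, 3], 1)

  # config mismatches are rejected
  ls5 <- lmer_set(seqs, l = 5)
  expect_error(cross_kernel(ls5, ls, w), "config mismatch")
  lsf <- lmer_set(seqs, l = 4, include_revcomp = FALSE)
  expect_error(cross_kernel(lsf, ls, w), "strand")
})
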