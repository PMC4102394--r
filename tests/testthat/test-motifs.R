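sharp_pwm <- function(consensus, p = 0.97, gc = 0.5) {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - p) / 3, 4, length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- p
  new_pwm(m, gc = gc)
}

test_that("PWM construction validates and summarizes", {
  expect_error(new_pwm(matrix(1, 3, 4)), "4 rows")
  expect_error(new_pwm(matrix(0.3, 4, 2)), "sum to 1")
  p <- sharp_pwm("ACGT")
  expect_equal(colSums(p$mat), rep(1, 4), tolerance = 1e-12)
  expect_equal(nrow(tidy(p)), 16)
})

test_that("best-match scoring: consensus, uniform PWM, strand invariance", {
  p <- sharp_pwm("ACGTTGCA")
  s <- seq_tbl(paste0("TTTT", "ACGTTGCA", "TTTT"))
  sc <- pwm_best_match_score(p, s)
  # perfect match attains the PWM's maximal log-odds
  expect_equal(sc$score, 8 * log(0.97 / 0.25), tolerance = 1e-10)

  u <- new_pwm(matrix(0.25, 4, 5), gc = 0.5)
  set.seed(53)
  su <- seq_tbl(vapply(1:5, function(i) random_dna(30), character(1)))
  expect_equal(pwm_best_match_score(u, su)$score, rep(0, 5), tolerance = 1e-12)

  for (i in 1:10) {
    s1 <- random_dna(40)
    a <- pwm_best_match_score(p, seq_tbl(s1))$score
    b <- pwm_best_match_score(p, seq_tbl(reverse_complement(s1)))$score
    expect_equal(a, b, tolerance = 1e-10)
  }
  expect_error(pwm_best_match_score(p, seq_tbl("ACG")), "shorter")
})

test_that("k-mer alignment accepts the consensus and rejects anti-matches", {
  p <- sharp_pwm("ACGTTGCAAC")
  al <- align_kmer_to_pwm("ACGTTGCAAC", p)
  expect_equal(al$offset, 0L)
  expect_equal(al$strand, "+")
  expect_true(al$accepted)

  # a k-mer of near-zero-probability bases is strongly negative
  worst <- paste(c("T", "T", "T", "A", "A", "A", "T", "T", "T", "T"),
                 collapse = "")
  expect_false(align_kmer_to_pwm(worst, p)$accepted)

  # the reverse complement aligns at the mirrored offset on the other strand
  km <- "CGTTGCAACT" # consensus shifted left by one (offset +1)
  a1 <- align_kmer_to_pwm(km, p)
  a2 <- align_kmer_to_pwm(reverse_complement(km), p)
  expect_equal(a1$offset, a2$offset)
  expect_setequal(c(a1$strand, a2$strand), c("+", "-"))
  expect_equal(a1$score, a2$score, tolerance = 1e-10)
})

test_that("build_pwms merges shifted variants of one word into one motif", {
  word <- "ACGTTGCAACGT"
  # top table: 8-mer windows of one 12-mer consensus, some reverse-complemented
  kmers <- vapply(1:5, function(i) substr(word, i, i + 7), character(1))
  kmers <- c(kmers, reverse_complement(kmers[2]))
  tab <- tibble::tibble(kmer = kmers,
                        weight = seq(2, 1, length.out = length(kmers)))
  pw <- build_pwms(tab, top_fraction = 1, min_kmers = 3, threshold = 2)
  expect_equal(length(pw), 1)
  cons <- paste(rownames(pw[[1]]$mat)[apply(pw[[1]]$mat, 2, which.max)],
                collapse = "")
  expect_true(grepl(cons, word) || grepl(cons, reverse_complement(word)))
  expect_equal(nrow(pw[[1]]$kmers), length(kmers))
})

test_that("disjoint k-mer families separate into pure motifs", {
  fam1 <- c("ACCACACCAC", "CCACACCACA", "ACACCACACC", "CACCACACCA",
            "ACCACACCAA", "CCACACCACC")
  fam2 <- c("GTGGTGTGGT", "TGGTGTGGTG", "GGTGTGGTGT", "GTGTGGTGTG",
            "GTGGTGTGGG", "TGGTGTGGTT")
  # A/C-only words: their reverse complements are G/T-only, so with a high
  # threshold no cross-family alignment is accepted on either strand...
  # except that fam2 IS the reverse complement family of fam1-like words;
  # use A/C vs A/G families instead to keep them disjoint on both strands
  fam2 <- chartr("CT", "GC", fam1) # A/G-only words, rc is C/T-only
  tab <- tibble::tibble(kmer = c(fam1, fam2),
                        weight = c(seq(3, 2.5, length.out = 6),
                                   seq(2.4, 2, length.out = 6)))
  pw <- build_pwms(tab, top_fraction = 1, min_kmers = 3, threshold = 6)
  expect_equal(length(pw), 2)
  in_fam <- function(pwm, fam) {
    all(pwm$kmers$kmer %in% fam)
  }
  expect_true(in_fam(pw[[1]], fam1))
  expect_true(in_fam(pw[[2]], fam2))
})

test_that("build_pwms edge cases and determinism", {
  expect_equal(build_pwms(tibble::tibble(kmer = character(), weight = numeric())),
               list())
  tab <- tibble::tibble(kmer = c("ACGTACGTAC", "CGTACGTACG"), weight = c(2, 1))
  expect_equal(build_pwms(tab, max_pwms = 0), list())

  set.seed(59)
  kmers <- unique(vapply(1:40, function(i) random_dna(8), character(1)))
  tab2 <- tibble::tibble(kmer = kmers, weight = round(runif(length(kmers)), 2))
  a <- build_pwms(tab2, top_fraction = 1, min_kmers = 2, threshold = 3)
  b <- build_pwms(tab2[sample(nrow(tab2)), ], top_fraction = 1, min_kmers = 2,
                  threshold = 3)
  expect_equal(length(a), length(b))
  if (length(a)) expect_equal(a[[1]]$mat, b[[1]]$mat, tolerance = 1e-12)
})

test_that("MEME minimal format round-trips", {
  p1 <- sharp_pwm("ACGTTGCA", gc = 0.42)
  p1$name <- "m1"
  p2 <- sharp_pwm("GGATCC", p = 0.8, gc = 0.42)
  p2$name <- "m2"
  tf <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(p1, p2), tf, gc = 0.42)
  back <- read_meme(tf)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$mat, p1$mat, tolerance = 1e-5)
  expect_equal(back[[2]]$mat, p2$mat, tolerance = 1e-5)
  expect_equal(colSums(back[[1]]$mat), rep(1, 8), tolerance = 1e-9)
  expect_equal(back[[1]]$gc, 0.42, tolerance = 1e-4)

  # zero motifs: valid header-only file
  tf2 <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(), tf2)
  expect_equal(read_meme(tf2), list())
})

test_that("compare_pwms finds the planted alignment", {
  p <- sharp_pwm("AACGTGCTTCAGGA")
  sub <- new_pwm(p$mat[, 4:11], gc = 0.5)
  cmp <- compare_pwms(sub, p)
  expect_equal(cmp$offset, 3L)
  expect_equal(cmp$strand, "+")
  expect_gt(cmp$mean_cor, 0.99)
  cmp_rc <- compare_pwms(gkmkit:::pwm_revcomp(sub), p)
  expect_equal(cmp_rc$strand, "-")
  expect_gt(cmp_rc$mean_cor, 0.99)
})
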