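# shared small fixture: a separable two-class toy set
toy_sets <- function(n = 8, len = 40, seed = 101) {
  set.seed(seed)
  pos <- vapply(seq_len(n), function(i) {
    s <- random_dna(len)
    substr(s, 10, 17) <- "ACGTACGT"
    s
  }, character(1))
  neg <- vapply(seq_len(n), function(i) {
    s <- random_dna(len)
    substr(s, 10, 17) <- "TTTTAAAA"
    s
  }, character(1))
  tibble::tibble(id = paste0(rep(c("p", "n"), each = n), seq_len(n)),
                 seq = c(pos, neg),
                 label = rep(c(1L, -1L), each = n))
}

test_that("SVM separates a separable toy set and validates inputs", {
  toy <- toy_sets()
  ls <- lmer_set(toy, l = 6)
  K <- gkm_kernel(ls, k = 3, algorithm = "direct")
  m <- train_svm(K, toy$label, lmers = ls)
  expect_equal(mean(sign(m$fitted_decision) == toy$label), 1)
  expect_equal(glance(m)$train_auc, 1)
  # dual feasibility: label-signed coefficients sum to zero
  expect_lt(abs(sum(m$coefs)), 1e-6)
  expect_true(all(tidy(m)$coef != 0))

  expect_error(train_svm(K, rep(1L, nrow(toy))), "both classes")
  expect_error(train_svm(K, c(0, toy$label[-1])), "\\+1/-1")
})

test_that("label flip negates decision scores", {
  toy <- toy_sets()
  ls <- lmer_set(toy, l = 6)
  K <- gkm_kernel(ls, k = 3, algorithm = "direct")
  m1 <- train_svm(K, toy$label)
  m2 <- train_svm(K, -toy$label)
  expect_equal(m1$fitted_decision, -m2$fitted_decision, tolerance = 1e-6)
})

test_that("duplicating every training sequence leaves held-out scores unchanged", {
  # the dual optimum is invariant under duplicating every training point
  # when no dual coefficient sits at the box bound; two tight, well
  # separated clusters keep every alpha well below C = 1
  set.seed(211)
  mutate_seq <- function(template, nmut = 1) {
    s <- strsplit(template, "")[[1]]
    at <- sample(length(s), nmut)
    s[at] <- sample(DNA, nmut, replace = TRUE)
    paste(s, collapse = "")
  }
  tmpl_pos <- random_dna(40)
  tmpl_neg <- random_dna(40)
  toy <- tibble::tibble(
    id = paste0("s", 1:16),
    seq = c(vapply(1:8, function(i) mutate_seq(tmpl_pos), character(1)),
            vapply(1:8, function(i) mutate_seq(tmpl_neg), character(1))),
    label = rep(c(1L, -1L), each = 8))
  holdout <- seq_tbl(vapply(1:6, function(i) random_dna(40), character(1)), "h")

  ls <- lmer_set(toy, l = 6)
  K <- gkm_kernel(ls, k = 3, algorithm = "direct")
  m <- train_svm(K, toy$label, C = 2, tol = 1e-8, lmers = ls)
  expect_lt(max(abs(m$coefs)), 2 - 1e-3) # no alpha at the bound
  s1 <- decision_scores(m, holdout)

  dup <- dplyr::bind_rows(toy, dplyr::mutate(toy, id = paste0(.data$id, "_dup")))
  lsd <- lmer_set(dup, l = 6)
  Kd <- gkm_kernel(lsd, k = 3, algorithm = "direct")
  md <- train_svm(Kd, dup$label, C = 2, tol = 1e-8, lmers = lsd)
  s2 <- decision_scores(md, holdout)
  expect_lt(max(abs(s1$score - s2$score)), 5e-3)
})

test_that("scoring reproduces training decisions and is strand/order invariant", {
  toy <- toy_sets()
  ls <- lmer_set(toy, l = 6)
  K <- gkm_kernel(ls, k = 3, algorithm = "direct")
  m <- train_svm(K, toy$label, lmers = ls)

  s <- decision_scores(m, toy[, c("id", "seq")])
  expect_equal(s$score, m$fitted_decision, tolerance = 1e-8)

  rc <- dplyr::mutate(toy[, c("id", "seq")], seq = reverse_complement(.data$seq))
  expect_equal(decision_scores(m, rc)$score, s$score, tolerance = 1e-10)

  perm <- sample(nrow(toy))
  sp <- decision_scores(m, toy[perm, c("id", "seq")])
  expect_equal(sp$score, s$score[perm], tolerance = 1e-12)
})

test_that("score_all_kmers: scatter path equals the generic kernel path", {
  toy <- toy_sets()
  ls <- lmer_set(toy, l = 6)
  K <- gkm_kernel(ls, k = 3, algorithm = "direct") # m_max = l - k = 3
  m <- train_svm(K, toy$label, lmers = ls)
  fast <- score_all_kmers(m, w = 6)
  # generic path: score each 6-mer as a standalone sequence
  wm <- fast$kmer[seq(1, 4096, by = 37)]
  slow <- decision_scores(m, tibble::tibble(id = wm, seq = wm))
  expect_equal(fast$weight[match(wm, fast$kmer)], slow$score, tolerance = 1e-9)

  # a w-mer and its reverse complement receive equal weight
  rc <- reverse_complement(fast$kmer[1:50])
  expect_equal(fast$weight[match(rc, fast$kmer)], fast$weight[1:50],
               tolerance = 1e-10)
})

test_that("w-mer ranking reflects the planted discriminative word", {
  toy <- toy_sets(n = 12)
  ls <- lmer_set(toy, l = 8)
  K <- gkm_kernel(ls, k = 4, m_max = 2, algorithm = "direct")
  m <- train_svm(K, toy$label, lmers = ls)
  kw <- score_all_kmers(m, w = 8)
  expect_true("ACGTACGT" %in% kw$kmer[1:4])
  expect_true("TTTTAAAA" %in% utils::tail(kw$kmer, 4))
})

test_that("degenerate all-identical training sets give near-constant weights", {
  same <- tibble::tibble(id = paste0("s", 1:6),
                         seq = rep(strrep("ACGT", 10), 6),
                         label = rep(c(1L, -1L), 3))
  ls <- lmer_set(same, l = 6)
  K <- gkm_kernel(ls, k = 3, algorithm = "direct")
  m <- train_svm(K, same$label, lmers = ls)
  kw <- score_all_kmers(m, w = 6)
  expect_lt(diff(range(kw$weight)), 1e-6)
})

test_that("NB: symmetric training data scores zero; single-l-mer sequences", {
  seqs <- seq_tbl(c("ACGTACGTAC", "GGTTAACCGT", "TTGGCCAATT"))
  nb <- nb_train(seqs, seqs, l = 4, k = 2)
  sc <- nb_score(nb, seqs)
  expect_equal(sc$score, rep(0, 3), tolerance = 1e-12)

  nbr <- nb_train(seq_tbl("AAAAC", "p"), seq_tbl("GGGGT", "n"), l = 5,
                  use_filter = FALSE)
  one <- nb_score(nbr, seq_tbl("AAAAC", "q"))
  np <- 1.5 # one occurrence (fwd strand of the table) + pseudo-count
  nn <- 0.5
  expect_equal(one$score, log(np / nn))
})

test_that("NB filter mode smooths unseen l-mers, raw mode does not", {
  pos <- seq_tbl(rep("AAAAAAAAAA", 5), "p") # only A-runs observed
  neg <- seq_tbl(rep("GGGGGGGGGG", 5), "n")
  # query an l-mer one mismatch away from the frequent positive l-mer
  q <- seq_tbl("AAAAAC", "q")
  nbf <- nb_train(pos, neg, l = 6, k = 3)
  nbr <- nb_train(pos, neg, l = 6, k = 3, use_filter = FALSE)
  expect_gt(nb_score(nbf, q)$score, 0.5)
  expect_equal(nb_score(nbr, q)$score, 0, tolerance = 1e-12)
})

test_that("NB with l = k reduces to the raw-count classifier", {
  set.seed(303)
  pos <- seq_tbl(vapply(1:5, function(i) random_dna(30), character(1)), "p")
  neg <- seq_tbl(vapply(1:5, function(i) random_dna(30), character(1)), "n")
  test <- seq_tbl(vapply(1:5, function(i) random_dna(30), character(1)), "t")
  a <- nb_score(nb_train(pos, neg, l = 4, k = 4, use_filter = TRUE), test)
  b <- nb_score(nb_train(pos, neg, l = 4, use_filter = FALSE), test)
  expect_equal(a$score, b$score, tolerance = 1e-12)
})

test_that("adding positive copies of a sequence never decreases its NB score", {
  set.seed(404)
  pos <- seq_tbl(vapply(1:6, function(i) random_dna(25), character(1)), "p")
  neg <- seq_tbl(vapply(1:6, function(i) random_dna(25), character(1)), "n")
  target <- seq_tbl(random_dna(25), "t")
  prev <- -Inf
  for (copies in 0:3) {
    aug <- dplyr::bind_rows(pos, target[rep(1, copies), ])
    aug$id <- paste0("p", seq_len(nrow(aug)))
    sc <- nb_score(nb_train(aug, neg, l = 5, k = 3), target)$score
    expect_gte(sc, prev - 1e-12)
    prev <- sc
  }
})

test_that("windowed NB takes the max over substrings and dominates them", {
  set.seed(505)
  pos <- seq_tbl(vapply(1:6, function(i) random_dna(40), character(1)), "p")
  neg <- seq_tbl(vapply(1:6, function(i) random_dna(40), character(1)), "n")
  nb <- nb_train(pos, neg, l = 4, k = 2)
  for (i in 1:5) {
    s <- random_dna(40)
    w <- 5 # window of 5 l-mers = substrings of length 8
    full <- nb_score(nb, seq_tbl(s), window = w)$score
    starts <- sample(1:(40 - (w + 4 - 1) + 1), 4)
    subs <- vapply(starts, function(st) substr(s, st, st + w + 4 - 2), character(1))
    sub_scores <- nb_score(nb, seq_tbl(subs), window = w)$score
    expect_true(all(full >= sub_scores - 1e-12))
  }
  expect_error(nb_score(nb, seq_tbl("ACG")), "too short")
})

test_that("NB scores are strand-symmetric", {
  set.seed(606)
  pos <- seq_tbl(vapply(1:5, function(i) random_dna(30), character(1)), "p")
  neg <- seq_tbl(vapply(1:5, function(i) random_dna(30), character(1)), "n")
  test <- seq_tbl(vapply(1:5, function(i) random_dna(30), character(1)), "t")
  for (filt in c(TRUE, FALSE)) {
    nb <- nb_train(pos, neg, l = 5, k = 3, use_filter = filt)
    a <- nb_score(nb, test)$score
    b <- nb_score(nb, dplyr::mutate(test, seq = reverse_complement(.data$seq)))$score
    expect_equal(a, b, tolerance = 1e-10)
  }
})
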