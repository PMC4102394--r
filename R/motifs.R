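# De novo PWM extraction from ranked k-mer weights, and PWM scoring.
#
# A trained SVM induces a weight for every w-mer; the top-weighted w-mers
# are merged into up to three PWMs by an iterated greedy alignment: seed
# from the single best w-mer, align each remaining top w-mer to the model
# (best offset/strand by log-odds, accepted above a threshold), rebuild the
# PWM from the accepted w-mers with mass exp(alpha * weight), and iterate
# to a fixed point. Log-odds are against a position-independent genomic
# background (GC = 0.42 by default), in natural log units.

#' Construct a PWM object
#'
#' @param mat 4 x width matrix of per-position base probabilities (rows
#'   A, C, G, T); columns must sum to 1.
#' @param gc Background GC fraction used for log-odds.
#' @param name Optional name.
#' @param kmers Optional tibble of contributing k-mers (provenance).
#' @return A `gkm_pwm` object.
#' @export
new_pwm <- function(mat, gc = 0.42, name = NULL, kmers = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM matrix must have 4 rows (A, C, G, T)")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9)) stop("PWM columns must sum to 1")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(mat = mat, gc = gc, name = name, kmers = kmers),
            class = "gkm_pwm")
}

#' @exportS3Method base::print
print.gkm_pwm <- function(x, ...) {
  cons <- paste(rownames(x$mat)[apply(x$mat, 2, which.max)], collapse = "")
  cat(sprintf("<gkm_pwm>%s width %d, consensus %s, background GC=%.2f\n",
              if (!is.null(x$name)) paste0(" ", x$name) else "",
              ncol(x$mat), cons, x$gc))
  invisible(x)
}

#' @export
tidy.gkm_pwm <- function(x, ...) {
  tibble::tibble(position = rep(seq_len(ncol(x$mat)), each = 4),
                 base = rep(c("A", "C", "G", "T"), ncol(x$mat)),
                 prob = as.vector(x$mat))
}

#' @export
autoplot.gkm_pwm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$base,
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "Position", y = NULL, fill = "p") +
    ggplot2::theme_minimal()
}

pwm_background <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# natural-log odds matrix; probabilities floored at a small epsilon so a
# zero-probability base stays strongly negative but finite
pwm_log_odds <- function(pwm, eps = 1e-4) {
  bg <- pwm_background(pwm$gc)
  log(pmax(pwm$mat, eps) / bg)
}

pwm_revcomp <- function(pwm) {
  m <- pwm$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm$mat))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  new_pwm(m, gc = pwm$gc, name = pwm$name, kmers = pwm$kmers)
}

#' Best PWM match score in a sequence
#'
#' Maximum summed log-odds over all offsets and both strands (the classic
#' single-PWM classifier score for a region).
#'
#' @param pwm A `gkm_pwm`.
#' @param seqs Sequence tibble (`id`, `seq`), each at least as long as the
#'   PWM.
#' @return Tibble with columns `id`, `score`.
#' @export
pwm_best_match_score <- function(pwm, seqs) {
  stopifnot(inherits(pwm, "gkm_pwm"))
  wd <- ncol(pwm$mat)
  if (any(nchar(seqs$seq) < wd)) stop("sequence(s) shorter than the PWM")
  los <- list(pwm_log_odds(pwm), pwm_log_odds(pwm_revcomp(pwm)))
  score <- vapply(seqs$seq, function(s) {
    codes <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
    npos <- length(codes) - wd + 1L
    best <- -Inf
    for (lo in los) {
      sc <- numeric(npos)
      ok <- rep(TRUE, npos)
      for (p in seq_len(wd)) {
        cp <- codes[p:(p + npos - 1L)]
        bad <- is.na(cp)
        ok <- ok & !bad
        cp[bad] <- 1L
        sc <- sc + lo[cbind(cp, p)]
      }
      if (any(ok)) best <- max(best, max(sc[ok]))
    }
    best
  }, numeric(1), USE.NAMES = FALSE)
  tibble::tibble(id = seqs$id, score = score)
}

#' Align a k-mer to a PWM
#'
#' Considers every offset with at least half the k-mer overlapping the PWM,
#' on both strands; log-odds are summed over the overlapping positions
#' only. The alignment is rejected if the best score falls below
#' `threshold`.
#'
#' @param kmer A k-mer string.
#' @param pwm A `gkm_pwm`.
#' @param threshold Log-odds acceptance cutoff (default 5.0).
#' @return List with `offset` (k-mer start relative to PWM column 1; may be
#'   negative), `strand`, `score`, `accepted`.
#' @export
align_kmer_to_pwm <- function(kmer, pwm, threshold = 5.0) {
  wk <- nchar(kmer)
  wp <- ncol(pwm$mat)
  minov <- ceiling(wk / 2)
  best <- list(offset = 0L, strand = "+", score = -Inf)
  for (strand in c("+", "-")) {
    km <- if (strand == "+") toupper(kmer) else reverse_complement(toupper(kmer))
    codes <- match(strsplit(km, "")[[1]], c("A", "C", "G", "T"))
    lo <- pwm_log_odds(pwm)
    for (off in seq.int(-(wk - minov), wp - minov)) {
      kpos <- seq_len(wk)
      ppos <- kpos + off
      keep <- ppos >= 1 & ppos <= wp
      sc <- sum(lo[cbind(codes[keep], ppos[keep])])
      if (sc > best$score) best <- list(offset = as.integer(off),
                                        strand = strand, score = sc)
    }
  }
  best$accepted <- best$score >= threshold
  best
}

# rebuild a PWM of fixed width from aligned, exponentially weighted k-mers;
# overhanging bases are ignored. Per-column pseudo-count: 1% of that
# column's mass, split over the four bases; empty columns are uniform.
pwm_from_alignments <- function(kmers, weights, offsets, strands, width, gc,
                                alpha) {
  mass <- matrix(0, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(kmers)) {
    km <- if (strands[i] == "+") kmers[i] else reverse_complement(kmers[i])
    codes <- match(strsplit(toupper(km), "")[[1]], c("A", "C", "G", "T"))
    w <- exp(alpha * weights[i])
    ppos <- seq_along(codes) + offsets[i]
    keep <- ppos >= 1 & ppos <= width
    mass[cbind(codes[keep], ppos[keep])] <-
      mass[cbind(codes[keep], ppos[keep])] + w
  }
  cm <- colSums(mass)
  for (j in seq_len(width)) {
    if (cm[j] == 0) mass[, j] <- 0.25 else {
      mass[, j] <- mass[, j] + 0.01 * cm[j] / 4
      mass[, j] <- mass[, j] / sum(mass[, j])
    }
  }
  new_pwm(mass, gc = gc)
}

#' Build de novo PWMs from ranked k-mer weights
#'
#' Takes the top `top_fraction` of the ranked table, seeds a PWM from the
#' single highest-weight k-mer, and iterates full passes in which every
#' remaining top k-mer is aligned to the current model
#' ([align_kmer_to_pwm()]), the accepted set recorded, and the PWM rebuilt
#' from the accepted k-mers with mass `exp(alpha * weight)` at their
#' aligned offsets/strands, until the assignment stops changing (batch
#' update, capped at `max_iter` passes). Accepted k-mers are then removed
#' and the process repeated for up to `max_pwms` motifs; motifs with fewer
#' than `min_kmers` contributing k-mers are dropped.
#'
#' @param kmer_weights Tibble (`kmer`, `weight`) sorted descending (as from
#'   [score_all_kmers()]).
#' @param max_pwms Maximum motifs to report (default 3).
#' @param threshold Alignment log-odds cutoff (default 5.0).
#' @param gc Background GC fraction (default 0.42).
#' @param alpha Exponential weighting of k-mer SVM scores (default 3.0).
#' @param top_fraction Fraction of the table used (default 0.01).
#' @param min_kmers Minimum contributing k-mers per reported PWM (default 5).
#' @param max_iter Cap on refinement passes (default 50).
#' @return List of `gkm_pwm` (possibly empty), each carrying its
#'   contributing k-mers in `$kmers`.
#' @export
build_pwms <- function(kmer_weights, max_pwms = 3L, threshold = 5.0,
                       gc = 0.42, alpha = 3.0, top_fraction = 0.01,
                       min_kmers = 5L, max_iter = 50L) {
  if (max_pwms < 1 || nrow(kmer_weights) == 0) return(list())
  tab <- kmer_weights[order(-kmer_weights$weight, kmer_weights$kmer), ]
  n_top <- max(1L, floor(nrow(tab) * top_fraction))
  tab <- tab[seq_len(n_top), ]
  pwms <- list()
  for (p in seq_len(max_pwms)) {
    if (nrow(tab) == 0) break
    width <- nchar(tab$kmer[1])
    seed <- list(offset = 0L, strand = "+", score = Inf)
    pwm <- pwm_from_alignments(tab$kmer[1], tab$weight[1], 0L, "+",
                               width, gc, alpha)
    assign_prev <- NULL
    for (iter in seq_len(max_iter)) {
      al <- lapply(tab$kmer, align_kmer_to_pwm, pwm = pwm,
                   threshold = threshold)
      al[[1]]$accepted <- TRUE # the seed always belongs to its own model
      acc <- vapply(al, `[[`, logical(1), "accepted")
      assign_now <- paste(acc,
                          vapply(al, `[[`, integer(1), "offset"),
                          vapply(al, `[[`, character(1), "strand"))
      pwm <- pwm_from_alignments(
        tab$kmer[acc], tab$weight[acc],
        vapply(al[acc], `[[`, integer(1), "offset"),
        vapply(al[acc], `[[`, character(1), "strand"),
        width, gc, alpha)
      if (identical(assign_now, assign_prev)) break
      if (iter == max_iter) message("build_pwms: refinement pass cap (",
                                    max_iter, ") reached")
      assign_prev <- assign_now
    }
    used <- which(acc)
    pwm$name <- paste0("denovo_", p)
    pwm$kmers <- tab[used, ]
    if (length(used) >= min_kmers) pwms[[length(pwms) + 1]] <- pwm
    tab <- tab[-used, ]
  }
  pwms
}

#' Best alignment correlation between two PWMs
#'
#' Slides one PWM against the other (both strands, overlap at least half
#' the shorter width) and reports the alignment maximizing the mean
#' per-column Pearson correlation of the probability columns.
#'
#' @param query,target `gkm_pwm` objects.
#' @return List with `offset`, `strand`, `mean_cor`, `overlap`.
#' @export
compare_pwms <- function(query, target) {
  wq <- ncol(query$mat)
  wt <- ncol(target$mat)
  minov <- ceiling(min(wq, wt) / 2)
  best <- list(offset = 0L, strand = "+", mean_cor = -Inf, overlap = 0L)
  for (strand in c("+", "-")) {
    qm <- if (strand == "+") query$mat else pwm_revcomp(query)$mat
    for (off in seq.int(-(wq - minov), wt - minov)) {
      qpos <- seq_len(wq)
      tpos <- qpos + off
      keep <- tpos >= 1 & tpos <= wt
      if (sum(keep) < minov) next
      cors <- vapply(which(keep), function(i) {
        a <- qm[, i]; b <- target$mat[, tpos[i]]
        if (sd(a) == 0 || sd(b) == 0) return(0)
        cor(a, b)
      }, numeric(1))
      mc <- mean(cors)
      if (mc > best$mean_cor) best <- list(offset = as.integer(off),
                                           strand = strand, mean_cor = mc,
                                           overlap = sum(keep))
    }
  }
  best
}

#' Write PWMs in MEME minimal format
#'
#' @param pwms List of `gkm_pwm` (may be empty; a valid header-only file is
#'   written).
#' @param path Output path.
#' @param gc Background GC for the frequency line.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, gc = 0.42) {
  bg <- pwm_background(gc)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", bg[1], bg[2], bg[3], bg[4]),
               ""), con)
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    nm <- p$name %||% paste0("motif_", i)
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(p$mat), max(1L, NROW(p$kmers))), con)
    for (j in seq_len(ncol(p$mat))) {
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         p$mat[1, j], p$mat[2, j], p$mat[3, j], p$mat[4, j]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from MEME minimal format
#'
#' @param path Path to a MEME file written by [write_meme()].
#' @return List of `gkm_pwm`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg_line <- grep("^A [0-9.]+ C", lines, value = TRUE)
  gc <- if (length(bg_line)) {
    v <- as.numeric(strsplit(bg_line[1], "\\s+")[[1]][c(2, 4, 6, 8)])
    v[2] + v[3]
  } else 0.42
  idx <- grep("^MOTIF ", lines)
  lapply(idx, function(i) {
    nm <- strsplit(lines[i], "\\s+")[[1]][2]
    hdr <- lines[i + 1]
    w <- as.integer(sub(".* w= *([0-9]+).*", "\\1", hdr))
    rows <- lines[(i + 2):(i + 1 + w)]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(4), USE.NAMES = FALSE))
    m <- t(mat)
    m <- sweep(m, 2, colSums(m), "/") # guard tiny rounding from the writer
    new_pwm(m, gc = gc, name = nm)
  })
}
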