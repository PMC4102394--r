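# Seeded planted-motif benchmark generator.
#
# Emulates the statistical structure of TF ChIP-seq benchmark sets: an
# i.i.d. random background of configurable GC content, positives carrying
# sampled PWM instances (one long high-information site, or several short
# degenerate sites), and negatives drawn at the positives' lengths and
# pooled GC (the length/GC matching used for real negative sets; genomic
# sampling with repeat matching is out of scope here).

#' Random background sequences
#'
#' i.i.d. bases with `P(G) = P(C) = gc/2`.
#'
#' @param n Number of sequences.
#' @param length Sequence length (bp); scalar or per-sequence vector.
#' @param gc Background GC fraction in `(0, 1)`.
#' @param seed Optional seed (set once before sampling).
#' @param prefix Id prefix.
#' @return Sequence tibble (`id`, `seq`).
#' @export
sample_background <- function(n, length, gc = 0.42, seed = NULL, prefix = "bg") {
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  len <- rep_len(length, n)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), sum(len), replace = TRUE, prob = p)
  stops <- cumsum(len)
  starts <- c(1, head(stops, -1) + 1)
  tibble::tibble(
    id = sprintf("%s_%0*d", prefix, nchar(n), seq_len(n)),
    seq = vapply(seq_len(n), function(i) {
      paste(bases[starts[i]:stops[i]], collapse = "")
    }, character(1))
  )
}

#' GC fraction of a pooled sequence set
#' @param seqs Sequence tibble.
#' @return Pooled GC fraction.
#' @export
pooled_gc <- function(seqs) {
  s <- toupper(paste(seqs$seq, collapse = ""))
  (nchar(gsub("[^GC]", "", s))) / nchar(s)
}

#' Plant PWM instances into background sequences
#'
#' Each sequence receives a number of instances drawn uniformly from
#' `n_instances` (a scalar or `c(min, max)`), each from a uniformly chosen
#' PWM, at uniformly random non-overlapping positions and uniform strand.
#' Instance letters are sampled independently per PWM column.
#'
#' @param background Sequence tibble to modify.
#' @param pwms A `gkm_pwm` or list of them.
#' @param n_instances Instances per sequence (scalar or range).
#' @param seed Optional seed.
#' @return List with `seqs` (modified tibble) and `meta` (tibble: `id`,
#'   `motif`, `offset`, `strand`, `instance`).
#' @export
plant_motifs <- function(background, pwms, n_instances = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(pwms, "gkm_pwm")) pwms <- list(pwms)
  rng <- range(n_instances)
  meta <- list()
  seqs <- background$seq
  for (i in seq_along(seqs)) {
    slen <- nchar(seqs[i])
    n_inst <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
    if (n_inst == 0) next
    which_pwm <- if (length(pwms) == 1) rep(1L, n_inst) else
      sample(length(pwms), n_inst, replace = TRUE)
    widths <- vapply(pwms[which_pwm], function(p) ncol(p$mat), integer(1))
    if (any(widths > slen)) stop("motif wider than sequence")
    # rejection sampling for non-overlapping placement
    starts <- NULL
    for (try in 1:200) {
      cand <- vapply(widths, function(w) sample.int(slen - w + 1L, 1), integer(1))
      ends <- cand + widths - 1L
      o <- order(cand)
      if (all(cand[o][-1] > ends[o][-n_inst])) { starts <- cand; break }
    }
    if (is.null(starts)) stop("infeasible packing of ", n_inst,
                              " instances into length ", slen)
    for (j in seq_len(n_inst)) {
      pw <- pwms[[which_pwm[j]]]
      inst <- paste(apply(pw$mat, 2, function(col) {
        sample(c("A", "C", "G", "T"), 1, prob = col)
      }), collapse = "")
      strand <- sample(c("+", "-"), 1)
      placed <- if (strand == "+") inst else reverse_complement(inst)
      substr(seqs[i], starts[j], starts[j] + widths[j] - 1L) <- placed
      meta[[length(meta) + 1]] <- tibble::tibble(
        id = background$id[i], motif = pw$name %||% as.character(which_pwm[j]),
        offset = starts[j], strand = strand, instance = inst)
    }
  }
  list(seqs = tibble::tibble(id = background$id, seq = seqs),
       meta = if (length(meta)) dplyr::bind_rows(meta) else
         tibble::tibble(id = character(), motif = character(),
                        offset = integer(), strand = character(),
                        instance = character()))
}

# fixed benchmark PWMs ------------------------------------------------------

consensus_pwm <- function(consensus, p_max, name) {
  bases <- strsplit(consensus, "")[[1]]
  mat <- matrix((1 - p_max) / 3, nrow = 4, ncol = length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) mat[bases[j], j] <- p_max
  new_pwm(mat, gc = 0.42, name = name)
}

#' Benchmark PWMs
#'
#' `ctcf_like_pwm()`: a single 19 bp high-information site (per-column max
#' probability 0.85), emulating a long zinc-finger footprint.
#' `ep300_like_pwms()`: three distinct 8 bp degenerate sites (max 0.6),
#' emulating diverse enhancer TFBS combinations.
#'
#' @return A `gkm_pwm`, or a list of them.
#' @export
ctcf_like_pwm <- function() {
  consensus_pwm("TGGCCACCAGGTGGCAGCA", 0.85, "ctcf_like")
}

#' @rdname ctcf_like_pwm
#' @export
ep300_like_pwms <- function() {
  list(consensus_pwm("TGACTCAG", 0.6, "site_a"),
       consensus_pwm("CAGCTGTT", 0.6, "site_b"),
       consensus_pwm("GGAAGTGA", 0.6, "site_c"))
}

#' Generate a labeled planted-motif benchmark
#'
#' Composes background sampling and motif planting; negatives are drawn at
#' the positives' lengths and pooled GC. All randomness flows from `seed`
#' through one RNG stream (background, planting, negatives in that order),
#' so the same configuration and seed reproduce the data byte-for-byte.
#'
#' @param preset `"ctcf_like"` (500+/500-, 300 bp, one planted 19 bp
#'   high-information PWM per positive) or `"ep300_like"` (three 8 bp
#'   degenerate PWMs, 1-3 instances per positive).
#' @param n_pos,n_neg Set sizes.
#' @param length Sequence length (bp).
#' @param gc Background GC fraction.
#' @param seed Integer seed.
#' @return List with `pos`, `neg` (tibbles with `label` +1/-1), `meta`
#'   (planted-instance metadata), `pwms`, `config`.
#' @export
make_benchmark <- function(preset = c("ctcf_like", "ep300_like"),
                           n_pos = 500L, n_neg = 500L, length = 300L,
                           gc = 0.42, seed = 1L) {
  preset <- match.arg(preset)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pwms <- if (preset == "ctcf_like") list(ctcf_like_pwm()) else ep300_like_pwms()
  n_inst <- if (preset == "ctcf_like") 1L else c(1L, 3L)
  bg <- sample_background(n_pos, length, gc, prefix = "pos")
  planted <- plant_motifs(bg, pwms, n_instances = n_inst)
  pos <- planted$seqs
  neg <- sample_background(n_neg, length, pooled_gc(pos), prefix = "neg")
  pos$label <- 1L
  neg$label <- -1L
  list(pos = pos, neg = neg, meta = planted$meta, pwms = pwms,
       config = list(preset = preset, n_pos = n_pos, n_neg = n_neg,
                     length = length, gc = gc, seed = seed))
}
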