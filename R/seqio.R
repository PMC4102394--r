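# Sequence I/O and l-mer extraction.
#
# Sequence sets are plain tibbles with columns `id`, `seq` and optionally
# `label` (+1/-1), so they compose with dplyr verbs. Lowercase bases mark
# repeat-masked positions; they are case-folded for feature extraction but
# preserved on disk, and `repeat_fraction()` exposes the masked fraction so
# heavily repetitive regions can be filtered up front.

IUPAC_CHARS <- c("A", "C", "G", "T", "N")

#' Read a FASTA file into a sequence tibble
#'
#' @param path Path to a FASTA file. Multi-line bodies are accepted and case
#'   is preserved (lowercase conventionally marks repeat-masked bases).
#' @param label Optional class label (+1 or -1) attached to every record.
#' @return A tibble with columns `id`, `seq` and, when `label` is given,
#'   `label`.
#' @export
read_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", names(set))
  if (length(seqs) > 0) {
    bad <- !grepl("^[ACGTNacgtn]*$", seqs)
    if (any(bad)) {
      stop("non-IUPAC characters in FASTA record(s): ",
           paste(head(ids[bad], 5), collapse = ", "))
    }
    if (anyDuplicated(ids)) stop("duplicate FASTA ids in ", path)
  }
  out <- tibble::tibble(id = unname(ids), seq = unname(seqs))
  if (!is.null(label)) out$label <- as.integer(label)
  out
}

#' Write a sequence tibble to FASTA
#'
#' Bodies are wrapped at 80 columns; case is preserved.
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed. `N` maps to `N`; case is preserved per
#' position (after reversal), so repeat masking travels with the base.
#'
#' @param bases Character vector of DNA strings over `{A,C,G,T,N}`, any case.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(bases) {
  bad <- !grepl("^[ACGTNacgtn]*$", bases)
  if (any(bad)) stop("non-IUPAC character in sequence(s): ",
                     paste(which(bad), collapse = ", "))
  comp <- chartr("ACGTacgt", "TGCAtgca", bases)
  vapply(comp, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Fraction of repeat-masked (lowercase) bases
#'
#' @param bases Character vector of DNA strings.
#' @return Numeric vector in `[0, 1]`.
#' @export
repeat_fraction <- function(bases) {
  n <- nchar(bases)
  low <- nchar(gsub("[^acgtn]", "", bases))
  ifelse(n == 0, 0, low / n)
}

#' Extract the l-mer multiset of a sequence
#'
#' Every width-`l` window on the forward strand containing only A/C/G/T
#' (case-folded) is kept; windows containing any other character are skipped.
#' With `include_revcomp` the reverse-complement strand's windows are
#' appended, which makes every downstream kernel exactly strand-symmetric
#' (palindromic l-mers are counted once per strand). The multiset is stored
#' deduplicated with occurrence counts and 2-bit packed keys.
#'
#' @param seq A single DNA string.
#' @param l Word length (1..26).
#' @param include_revcomp Append the reverse-complement strand's windows
#'   (default `TRUE`).
#' @param t Chunk width in bases for the chunked integer encoding exposed by
#'   [encode_lmer()]; recorded for downstream use (default 6).
#' @return An object of class `lmer_list`: list with `keys` (packed unique
#'   l-mers, sorted), `counts`, `n` (total retained windows), `l`, `t`.
#' @export
extract_lmers <- function(seq, l, include_revcomp = TRUE, t = 6L) {
  stopifnot(length(seq) == 1, is.character(seq))
  res <- cpp_extract_lmers(seq, as.integer(l), isTRUE(include_revcomp))
  structure(
    list(keys = res$keys, counts = res$counts, n = res$n,
         l = as.integer(l), t = as.integer(t),
         include_revcomp = isTRUE(include_revcomp)),
    class = "lmer_list"
  )
}

#' @exportS3Method base::print
print.lmer_list <- function(x, ...) {
  cat(sprintf("<lmer_list> l=%d, %d unique l-mers, n=%d windows%s\n",
              x$l, length(x$keys), x$n,
              if (x$include_revcomp) " (both strands)" else ""))
  invisible(x)
}

#' Decode an lmer_list back to l-mer strings
#'
#' @param x An `lmer_list`.
#' @return Tibble with columns `lmer` and `count`.
#' @export
tidy.lmer_list <- function(x, ...) {
  tibble::tibble(lmer = cpp_keys_to_strings(x$keys, x$l), count = x$counts)
}

#' l-mer lists for a whole sequence set
#'
#' @param seqs Sequence tibble (columns `id`, `seq`).
#' @inheritParams extract_lmers
#' @return An object of class `lmer_set`: a list of `lmer_list`, with the
#'   ids and the shared configuration as attributes.
#' @export
lmer_set <- function(seqs, l, include_revcomp = TRUE, t = 6L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  lists <- lapply(seqs$seq, extract_lmers, l = l,
                  include_revcomp = include_revcomp, t = t)
  structure(lists, ids = seqs$id, l = as.integer(l), t = as.integer(t),
            include_revcomp = isTRUE(include_revcomp), class = "lmer_set")
}

#' @exportS3Method base::print
print.lmer_set <- function(x, ...) {
  cat(sprintf("<lmer_set> %d sequences, l=%d%s\n", length(x), attr(x, "l"),
              if (attr(x, "include_revcomp")) ", both strands" else ""))
  invisible(x)
}

#' Chunked integer encoding of l-mers
#'
#' Packs each l-mer into `ceiling(l/t)` integers, `t` bases per chunk at two
#' bits per base. Decoding is exact, and two encodings are equal iff the
#' l-mer strings are equal.
#'
#' @param lmers Character vector of equal-length l-mers (A/C/G/T).
#' @param t Chunk width in bases (default 6; the best value is
#'   machine-dependent).
#' @return Integer matrix, one column per l-mer, with attributes `l` and `t`.
#' @export
encode_lmer <- function(lmers, t = 6L) {
  l <- unique(nchar(lmers))
  if (length(l) != 1) stop("all l-mers must have the same length")
  m <- cpp_encode_chunks(toupper(lmers), as.integer(l), as.integer(t))
  structure(m, l = as.integer(l), t = as.integer(t))
}

#' @rdname encode_lmer
#' @param chunks Integer matrix produced by [encode_lmer()].
#' @export
decode_lmer <- function(chunks, l = attr(chunks, "l"), t = attr(chunks, "t")) {
  cpp_decode_chunks(chunks, as.integer(l), as.integer(t))
}

#' Hamming distance between two encoded l-mers
#'
#' Chunkwise bitwise XOR followed by a precomputed `2^(2t)`-entry lookup
#' table mapping each XOR pattern to its mismatched-base count.
#'
#' @param u1,u2 Single-column chunk encodings (or single columns of a matrix
#'   from [encode_lmer()]) sharing `l` and `t`.
#' @param t Chunk width used for encoding.
#' @return Integer mismatch count.
#' @export
count_mismatches <- function(u1, u2, t = attr(u1, "t") %||% 6L) {
  u1 <- as.integer(u1)
  u2 <- as.integer(u2)
  cpp_count_mismatches_chunks(u1, u2, as.integer(t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
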