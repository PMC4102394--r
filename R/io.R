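# Table/serialization interfaces: kernel matrices as headered TSV with the
# configuration echoed in '#' comment lines, profile dumps, score tables,
# and model archives.

config_header <- function(cfg) {
  w <- cfg$weights
  sprintf("# gkmkit %s | variant=%s l=%d%s%s%s m_max=%s revcomp=%s",
          as.character(utils::packageVersion("gkmkit")),
          w$variant, w$l,
          if (!is.null(w$k)) paste0(" k=", w$k) else "",
          if (!is.null(w$M)) paste0(" M=", w$M) else "",
          if (!is.null(w$lambda)) paste0(" lambda=", w$lambda) else "",
          cfg$m_max, isTRUE(cfg$include_revcomp))
}

#' Write / read a kernel matrix as tab-separated text
#'
#' Sequence ids occupy the first row and column; the feature configuration
#' is echoed in a leading `#` comment line.
#'
#' @param K A `gkm_kernel`.
#' @param path File path.
#' @return `path` invisibly; `read_kernel()` returns the matrix with the
#'   ids as dimnames.
#' @export
write_kernel <- function(K, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(attr(K, "config")), con)
  writeLines(paste(c("id", colnames(K)), collapse = "\t"), con)
  m <- unclass(K)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], format(m[i, ], digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Dump mismatch profiles as a tab-separated table
#'
#' One row per (pair, m): columns `i`, `j`, `m`, `count`.
#'
#' @param profiles A `gkm_profiles`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.table(tidy(profiles), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a per-sequence score table
#'
#' @param scores Tibble with columns `id`, `score`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained model
#'
#' Models are self-describing archives (training ids, dual coefficients,
#' feature configuration and l-mer tables) serialized with R's native
#' format.
#'
#' @param model A `gkm_svm` or `gkm_nb`.
#' @param path File path (conventionally `.rds`).
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gkm_svm") || inherits(model, "gkm_nb"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "gkm_svm") && !inherits(m, "gkm_nb")) {
    stop("file does not contain a gkmkit model")
  }
  m
}
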