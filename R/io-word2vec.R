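#' Read a word2vec-dialect binary embedding file
#'
#' The dialect of the released Google News vectors: an ASCII header line
#' `"vocab_size dim"`, then one record per token — the token's bytes, a
#' single space, then `dim` little-endian 32-bit floats. A newline between
#' records (written by the original C tool) is tolerated and skipped.
#'
#' @param path file path.
#' @param vocab_filter optional character vector of tokens to keep.
#' @return an [embedding_set()] with exactly `vocab_size` terms (or the
#'   filtered subset), `normalized` unset, record order preserved.
#' @seealso [write_word2vec_binary()], [read_glove_text()]
#' @export
read_word2vec_binary <- function(path, vocab_filter = NULL) {
  if (!file.exists(path)) ea_stop("io", "no such file: %s", path)
  bytes <- readBin(path, what = "raw", n = file.size(path))
  nl <- which(bytes == as.raw(0x0a))
  if (length(nl) == 0L) ea_stop("malformed_file", "no header line in %s", path)
  header <- rawToChar(bytes[seq_len(nl[1L] - 1L)])
  hf <- suppressWarnings(as.integer(strsplit(trimws(header), " +")[[1L]]))
  if (length(hf) != 2L || anyNA(hf) || any(hf < 1L)) {
    ea_stop("malformed_file", "bad header '%s' in %s", header, path)
  }
  n <- hf[1L]; d <- hf[2L]
  vec_bytes <- 4L * d
  toks <- character(n)
  vecs <- matrix(NA_real_, nrow = n, ncol = d)
  pos <- nl[1L] + 1L
  total <- length(bytes)
  ws <- as.raw(c(0x0a, 0x0d, 0x20))
  for (i in seq_len(n)) {
    while (pos <= total && bytes[pos] %in% ws) pos <- pos + 1L  # inter-record padding
    start <- pos
    while (pos <= total && bytes[pos] != as.raw(0x20)) pos <- pos + 1L
    if (pos > total || pos == start) {
      ea_stop("malformed_file", "truncated record %d of %d in %s", i, n, path)
    }
    tok <- rawToChar(bytes[start:(pos - 1L)])
    if (!validUTF8(tok)) {
      ea_log(sprintf("record %d token has undecodable bytes; replaced", i),
             level = "warn")
      tok <- iconv(tok, "UTF-8", "UTF-8", sub = "�")
    }
    Encoding(tok) <- "UTF-8"
    pos <- pos + 1L  # the separating space
    if (pos + vec_bytes - 1L > total) {
      ea_stop("malformed_file", "truncated record %d of %d in %s", i, n, path)
    }
    vecs[i, ] <- readBin(bytes[pos:(pos + vec_bytes - 1L)], what = "numeric",
                         size = 4L, n = d, endian = "little")
    pos <- pos + vec_bytes
    toks[i] <- tok
  }
  if (!is.null(vocab_filter)) {
    keep <- toks %in% vocab_filter
    toks <- toks[keep]; vecs <- vecs[keep, , drop = FALSE]
  }
  if (anyDuplicated(toks)) {
    ea_stop("duplicate_term", "duplicate token '%s' in %s",
            toks[duplicated(toks)][1L], path)
  }
  ea_log(sprintf("read %d terms x %d dims from %s (word2vec binary)",
                 length(toks), d, path))
  embedding_set(toks, vecs, normalized = FALSE, source = path)
}

#' Write an embedding set as word2vec-dialect binary
#'
#' Components are stored as little-endian 32-bit floats, so values round-trip
#' exactly at single precision (absolute error below 1e-6 for unit-scale
#' components).
#'
#' @param set an [embedding_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_word2vec_binary <- function(set, path) {
  stopifnot(inherits(set, "embedding_set"))
  check_writable_tokens(set$terms)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(sprintf("%d %d\n", length(set$terms), set$dim)), con)
  for (i in seq_along(set$terms)) {
    writeBin(c(charToRaw(enc2utf8(set$terms[i])), as.raw(0x20)), con)
    writeBin(set$vectors[i, ], con, size = 4L, endian = "little")
    writeBin(as.raw(0x0a), con)
  }
  invisible(path)
}

check_writable_tokens <- function(terms) {
  bad <- grepl("[[:space:]]", terms)
  if (any(bad)) {
    ea_stop("invalid_token", "token contains whitespace: '%s'", terms[bad][1L])
  }
  invisible(NULL)
}
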