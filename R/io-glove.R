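#' Read a GloVe-dialect plain-text embedding file
#'
#' The GloVe dialect is headerless: each line is a token followed by d
#' numeric fields, whitespace-separated. The dimension is inferred from the
#' first line and every subsequent line must match it. Undecodable bytes are
#' replaced (UTF-8 with substitution) and logged; duplicate tokens are a
#' hard error because a silent last-wins overwrite would corrupt an audit.
#'
#' @param path file path.
#' @param vocab_filter optional character vector; when given, only lines
#'   whose token is in the filter are kept (loading a few probe terms from a
#'   large file without holding all of it).
#' @return an [embedding_set()], `normalized` unset, rows in file order.
#' @seealso [write_glove_text()], [read_word2vec_binary()]
#' @export
read_glove_text <- function(path, vocab_filter = NULL) {
  if (!file.exists(path)) ea_stop("io", "no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  bad <- !validUTF8(lines)
  if (any(bad)) {
    ea_log(sprintf("%d line(s) contained undecodable bytes; replaced",
                   sum(bad)), level = "warn")
    lines[bad] <- iconv(lines[bad], "UTF-8", "UTF-8", sub = "�")
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) ea_stop("malformed_file", "empty embedding file: %s", path)

  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  d <- nf[1L] - 1L
  if (d < 1L) ea_stop("malformed_file", "line 1 has no vector fields")
  if (any(nf != nf[1L])) {
    ln <- which(nf != nf[1L])[1L]
    ea_stop("malformed_file",
            "line %d has %d fields, expected %d", ln, nf[ln], nf[1L])
  }
  toks <- vapply(fields, `[[`, "", 1L)
  if (!is.null(vocab_filter)) {
    keep <- toks %in% vocab_filter
    fields <- fields[keep]; toks <- toks[keep]
    if (length(toks) == 0L) {
      ea_stop("malformed_file", "no filter token present in %s", path)
    }
  }
  if (anyDuplicated(toks)) {
    ea_stop("duplicate_term", "duplicate token '%s' in %s",
            toks[duplicated(toks)][1L], path)
  }
  vecs <- matrix(NA_real_, nrow = length(toks), ncol = d)
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]][-1L]))
    if (anyNA(v)) ea_stop("malformed_file", "non-numeric field on line %d", i)
    vecs[i, ] <- v
  }
  ea_log(sprintf("read %d terms x %d dims from %s (GloVe text)",
                 length(toks), d, path))
  embedding_set(toks, vecs, normalized = FALSE, source = path)
}

#' Write an embedding set as GloVe-dialect plain text
#'
#' @param set an [embedding_set()].
#' @param path output file path.
#' @param digits significant digits for vector components; the default (17)
#'   round-trips doubles exactly through [read_glove_text()].
#' @return `path`, invisibly.
#' @export
write_glove_text <- function(set, path, digits = 17L) {
  stopifnot(inherits(set, "embedding_set"))
  check_writable_tokens(set$terms)
  rows <- vapply(seq_along(set$terms), function(i) {
    paste(set$terms[i],
          paste(formatC(set$vectors[i, ], format = "g", digits = digits),
                collapse = " "))
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(rows, con, useBytes = TRUE)
  invisible(path)
}
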