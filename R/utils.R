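#' @keywords internal
"_PACKAGE"

# Logging goes to stderr via message() so audits stay pipeable; gated on an
# option rather than a function argument so library internals stay quiet in
# programmatic use but the CLI can turn everything on.
ea_log <- function(..., level = "info") {
  if (isTRUE(getOption("embaudit.verbose", FALSE)) || level == "warn") {
    message(sprintf("[embaudit %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

#' Enable or disable embaudit progress/diagnostic logging
#'
#' @param verbose logical; `TRUE` logs vocabulary sizes, skipped lines and
#'   out-of-vocabulary terms to stderr.
#' @return the previous setting, invisibly.
#' @export
embaudit_verbose <- function(verbose = TRUE) {
  old <- getOption("embaudit.verbose", FALSE)
  options(embaudit.verbose = isTRUE(verbose))
  invisible(old)
}

# MD5 of a file, used in audit metadata so a result can be tied to the exact
# lexicon/embedding files that produced it.
file_hash <- function(path) {
  unname(tools::md5sum(path.expand(path)))
}

# MD5 of an in-memory object (canonical text serialization, not RDS, so the
# hash is stable across R versions).
object_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(utils::capture.output(dput(x)), tmp)
  file_hash(tmp)
}

ea_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(paste0("embaudit_", class), "embaudit_error")))
}

# Deterministic ranking: score descending, ties broken by C-locale
# lexicographic order of the term (radix sort is locale-independent).
rank_scored <- function(terms, scores, top_k = length(terms)) {
  ord <- order(-scores, terms, method = "radix")
  ord <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(term = terms[ord], score = scores[ord],
             stringsAsFactors = FALSE)
}
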