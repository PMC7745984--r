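#' Construct a lexicon of probe terms
#'
#' A lexicon is a named list of entries, each a canonical label plus the
#' token variants that may represent it in an embedding vocabulary: case
#' forms ("Teenager"/"teenager") and underscore-joined phrases
#' ("perinatal_depression"). Demographic label sets and the DSM-5-derived
#' diagnosis list are both lexicons.
#'
#' @param name lexicon name (used in audit metadata).
#' @param entries named list: canonical label -> character vector of
#'   variants. Unnamed character vectors are accepted and used as both
#'   canonical and single variant.
#' @return an object of class `lexicon`.
#' @export
lexicon <- function(name, entries) {
  if (is.character(entries)) {
    entries <- stats::setNames(as.list(entries), entries)
  }
  canon <- names(entries)
  if (is.null(canon) || any(!nzchar(canon))) {
    ea_stop("invalid_lexicon", "every entry needs a canonical name")
  }
  if (anyDuplicated(canon)) {
    ea_stop("duplicate_entry", "duplicate canonical label '%s'",
            canon[duplicated(canon)][1L])
  }
  entries <- lapply(entries, function(v) {
    v <- unique(as.character(v))
    if (length(v) == 0L || any(!nzchar(v))) {
      ea_stop("invalid_lexicon", "entry with no variants")
    }
    if (any(grepl("[[:space:]]", v))) {
      ea_stop("invalid_token", "variant contains whitespace: '%s'",
              v[grepl("[[:space:]]", v)][1L])
    }
    v
  })
  structure(list(name = name, entries = entries), class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon '%s'> %d entries\n", x$name, length(x$entries)))
  invisible(x)
}

#' @export
length.lexicon <- function(x) length(x$entries)

#' Load a lexicon from a plain-text file
#'
#' One entry per line: the canonical token, optionally followed by variant
#' tokens, whitespace-separated. A line with only the canonical token gets
#' that token as its single variant. Curly quotes and apostrophes are
#' normalized to their ASCII forms before parsing (they appear in lists
#' copied out of manuscripts).
#'
#' @param path file path; lines starting with `#` are comments.
#' @param name lexicon name; defaults to the file's base name.
#' @return a [lexicon()], entries in file order, plus attributes `path` and
#'   `hash` (MD5 of the file) recorded into audit metadata downstream.
#' @export
load_lexicon <- function(path, name = NULL) {
  if (!file.exists(path)) ea_stop("io", "no such file: %s", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- ascii_quotes(lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) ea_stop("empty_lexicon", "no entries in %s", path)
  fields <- strsplit(lines, "[[:space:]]+")
  canon <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(canon)) {
    ea_stop("duplicate_entry", "duplicate canonical label '%s' in %s",
            canon[duplicated(canon)][1L], path)
  }
  entries <- stats::setNames(lapply(fields, function(f) {
    if (length(f) > 1L) unique(f[-1L]) else f[1L]
  }), canon)
  lx <- lexicon(name, entries)
  attr(lx, "path") <- path
  attr(lx, "hash") <- file_hash(path)
  lx
}

ascii_quotes <- function(x) {
  chartr("‘’“”", "''\"\"", x)
}

#' Load one of the lexicons shipped with the package
#'
#' Shipped sets cover the demographic themes of the audits — gender, race,
#' nationality/ethnicity, religion, age, sexuality — plus `family` (gendered
#' family terms), `axes` (pole words such as safe/dangerous, he/she,
#' suicide/healthy) and `diagnoses` (a best-effort reconstruction of a
#' DSM-5-derived diagnosis list; the authoritative list for any given study
#' should be supplied by the analyst, and every audit records the lexicon
#' hash for exactly this reason).
#'
#' @param which one of `"gender"`, `"race"`, `"nationality"`, `"religion"`,
#'   `"age"`, `"sexuality"`, `"family"`, `"axes"`, `"diagnoses"`.
#' @return a [lexicon()].
#' @export
default_lexicon <- function(which = c("gender", "race", "nationality",
                                      "religion", "age", "sexuality",
                                      "family", "axes", "diagnoses")) {
  which <- match.arg(which)
  fname <- if (which == "diagnoses") "diagnoses_dsm5_reconstructed.txt"
           else paste0(which, ".txt")
  path <- system.file("extdata", "lexicons", fname, package = "embaudit")
  if (!nzchar(path)) ea_stop("io", "shipped lexicon '%s' not found", which)
  load_lexicon(path, name = which)
}

# Fetch one entry (canonical -> variants) from a lexicon or pass through a
# bare character vector of variants (first element doubles as canonical).
as_entry <- function(x, lex = NULL) {
  if (is.character(x) && length(x) >= 1L && !is.null(lex) &&
      x[1L] %in% names(lex$entries) && length(x) == 1L) {
    return(list(canonical = x, variants = lex$entries[[x]]))
  }
  if (is.character(x)) {
    return(list(canonical = x[1L], variants = unique(x)))
  }
  if (is.list(x) && !is.null(x$variants)) {
    return(list(canonical = x$canonical %||% x$variants[1L],
                variants = unique(x$variants)))
  }
  ea_stop("invalid_lexicon", "cannot interpret entry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a lexicon entry to a single unit vector
#'
#' Case and phrase variants of one label are combined by taking the
#' arithmetic mean of the unit vectors of all variants present in the
#' vocabulary, then renormalizing to unit length. The mean is symmetric in
#' the variants, so resolution does not depend on variant order. Missing
#' variants are logged and skipped; only total absence is an error (GloVe
#' vocabularies are lowercase-only while word2vec is mixed-case, so partial
#' coverage is the norm, not a defect).
#'
#' @param entry a character vector of variant tokens, or an entry taken from
#'   a [lexicon()] (`list(canonical=, variants=)`).
#' @param set a unit-normalized [embedding_set()].
#' @return list with `vector` (unit-length numeric), `canonical`, `found`
#'   and `missing` variant character vectors.
#' @examples
#' es <- unit_normalize(embedding_set(c("a", "A"), rbind(c(1, 0), c(0, 1))))
#' resolve_term_vector(c("a", "A"), es)$vector
#' @export
resolve_term_vector <- function(entry, set) {
  stopifnot(inherits(set, "embedding_set"))
  if (!set$normalized) {
    ea_stop("not_normalized", "embedding set must be unit-normalized first")
  }
  e <- as_entry(entry)
  present <- e$variants[e$variants %in% set$terms]
  missing <- setdiff(e$variants, present)
  if (length(present) == 0L) {
    ea_stop("oov", "no variant of '%s' in vocabulary (tried: %s)",
            e$canonical, paste(e$variants, collapse = ", "))
  }
  if (length(missing) > 0L) {
    ea_log(sprintf("'%s': variant(s) not in vocabulary, skipped: %s",
                   e$canonical, paste(missing, collapse = ", ")))
  }
  v <- colMeans(set$vectors[present, , drop = FALSE])
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    ea_stop("degenerate_vector",
            "variants of '%s' cancel to the zero vector", e$canonical)
  }
  list(vector = v / nrm, canonical = e$canonical,
       found = present, missing = missing)
}
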