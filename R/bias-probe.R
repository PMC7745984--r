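#' Cosine similarity between two vectors
#'
#' Symmetric, bounded in [-1, 1]; 1 means identical direction (a term
#' compared with itself), -1 opposite. This is the score underlying every
#' ranking in the package.
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return a single number in [-1, 1].
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1))  # 0
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    ea_stop("degenerate_vector", "cosine similarity of a zero vector")
  }
  s <- sum(u * v) / (nu * nv)
  max(-1, min(1, s))
}

# All variants of the given entries, for candidate exclusion.
entry_variants <- function(entries) {
  unique(unlist(lapply(entries, function(e) as_entry(e)$variants)))
}

# Build the candidate pool: restriction lexicon's resolvable entries (one
# pooled vector per entry, canonical as the returned term) or the raw
# vocabulary.
candidate_pool <- function(set, restrict = NULL, exclude_tokens = character(),
                           exclude_canonical = character()) {
  if (is.null(restrict)) {
    keep <- !(set$terms %in% exclude_tokens)
    list(terms = set$terms[keep],
         vectors = set$vectors[keep, , drop = FALSE])
  } else {
    stopifnot(inherits(restrict, "lexicon"))
    canon <- names(restrict$entries)
    rows <- vector("list", length(canon))
    ok <- logical(length(canon))
    for (i in seq_along(canon)) {
      if (canon[i] %in% exclude_canonical) next
      vars <- restrict$entries[[i]]
      if (any(vars %in% exclude_tokens)) next
      present <- vars[vars %in% set$terms]
      if (length(present) == 0L) next
      v <- colMeans(set$vectors[present, , drop = FALSE])
      nrm <- sqrt(sum(v^2))
      if (nrm == 0) next
      rows[[i]] <- v / nrm
      ok[i] <- TRUE
    }
    list(terms = canon[ok], vectors = do.call(rbind, rows[ok]))
  }
}

#' Complete an analogy by vector arithmetic (3CosAdd)
#'
#' Answers "w1 is to w2 as w3 is to ?" by forming the query vector
#' q = v(w2) - v(w1) + v(w3), renormalizing it, and ranking candidate terms
#' by cosine similarity to q. With `score_rule = "pairwise"` the ranking is
#' unchanged conceptually but candidates are scored by cosine to v(w3)
#' alone after being retrieved by q — the two readings of a printed
#' "vector similarity" column — so both can be compared; the rule used is
#' recorded in audit metadata.
#'
#' @param set a unit-normalized [embedding_set()].
#' @param w1 reference attribute entry (e.g. "depression"): character
#'   vector of variants or a lexicon entry.
#' @param w2 reference group entry (e.g. "british").
#' @param w3 probe group entry (e.g. "irish").
#' @param restrict optional [lexicon()]; candidates are its resolvable
#'   entries instead of the full vocabulary.
#' @param exclude_inputs drop all variants of w1, w2, w3 from the candidate
#'   pool (default `TRUE`; an analogy answered by one of its own query words
#'   is vacuous).
#' @param top_k number of completions to return.
#' @param score_rule `"3cosadd"` (cosine to the renormalized query, default)
#'   or `"pairwise"` (cosine to v(w3)).
#' @return data.frame with columns `term`, `score`, sorted by score
#'   descending, ties broken lexicographically.
#' @examples
#' es <- unit_normalize(embedding_set(
#'   c("king", "queen", "man", "woman"),
#'   rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 0.1), c(0, 0.1, 1))))
#' analogy_query(es, "king", "queen", "man", top_k = 1)
#' @export
analogy_query <- function(set, w1, w2, w3, restrict = NULL,
                          exclude_inputs = TRUE, top_k = 3L,
                          score_rule = c("3cosadd", "pairwise")) {
  score_rule <- match.arg(score_rule)
  stopifnot(inherits(set, "embedding_set"), top_k >= 1L)
  if (!set$normalized) {
    ea_stop("not_normalized", "embedding set must be unit-normalized first")
  }
  r1 <- resolve_term_vector(w1, set)
  r2 <- resolve_term_vector(w2, set)
  r3 <- resolve_term_vector(w3, set)
  q <- r2$vector - r1$vector + r3$vector
  nq <- sqrt(sum(q^2))
  if (nq == 0) ea_stop("degenerate_vector", "query vector is zero")
  q <- q / nq

  excl_tok <- if (exclude_inputs) {
    entry_variants(list(w1, w2, w3))
  } else character()
  excl_can <- if (exclude_inputs) {
    c(r1$canonical, r2$canonical, r3$canonical)
  } else character()
  pool <- candidate_pool(set, restrict, excl_tok, excl_can)
  if (length(pool$terms) == 0L) {
    ea_stop("empty_candidates", "no candidates left after exclusion")
  }
  ref <- if (score_rule == "3cosadd") q else r3$vector
  scores <- as.numeric(pool$vectors %*% ref)
  # rank always follows the analogy query; pairwise only re-labels the score
  rank_scores <- as.numeric(pool$vectors %*% q)
  ord <- order(-rank_scores, pool$terms, method = "radix")
  ord <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(term = pool$terms[ord], score = pmin(1, pmax(-1, scores[ord])),
             stringsAsFactors = FALSE)
}

#' Rank a lexicon's terms by closeness to a demographic label
#'
#' The nearest-diagnosis audit: resolve the label to a single unit vector
#' (case variants combined) and rank every resolvable entry of the lexicon
#' by cosine similarity to it. By default the label's own variants are
#' excluded from the candidates if the lexicon happens to contain them.
#'
#' @param set a unit-normalized [embedding_set()].
#' @param label entry for the demographic label: character vector of
#'   variants or a lexicon entry.
#' @param lex a [lexicon()] of candidate terms (e.g. the diagnosis list).
#' @param top_k number of terms to return.
#' @param exclude_self drop the label's own variants from candidates.
#' @return data.frame with columns `term`, `score`, score-descending,
#'   lexicographic tie-break.
#' @export
nearest_in_lexicon <- function(set, label, lex, top_k = 3L,
                               exclude_self = TRUE) {
  stopifnot(inherits(set, "embedding_set"), inherits(lex, "lexicon"),
            top_k >= 1L)
  if (!set$normalized) {
    ea_stop("not_normalized", "embedding set must be unit-normalized first")
  }
  r <- resolve_term_vector(label, set)
  excl_tok <- if (exclude_self) as_entry(label)$variants else character()
  excl_can <- if (exclude_self) r$canonical else character()
  pool <- candidate_pool(set, lex, excl_tok, excl_can)
  if (length(pool$terms) == 0L) {
    ea_stop("empty_candidates", "no lexicon entry resolvable in vocabulary")
  }
  scores <- as.numeric(pool$vectors %*% r$vector)
  rank_scored(pool$terms, pmin(1, pmax(-1, scores)), top_k)
}

#' Run an audit over a whole label set
#'
#' One row per resolvable label. When `against` is a [lexicon()], each row
#' is a [nearest_in_lexicon()] ranking (the nearest-diagnosis table). When
#' `against` is an analogy template `list(w1 = ..., w2 = ...)`, each label
#' plays w3 in [analogy_query()] (the analogy table, one fixed reference
#' pair). Labels with no variant in the vocabulary are logged and skipped.
#'
#' @param set a unit-normalized [embedding_set()].
#' @param labels a [lexicon()] of demographic labels.
#' @param against a [lexicon()] or a template `list(w1=, w2=, restrict=)`.
#' @param top_k results per label.
#' @param ... passed to [nearest_in_lexicon()] or [analogy_query()].
#' @return an `audit_table`: `$rows` data.frame (label, rank, term, score)
#'   and `$metadata` (embedding source and dim, lexicon names/hashes,
#'   settings, scoring rule).
#' @export
batch_audit <- function(set, labels, against, top_k = 3L, ...) {
  stopifnot(inherits(set, "embedding_set"), inherits(labels, "lexicon"))
  analogy <- !inherits(against, "lexicon")
  if (analogy && (is.null(against$w1) || is.null(against$w2))) {
    ea_stop("config", "analogy template needs w1 and w2")
  }
  rows <- list()
  skipped <- character()
  for (canon in names(labels$entries)) {
    entry <- labels$entries[[canon]]
    res <- tryCatch({
      if (analogy) {
        analogy_query(set, against$w1, against$w2, entry,
                      restrict = against$restrict, top_k = top_k, ...)
      } else {
        nearest_in_lexicon(set, entry, against, top_k = top_k, ...)
      }
    }, embaudit_oov = function(e) NULL)
    if (is.null(res)) {
      skipped <- c(skipped, canon)
      next
    }
    rows[[canon]] <- data.frame(label = canon, rank = seq_len(nrow(res)),
                                term = res$term, score = res$score,
                                stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0L) {
    ea_log(sprintf("skipped out-of-vocabulary label(s): %s",
                   paste(skipped, collapse = ", ")), level = "warn")
  }
  if (length(rows) == 0L) {
    ea_stop("empty_audit", "no label of '%s' resolvable in vocabulary",
            labels$name)
  }
  dots <- list(...)
  meta <- list(
    embedding_source = set$source,
    dim = set$dim,
    normalized = set$normalized,
    mode = if (analogy) "analogy" else "nearest",
    labels_lexicon = labels$name,
    labels_hash = attr(labels, "hash") %||% object_hash(labels$entries),
    against = if (analogy) {
      list(w1 = as_entry(against$w1)$canonical,
           w2 = as_entry(against$w2)$canonical,
           restrict = if (!is.null(against$restrict)) against$restrict$name)
    } else {
      list(lexicon = against$name,
           hash = attr(against, "hash") %||% object_hash(against$entries))
    },
    top_k = top_k,
    score_rule = dots$score_rule %||% "3cosadd",
    skipped_labels = skipped,
    resolution = "mean of unit variant vectors, renormalized"
  )
  structure(list(rows = do.call(rbind, c(rows, make.row.names = FALSE)),
                 metadata = meta),
            class = "audit_table")
}

#' @export
print.audit_table <- function(x, ...) {
  cat(sprintf("<audit_table> %s audit, %d labels x top-%d (%dd embedding)\n",
              x$metadata$mode, length(unique(x$rows$label)),
              x$metadata$top_k, x$metadata$dim))
  print(utils::head(x$rows, 12L), row.names = FALSE)
  if (nrow(x$rows) > 12L) cat("  ...\n")
  invisible(x)
}

#' Write an audit table to TSV (rows) or JSON (rows + metadata)
#'
#' @param audit an `audit_table` from [batch_audit()].
#' @param path output path; `.json` gets the metadata block, anything else
#'   a four-column TSV (label, rank, term, score).
#' @return `path`, invisibly.
#' @export
write_audit <- function(audit, path) {
  stopifnot(inherits(audit, "audit_table"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(metadata = audit$metadata, rows = audit$rows),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(audit$rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
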