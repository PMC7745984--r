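#' Construct an embedding set
#'
#' An `embedding_set` holds an ordered vocabulary and one d-dimensional real
#' vector per token, the in-memory form of a GloVe text or word2vec binary
#' file. Row order mirrors file order so index i corresponds to line/record i.
#'
#' @param terms character vector of unique tokens (no whitespace).
#' @param vectors numeric matrix, one row per term, `d` columns.
#' @param normalized logical; `TRUE` asserts every row has unit Euclidean
#'   norm (within 1e-6). Set by [unit_normalize()], not by hand.
#' @param source free-text provenance label (file path, generator settings).
#' @return an object of class `embedding_set` with fields `terms`, `vectors`
#'   (rownames = terms), `dim`, `normalized`, `source`.
#' @examples
#' es <- embedding_set(c("a", "b"), rbind(c(1, 0), c(0, 1)))
#' es$dim
#' @export
embedding_set <- function(terms, vectors, normalized = FALSE, source = "") {
  terms <- as.character(terms)
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = length(terms))
  storage.mode(vectors) <- "double"
  if (length(terms) != nrow(vectors)) {
    ea_stop("invalid_set", "got %d terms but %d vector rows",
            length(terms), nrow(vectors))
  }
  if (anyDuplicated(terms)) {
    dup <- terms[duplicated(terms)][1L]
    ea_stop("duplicate_term", "duplicate token in vocabulary: '%s'", dup)
  }
  if (any(grepl("[[:space:]]", terms))) {
    ea_stop("invalid_token", "token contains whitespace: '%s'",
            terms[grepl("[[:space:]]", terms)][1L])
  }
  if (!all(is.finite(vectors))) {
    ea_stop("invalid_set", "non-finite vector components present")
  }
  rownames(vectors) <- terms
  out <- structure(list(terms = terms, vectors = vectors,
                        dim = ncol(vectors), normalized = isTRUE(normalized),
                        source = source),
                   class = "embedding_set")
  if (out$normalized) {
    nrm <- sqrt(rowSums(vectors^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      ea_stop("invalid_set", "normalized flag set but row norms deviate from 1")
    }
  }
  out
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d terms x %d dims%s\n", length(x$terms),
              x$dim, if (x$normalized) " (unit-normalized)" else ""))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Unit-normalize every row of an embedding set
#'
#' Cosine ranking assumes unit vectors; all audit operations require a
#' normalized set. Idempotent.
#'
#' @param set an [embedding_set()].
#' @return the set with every row scaled to unit Euclidean norm and the
#'   `normalized` flag set.
#' @examples
#' es <- embedding_set("x", matrix(c(3, 4), 1))
#' unit_normalize(es)$vectors  # (0.6, 0.8)
#' @export
unit_normalize <- function(set) {
  stopifnot(inherits(set, "embedding_set"))
  nrm <- sqrt(rowSums(set$vectors^2))
  if (any(nrm == 0)) {
    ea_stop("degenerate_vector", "zero vector for term '%s'",
            set$terms[nrm == 0][1L])
  }
  v <- set$vectors / nrm
  embedding_set(set$terms, v, normalized = TRUE, source = set$source)
}

# Fetch the vectors of tokens that exist in the vocabulary; always a matrix.
set_vectors <- function(set, tokens) {
  hit <- tokens[tokens %in% set$terms]
  set$vectors[hit, , drop = FALSE]
}

#' Test which tokens are in an embedding's vocabulary
#'
#' @param set an [embedding_set()].
#' @param tokens character vector.
#' @return logical vector parallel to `tokens`.
#' @export
in_vocabulary <- function(set, tokens) {
  tokens %in% set$terms
}
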