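# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's ranking code paths: plain sum/sqrt cosines and full sorts.

tiny_set <- function(normalized = TRUE) {
  es <- embedding_set(
    c("a", "b", "c", "d"),
    rbind(c(1, 0), c(0, 1), c(1, 1), c(-1, 0)))
  if (normalized) unit_normalize(es) else es
}

# cosine from first principles
oracle_cos <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

# exhaustive ranking of candidate rows against a query vector:
# score descending, lexicographic tie-break
oracle_rank <- function(q, terms, vectors, k = length(terms)) {
  s <- apply(vectors, 1L, oracle_cos, v = q)
  ord <- order(-s, terms, method = "radix")[seq_len(min(k, length(terms)))]
  data.frame(term = terms[ord], score = s[ord], stringsAsFactors = FALSE)
}

# resolve an entry the way the package documents it, but independently:
# mean of unit rows, renormalized
oracle_resolve <- function(set, variants) {
  present <- variants[variants %in% set$terms]
  m <- set$vectors[present, , drop = FALSE]
  m <- m / sqrt(rowSums(m^2))
  v <- colMeans(m)
  v / sqrt(sum(v^2))
}

# Kendall tau-a by definition, coded separately from the package version
oracle_tau <- function(x, y) {
  n <- length(x)
  pairs <- utils::combn(n, 2L)
  s <- sign(x[pairs[2L, ]] - x[pairs[1L, ]]) *
    sign(y[pairs[2L, ]] - y[pairs[1L, ]])
  sum(s) / ncol(pairs)
}

# run every planted analogy probe of a space, return top-1 hit fraction
planted_analogy_top1 <- function(space, set = NULL, top_k = 1L) {
  es <- set %||% unit_normalize(space$set)
  pr <- space$truth$probes
  hits <- vapply(seq_len(nrow(pr)), function(i) {
    r <- analogy_query(es,
                       space$truth$diagnoses$entries[[pr$w1[i]]],
                       space$truth$groups$entries[[pr$w2[i]]],
                       space$truth$groups$entries[[pr$w3[i]]],
                       restrict = space$truth$diagnoses, top_k = top_k)
    r$term[1L] == pr$target[i]
  }, TRUE)
  mean(hits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
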