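#' Configuration for a synthetic planted-bias embedding space
#'
#' The generator builds an embedding space whose geometry encodes a known
#' demographic-group-to-diagnosis bias structure, so analogy probes,
#' nearest-diagnosis audits and gradient rankings can be validated against
#' ground truth without downloading real multi-gigabyte embeddings.
#'
#' Construction: one base direction per group, diagnosis and gradient pole,
#' drawn as standard normal vectors and orthonormalized (QR), so planted
#' signals are exactly separable before noise. Each group's vector is its
#' own direction displaced by `bias_magnitude` toward its planted
#' diagnosis's direction; isotropic Gaussian noise with standard deviation
#' `noise_sd` is then added to every component of every vector. A fraction
#' `case_variant_rate` of tokens also appear capitalized as a noisy
#' duplicate, emulating mixed-case vocabularies. Eight gradient terms are
#' laid out at evenly spaced mixtures of the two pole directions.
#'
#' @param dim embedding dimension (must be at least
#'   `n_groups + n_diagnoses + 2` so base directions can be orthonormal).
#' @param n_groups number of demographic group terms.
#' @param n_diagnoses number of diagnosis terms (groups are assigned
#'   diagnoses cyclically).
#' @param n_background filler vocabulary size (random directions).
#' @param bias_magnitude length of the group-to-diagnosis displacement;
#'   0 plants no bias.
#' @param noise_sd per-component Gaussian noise standard deviation.
#' @param case_variant_rate fraction of tokens duplicated in capitalized
#'   form.
#' @param seed integer seed; all randomness comes from one stream, so equal
#'   seeds give bit-identical spaces.
#' @return a `plant_config` list.
#' @export
plant_config <- function(dim = 50L, n_groups = 6L, n_diagnoses = 12L,
                         n_background = 100L, bias_magnitude = 0.5,
                         noise_sd = 0.1, case_variant_rate = 0.3,
                         seed = 1L) {
  cfg <- list(dim = as.integer(dim), n_groups = as.integer(n_groups),
              n_diagnoses = as.integer(n_diagnoses),
              n_background = as.integer(n_background),
              bias_magnitude = bias_magnitude, noise_sd = noise_sd,
              case_variant_rate = case_variant_rate, seed = as.integer(seed))
  if (cfg$dim < 2L || cfg$n_groups < 1L || cfg$n_diagnoses < 1L ||
      cfg$n_background < 0L) {
    ea_stop("config", "counts out of range")
  }
  if (cfg$bias_magnitude < 0 || cfg$noise_sd < 0 ||
      cfg$case_variant_rate < 0 || cfg$case_variant_rate > 1) {
    ea_stop("config", "magnitudes/rates out of range")
  }
  n_planted <- cfg$n_groups + cfg$n_diagnoses + 2L
  if (cfg$dim < n_planted) {
    ea_stop("config",
            "dim %d cannot hold %d orthogonal planted directions",
            cfg$dim, n_planted)
  }
  structure(cfg, class = "plant_config")
}

capitalize <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

#' Generate a synthetic embedding space with planted bias
#'
#' @param config a [plant_config()].
#' @return a `planted_space`: `$set` (an [embedding_set()], not yet
#'   normalized, like a file fresh off disk), `$truth` with
#'   `group_diagnosis` (named map), `probes` (data.frame `w1`, `w2`, `w3`,
#'   `target`: analogy queries whose intended completion is known),
#'   `gradient` (pole names and the planted ascending ordering), and
#'   `groups`/`diagnoses`/`gradient_terms` [lexicon()]s including any case
#'   variants, and `$config`.
#' @examples
#' sp <- generate_planted_space(plant_config(noise_sd = 0, seed = 7))
#' es <- unit_normalize(sp$set)
#' nearest_in_lexicon(es, sp$truth$groups$entries[[1]],
#'                    sp$truth$diagnoses, top_k = 1)
#' @export
generate_planted_space <- function(config) {
  stopifnot(inherits(config, "plant_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  d <- config$dim
  ng <- config$n_groups; nd <- config$n_diagnoses
  n_grad <- 8L
  n_dirs <- ng + nd + 2L
  # exactly orthonormal planted directions
  basis <- qr.Q(qr(matrix(stats::rnorm(d * n_dirs), nrow = d)))
  g_dirs <- t(basis[, seq_len(ng), drop = FALSE])
  d_dirs <- t(basis[, ng + seq_len(nd), drop = FALSE])
  pole_lo <- basis[, ng + nd + 1L]
  pole_hi <- basis[, ng + nd + 2L]

  assign_d <- ((seq_len(ng) - 1L) %% nd) + 1L
  group_terms <- sprintf("group%02d", seq_len(ng))
  diag_terms <- sprintf("diagnosis_%02d", seq_len(nd))
  grad_terms <- sprintf("grad_%02d", seq_len(n_grad))
  bg_terms <- if (config$n_background > 0L)
    sprintf("word%04d", seq_len(config$n_background)) else character()

  g_vecs <- g_dirs + config$bias_magnitude * d_dirs[assign_d, , drop = FALSE]
  w <- (seq_len(n_grad) - 1L) / (n_grad - 1L)
  grad_vecs <- outer(1 - w, pole_lo) + outer(w, pole_hi)
  bg_vecs <- matrix(stats::rnorm(config$n_background * d),
                    nrow = config$n_background, ncol = d)
  if (config$n_background > 0L) {
    bg_vecs <- bg_vecs / sqrt(rowSums(bg_vecs^2))
  }

  terms <- c(group_terms, diag_terms, "pole_low", "pole_high", grad_terms,
             bg_terms)
  vecs <- rbind(g_vecs, d_dirs, matrix(pole_lo, 1L), matrix(pole_hi, 1L),
                grad_vecs, bg_vecs)
  vecs <- vecs + matrix(stats::rnorm(length(vecs), sd = config$noise_sd),
                        nrow = nrow(vecs))

  # capitalized noisy duplicates
  dup <- stats::runif(length(terms)) < config$case_variant_rate
  cap <- capitalize(terms[dup])
  dup[dup] <- !(cap %in% terms) & cap != terms[dup]
  cap <- capitalize(terms[dup])
  if (any(dup)) {
    cap_vecs <- vecs[dup, , drop = FALSE] +
      matrix(stats::rnorm(sum(dup) * d, sd = config$noise_sd), nrow = sum(dup))
    terms <- c(terms, cap)
    vecs <- rbind(vecs, cap_vecs)
  }

  variants_of <- function(tok) {
    v <- tok
    ctok <- capitalize(tok)
    if (ctok %in% terms && ctok != tok) v <- c(v, ctok)
    v
  }
  mk_lex <- function(name, toks) {
    lexicon(name, stats::setNames(lapply(toks, variants_of), toks))
  }

  group_diag <- stats::setNames(diag_terms[assign_d], group_terms)
  probes <- NULL
  if (ng >= 2L) {
    w3 <- group_terms[-1L]
    tgt <- group_diag[w3]
    keep <- tgt != group_diag[[1L]]
    if (any(keep)) {
      probes <- data.frame(w1 = group_diag[[1L]], w2 = group_terms[1L],
                           w3 = w3[keep], target = unname(tgt[keep]),
                           stringsAsFactors = FALSE)
    }
  }

  set <- embedding_set(terms, vecs, normalized = FALSE,
                       source = sprintf("planted(seed=%d,bias=%g,noise=%g)",
                                        config$seed, config$bias_magnitude,
                                        config$noise_sd))
  truth <- list(
    group_diagnosis = group_diag,
    probes = probes,
    gradient = list(pole_low = "pole_low", pole_high = "pole_high",
                    ordering = grad_terms),
    groups = mk_lex("planted_groups", group_terms),
    diagnoses = mk_lex("planted_diagnoses", diag_terms),
    gradient_terms = mk_lex("planted_gradient", grad_terms)
  )
  structure(list(set = set, truth = truth, config = config),
            class = "planted_space")
}

#' @export
print.planted_space <- function(x, ...) {
  cat(sprintf(
    "<planted_space> %d terms x %d dims (%d groups, %d diagnoses, bias %g, noise %g, seed %d)\n",
    length(x$set$terms), x$config$dim, x$config$n_groups,
    x$config$n_diagnoses, x$config$bias_magnitude, x$config$noise_sd,
    x$config$seed))
  invisible(x)
}

#' Score an audit of a planted space against its ground truth
#'
#' @param space a `planted_space`.
#' @param audit an `audit_table` from [batch_audit()] run on `space$set`
#'   with the planted group labels (nearest-diagnosis mode or analogy mode;
#'   in both, the truth for each group label is its planted diagnosis).
#' @return list with `top1` (fraction of labels whose rank-1 term is the
#'   planted diagnosis) and `mrr` (mean reciprocal rank of the planted
#'   diagnosis; an absent truth term contributes 0).
#' @export
recovery_metrics <- function(space, audit) {
  stopifnot(inherits(space, "planted_space"), inherits(audit, "audit_table"))
  labels <- unique(audit$rows$label)
  truth <- space$truth$group_diagnosis
  if (!all(labels %in% names(truth))) {
    ea_stop("incomparable", "audit labels are not planted group terms")
  }
  rr <- vapply(labels, function(lb) {
    rows <- audit$rows[audit$rows$label == lb, ]
    hit <- which(rows$term == truth[[lb]])
    if (length(hit) == 0L) 0 else 1 / rows$rank[hit[1L]]
  }, 0)
  list(top1 = mean(rr == 1), mrr = mean(rr))
}

#' Write a planted space to disk as fixture files
#'
#' Emits the space in both embedding dialects plus the ground truth as
#' JSON, so file readers and downstream audits can be exercised on the
#' same planted structure.
#'
#' @param space a `planted_space`.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_planted_space <- function(space, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(glove = file.path(dir, "planted_glove.txt"),
             word2vec = file.path(dir, "planted_word2vec.bin"),
             truth = file.path(dir, "planted_truth.json"))
  write_glove_text(space$set, paths[["glove"]])
  write_word2vec_binary(space$set, paths[["word2vec"]])
  truth <- space$truth
  jsonlite::write_json(
    list(config = unclass(space$config),
         group_diagnosis = as.list(truth$group_diagnosis),
         probes = truth$probes,
         gradient = truth$gradient,
         groups = truth$groups$entries,
         diagnoses = truth$diagnoses$entries,
         gradient_terms = truth$gradient_terms$entries),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
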