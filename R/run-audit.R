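#' Run a full embedding bias audit from a declarative configuration
#'
#' Ties the stages together: load an embedding file, resolve lexicons, run
#' the configured analogy probes, nearest-diagnosis audits and axis
#' placements/gradients, optionally repeat the axis analyses on other
#' dimensionalities of the model and compare stability, and write every
#' table plus a run manifest into an output directory. Outputs are
#' deterministic functions of config + input files: re-running an identical
#' config reproduces byte-identical tables.
#'
#' The configuration (YAML file or equivalent list) has fields:
#' \describe{
#'   \item{embeddings}{path to the embedding file.}
#'   \item{format}{`"glove"` or `"word2vec-bin"`.}
#'   \item{lexicons}{named map of lexicon name to file path; shipped
#'     defaults (see [default_lexicon()]) are available by bare name.}
#'   \item{probes}{list of `{name, w1, w2, w3, restrict}` analogy specs.
#'     Terms are written `"lexicon:entry"` to use a lexicon entry's
#'     variants, or as a bare token (its capitalized form is tried too).}
#'   \item{nearest}{list of `{name, labels, against}` lexicon-name pairs.}
#'   \item{axes}{list of `{name, terms, low, high}` (gradient) or
#'     `{name, terms, x_low, x_high, y_low, y_high}` (plane) specs.}
#'   \item{compare_dims}{named map of dimensionality label to embedding
#'     path; every axis analysis is repeated there and compared with the
#'     primary embedding.}
#'   \item{top_k, score_rule, out, seed}{ranking depth, `"3cosadd"` or
#'     `"pairwise"`, output directory, integer seed.}
#' }
#'
#' @param config path to a YAML file, or a list with the fields above.
#' @param out output directory; overrides `config$out`.
#' @return invisibly, a list with the loaded `set`, the result objects
#'   (`analogy`, `nearest`, `axes`, `stability`) and `files` (all paths
#'   written, manifest last).
#' @export
run_audit <- function(config, out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_run_config(config, out)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  set <- switch(cfg$format,
                "glove" = read_glove_text(cfg$embeddings),
                "word2vec-bin" = read_word2vec_binary(cfg$embeddings))
  set <- unit_normalize(set)
  lexs <- load_config_lexicons(cfg)

  files <- character()
  results <- list(analogy = list(), nearest = list(), axes = list(),
                  stability = list())

  spec_entry <- function(s) {
    if (grepl(":", s, fixed = TRUE)) {
      parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
      lx <- lexs[[parts[1L]]]
      if (is.null(lx) || !parts[2L] %in% names(lx$entries)) {
        ea_stop("config", "unknown lexicon entry '%s'", s)
      }
      lx$entries[[parts[2L]]]
    } else unique(c(s, capitalize(s)))
  }

  for (p in cfg$probes) {
    labels <- lexicon(p$name, stats::setNames(list(spec_entry(p$w3)), p$w3))
    tab <- batch_audit(set, labels,
                       list(w1 = spec_entry(p$w1), w2 = spec_entry(p$w2),
                            restrict = if (!is.null(p$restrict)) lexs[[p$restrict]]),
                       top_k = cfg$top_k, score_rule = cfg$score_rule)
    results$analogy[[p$name]] <- tab
    f <- file.path(cfg$out, sprintf("analogy_%s.tsv", p$name))
    write_audit(tab, f)
    write_audit(tab, sub("\\.tsv$", ".json", f))
    files <- c(files, f, sub("\\.tsv$", ".json", f))
  }

  for (p in cfg$nearest) {
    tab <- batch_audit(set, lexs[[p$labels]], lexs[[p$against]],
                       top_k = cfg$top_k)
    results$nearest[[p$name]] <- tab
    f <- file.path(cfg$out, sprintf("nearest_%s.tsv", p$name))
    write_audit(tab, f)
    write_audit(tab, sub("\\.tsv$", ".json", f))
    files <- c(files, f, sub("\\.tsv$", ".json", f))
  }

  run_axes <- function(es) {
    lapply(cfg$axes, function(a) {
      if (!is.null(a$low)) {
        gradient_rank(es, lexs[[a$terms]],
                      axis_spec(spec_entry(a$low), spec_entry(a$high)))
      } else {
        project_plane(es, lexs[[a$terms]],
                      axis_spec(spec_entry(a$x_low), spec_entry(a$x_high)),
                      axis_spec(spec_entry(a$y_low), spec_entry(a$y_high)))
      }
    })
  }
  axis_names <- vapply(cfg$axes, `[[`, "", "name")
  primary_axes <- run_axes(set)
  names(primary_axes) <- axis_names
  results$axes <- primary_axes
  for (nm in axis_names) {
    f <- file.path(cfg$out, sprintf("axes_%s.tsv", nm))
    write_coordinates(primary_axes[[nm]], f)
    files <- c(files, f)
  }

  if (length(cfg$compare_dims) > 0L && length(cfg$axes) > 0L) {
    per_dim <- list()
    per_dim[[as.character(set$dim)]] <- primary_axes
    for (lab in names(cfg$compare_dims)) {
      other <- switch(cfg$format,
                      "glove" = read_glove_text(cfg$compare_dims[[lab]]),
                      "word2vec-bin" = read_word2vec_binary(cfg$compare_dims[[lab]]))
      per_dim[[lab]] <- run_axes(unit_normalize(other))
    }
    for (i in seq_along(axis_names)) {
      rep_i <- stability_compare(lapply(per_dim, `[[`, i))
      results$stability[[axis_names[i]]] <- rep_i
      f <- file.path(cfg$out, sprintf("stability_%s.json", axis_names[i]))
      write_stability(rep_i, f)
      files <- c(files, f)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("embaudit")),
    embeddings = list(path = cfg$embeddings, format = cfg$format,
                      md5 = file_hash(cfg$embeddings), dim = set$dim,
                      vocabulary = length(set$terms)),
    lexicons = lapply(lexs, function(l)
      list(name = l$name, hash = attr(l, "hash") %||% object_hash(l$entries))),
    settings = cfg[c("top_k", "score_rule", "seed")],
    normalization = "rows unit-normalized on load; cosine on unit vectors",
    coordinate_rule = "cos(term, pole_high) - cos(term, pole_low)",
    outputs = basename(files)
  )
  mf <- file.path(cfg$out, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, mf)
  ea_log(sprintf("audit complete: %d file(s) in %s", length(files), cfg$out))
  invisible(c(results, list(set = set, files = files)))
}

validate_run_config <- function(config, out = NULL) {
  stopifnot(is.list(config))
  cfg <- config
  cfg$out <- out %||% cfg$out %||% ea_stop("config", "no output directory")
  if (is.null(cfg$embeddings)) ea_stop("config", "no embeddings path")
  if (!file.exists(cfg$embeddings)) {
    ea_stop("io", "embedding file not found: %s", cfg$embeddings)
  }
  cfg$format <- cfg$format %||% "glove"
  if (!cfg$format %in% c("glove", "word2vec-bin")) {
    ea_stop("config", "format must be glove or word2vec-bin")
  }
  cfg$top_k <- as.integer(cfg$top_k %||% 3L)
  if (cfg$top_k < 1L) ea_stop("config", "top_k must be >= 1")
  cfg$score_rule <- cfg$score_rule %||% "3cosadd"
  if (!cfg$score_rule %in% c("3cosadd", "pairwise")) {
    ea_stop("config", "score_rule must be 3cosadd or pairwise")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$probes <- cfg$probes %||% list()
  cfg$nearest <- cfg$nearest %||% list()
  cfg$axes <- cfg$axes %||% list()
  cfg$compare_dims <- cfg$compare_dims %||% list()
  for (p in cfg$probes) {
    if (is.null(p$name) || is.null(p$w1) || is.null(p$w2) || is.null(p$w3)) {
      ea_stop("config", "probe needs name, w1, w2, w3")
    }
  }
  for (p in cfg$nearest) {
    if (is.null(p$name) || is.null(p$labels) || is.null(p$against)) {
      ea_stop("config", "nearest audit needs name, labels, against")
    }
  }
  for (a in cfg$axes) {
    grad <- !is.null(a$low) && !is.null(a$high)
    plane <- !is.null(a$x_low) && !is.null(a$x_high) &&
      !is.null(a$y_low) && !is.null(a$y_high)
    if (is.null(a$name) || is.null(a$terms) || !(grad || plane)) {
      ea_stop("config", "axis spec needs name, terms, and low/high or x_/y_ poles")
    }
  }
  for (pth in unlist(cfg$compare_dims)) {
    if (!file.exists(pth)) ea_stop("io", "embedding file not found: %s", pth)
  }
  cfg
}

load_config_lexicons <- function(cfg) {
  shipped <- c("gender", "race", "nationality", "religion", "age",
               "sexuality", "family", "axes", "diagnoses")
  named <- lapply(cfg$lexicons %||% list(), load_lexicon)
  used <- unique(c(
    vapply(cfg$probes, function(p) p$restrict %||% "", ""),
    vapply(cfg$nearest, function(p) p$labels, ""),
    vapply(cfg$nearest, function(p) p$against, ""),
    vapply(cfg$axes, function(a) a$terms, ""),
    unlist(lapply(c(cfg$probes, cfg$axes), function(p) {
      specs <- unlist(p[c("w1", "w2", "w3", "low", "high",
                          "x_low", "x_high", "y_low", "y_high")])
      sub(":.*$", "", specs[grepl(":", specs %||% character())])
    }))
  ))
  used <- setdiff(used[nzchar(used)], names(named))
  for (nm in used) {
    if (nm %in% shipped) {
      named[[nm]] <- default_lexicon(nm)
    } else if (file.exists(nm)) {
      named[[nm]] <- load_lexicon(nm)
    } else {
      ea_stop("config", "unknown lexicon '%s'", nm)
    }
  }
  named
}
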