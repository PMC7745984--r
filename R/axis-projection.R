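#' Define a semantic axis from two opposing pole words
#'
#' @param pole_low,pole_high entries (character vectors of variants or
#'   lexicon entries) for the two poles, e.g. "dangerous"/"safe" or
#'   "he"/"she". Negative coordinates mean closer to `pole_low`.
#' @param name axis label used in output tables; defaults to
#'   `"low..high"`.
#' @return an object of class `axis_spec`.
#' @export
axis_spec <- function(pole_low, pole_high, name = NULL) {
  lo <- as_entry(pole_low); hi <- as_entry(pole_high)
  if (identical(sort(lo$variants), sort(hi$variants))) {
    ea_stop("config", "axis poles must be distinct")
  }
  if (is.null(name)) name <- paste0(lo$canonical, "..", hi$canonical)
  structure(list(pole_low = lo, pole_high = hi, name = name),
            class = "axis_spec")
}

#' @export
print.axis_spec <- function(x, ...) {
  cat(sprintf("<axis_spec '%s'> %s (-) ... %s (+)\n", x$name,
              x$pole_low$canonical, x$pole_high$canonical))
  invisible(x)
}

#' Scalar coordinate of a term along a pole axis
#'
#' The coordinate is the difference of cosines to the two poles,
#' cos(term, pole_high) - cos(term, pole_low): positive means closer to
#' `pole_high`, bounded in [-2, 2], antisymmetric under pole swap, and
#' invariant to vector scale. This is the rule behind all placements and
#' gradients and is recorded in every output.
#'
#' @param set a unit-normalized [embedding_set()].
#' @param term entry to place.
#' @param axis an [axis_spec()].
#' @return a single number in [-2, 2].
#' @export
axis_coordinate <- function(set, term, axis) {
  stopifnot(inherits(axis, "axis_spec"))
  t <- resolve_term_vector(term, set)
  lo <- resolve_term_vector(axis$pole_low, set)
  hi <- resolve_term_vector(axis$pole_high, set)
  sum(t$vector * hi$vector) - sum(t$vector * lo$vector)
}

#' Place a set of terms in the plane of two pole axes
#'
#' The 2-D placement: each term gets an x coordinate along `x_axis`
#' and a y coordinate along `y_axis` (e.g. she/he crossed with
#' safe/dangerous). Unresolvable terms are logged and skipped.
#'
#' @param set a unit-normalized [embedding_set()].
#' @param terms a [lexicon()] of terms to place.
#' @param x_axis,y_axis [axis_spec()] objects.
#' @return data.frame `term`, `x`, `y` with attributes `x_axis`, `y_axis`,
#'   `dim`, in lexicon order.
#' @export
project_plane <- function(set, terms, x_axis, y_axis) {
  stopifnot(inherits(terms, "lexicon"))
  coords <- lapply(names(terms$entries), function(canon) {
    tryCatch({
      data.frame(term = canon,
                 x = axis_coordinate(set, terms$entries[[canon]], x_axis),
                 y = axis_coordinate(set, terms$entries[[canon]], y_axis),
                 stringsAsFactors = FALSE)
    }, embaudit_oov = function(e) {
      ea_log(sprintf("skipped out-of-vocabulary term '%s'", canon),
             level = "warn")
      NULL
    })
  })
  coords <- coords[!vapply(coords, is.null, TRUE)]
  if (length(coords) == 0L) {
    ea_stop("empty_result", "no term of '%s' resolvable in vocabulary",
            terms$name)
  }
  out <- do.call(rbind, c(coords, make.row.names = FALSE))
  attr(out, "x_axis") <- x_axis$name
  attr(out, "y_axis") <- y_axis$name
  attr(out, "embedding_dim") <- set$dim
  out
}

#' Rank terms along a single pole axis (gradient)
#'
#' Orders terms by their [axis_coordinate()], ascending, so the term closest
#' to `pole_low` (e.g. "suicide" on a suicide/healthy axis) comes first.
#' Ties are broken lexicographically. Swapping the poles reverses the order
#' exactly.
#'
#' @param set a unit-normalized [embedding_set()].
#' @param terms a [lexicon()] with at least two resolvable terms.
#' @param axis an [axis_spec()].
#' @return data.frame `term`, `coordinate`, ascending, with attributes
#'   `axis` and `dim`.
#' @export
gradient_rank <- function(set, terms, axis) {
  pl <- project_plane(set, terms, axis, axis)
  if (nrow(pl) < 2L) {
    ea_stop("empty_result", "gradient needs at least 2 resolvable terms")
  }
  ord <- order(pl$x, pl$term, method = "radix")
  out <- data.frame(term = pl$term[ord], coordinate = pl$x[ord],
                    stringsAsFactors = FALSE)
  attr(out, "axis") <- axis$name
  attr(out, "embedding_dim") <- attr(pl, "embedding_dim")
  out
}

#' Write a coordinate table (placement or gradient) as TSV
#'
#' @param coords output of [project_plane()] or [gradient_rank()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(coords, path) {
  df <- coords
  for (a in c("x_axis", "y_axis", "axis", "embedding_dim")) {
    if (!is.null(attr(coords, a))) df[[a]] <- attr(coords, a)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scatter plot of a plane placement
#'
#' Presentation only — the coordinate table is the canonical artifact.
#' Requires ggplot2.
#'
#' @param placements output of [project_plane()].
#' @return a ggplot object.
#' @export
plot_placements <- function(placements) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    ea_stop("io", "ggplot2 is required for plotting")
  }
  ggplot2::ggplot(placements, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$term), vjust = -0.6,
                       size = 3) +
    ggplot2::labs(x = attr(placements, "x_axis"),
                  y = attr(placements, "y_axis")) +
    ggplot2::theme_minimal()
}
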