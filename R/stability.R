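#' Kendall rank correlation by explicit pair counting
#'
#' Tau-a: (concordant - discordant) / total pairs, counted exhaustively
#' over all unordered pairs with no tie or continuity correction — exact on
#' the short lists these audits compare. Tied pairs (in either vector)
#' count as neither concordant nor discordant.
#'
#' @param x,y numeric vectors of equal length >= 2, paired by position.
#' @return a single number in [-1, 1].
#' @examples
#' kendall_pair_tau(1:4, c(2, 1, 3, 4))  # one adjacent swap: 4/6
#' @export
kendall_pair_tau <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2L)
  conc <- 0L; disc <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1L else if (s < 0) disc <- disc + 1L
    }
  }
  (conc - disc) / (n * (n - 1L) / 2)
}

#' Compare gradient/placement results across embedding dimensionalities
#'
#' Checks whether the ordering and sidedness a low-dimensional model shows
#' survive in higher-dimensional versions of the same embedding. The first
#' result set is the reference; every other set is compared against it on
#' three metrics per axis: Kendall tau-a rank correlation of the
#' coordinates ([kendall_pair_tau()]), agreement of the extreme (top-1,
#' closest to `pole_low`) term, and the fraction of terms whose coordinate
#' sign (side of the axis midpoint) agrees.
#'
#' @param results named list (names = dimensionality labels, e.g. "50",
#'   "200") of outputs of [gradient_rank()] (columns `term`, `coordinate`)
#'   or of [project_plane()] (columns `term`, `x`, `y`). All sets must
#'   cover an identical term set.
#' @return a `stability_report`: data.frame with one row per non-reference
#'   set and axis, columns `dims`, `axis`, `rank_correlation`,
#'   `top1_agreement`, `side_agreement`, plus attribute `reference`.
#' @export
stability_compare <- function(results) {
  stopifnot(is.list(results), length(results) >= 2L)
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    names(results) <- paste0("set", seq_along(results))
  }
  terms0 <- sort(results[[1L]]$term)
  for (r in results[-1L]) {
    if (!identical(sort(r$term), terms0)) {
      ea_stop("incomparable", "result sets cover different term lists")
    }
  }
  axes_of <- function(df) {
    if ("coordinate" %in% names(df)) "coordinate" else intersect(c("x", "y"), names(df))
  }
  ax <- axes_of(results[[1L]])
  rows <- list()
  ref <- results[[1L]]
  for (nm in names(results)[-1L]) {
    cur <- results[[nm]]
    if (!identical(axes_of(cur), ax)) {
      ea_stop("incomparable", "result sets have different axis columns")
    }
    m <- match(ref$term, cur$term)
    for (a in ax) {
      x <- ref[[a]]; y <- cur[[a]][m]
      # top-1 = most negative coordinate = term nearest pole_low
      top1 <- identical(ref$term[which.min(x)], ref$term[which.min(y)])
      rows[[length(rows) + 1L]] <- data.frame(
        dims = nm,
        axis = if (a == "coordinate") attr(ref, "axis") %||% "axis" else a,
        rank_correlation = kendall_pair_tau(x, y),
        top1_agreement = as.numeric(top1),
        side_agreement = mean(sign(x) == sign(y)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "reference") <- names(results)[1L]
  class(out) <- c("stability_report", "data.frame")
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> reference: %s\n", attr(x, "reference")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a stability report as JSON
#'
#' @param report a `stability_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stability <- function(report, path) {
  jsonlite::write_json(list(reference = attr(report, "reference"),
                            comparisons = as.data.frame(report)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
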