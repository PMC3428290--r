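# 2D probability / pseudo-free-energy surfaces over two descriptor series
# (conventionally RMSD x Rg). The "energy" is the Boltzmann inversion of
# the normalized histogram, G = -ln(P / P_max), in kT units: temperature is
# factored out and only relative depths are meaningful. Empty bins carry a
# +Inf sentinel.

#' 2D pseudo-free-energy landscape from two descriptor series
#'
#' Bins the paired samples on an equal-width grid spanning each axis's data
#' range (the default 8 bins per axis gives the conventional 64-cell grid),
#' normalizes counts to probabilities and converts to
#' `G = -ln(P / P_max)`.
#'
#' @param x,y `descriptor_series` (or anything with a `value` column /
#'   numeric vector) of equal length.
#' @param bins_per_axis number of bins per axis, >= 2 (default 8).
#' @return list of class `landscape2d`: `x_edges`, `y_edges` (length
#'   `bins + 1`), `P` (probability matrix, rows = x bins), `G` (kT), and
#'   `basin` (see [basin_summary()]).
#' @export
energy_landscape <- function(x, y, bins_per_axis = 8) {
  xv <- if (is.data.frame(x)) x$value else as.numeric(x)
  yv <- if (is.data.frame(y)) y$value else as.numeric(y)
  if (length(xv) != length(yv)) stop("x and y series differ in length")
  if (bins_per_axis < 2) stop("bins_per_axis must be >= 2")
  if (length(xv) < bins_per_axis) {
    stop("need at least as many samples as bins per axis")
  }
  if (diff(range(xv)) == 0 || diff(range(yv)) == 0) {
    stop("degenerate axis: zero variance along one coordinate")
  }
  x_edges <- seq(min(xv), max(xv), length.out = bins_per_axis + 1)
  y_edges <- seq(min(yv), max(yv), length.out = bins_per_axis + 1)
  ix <- findInterval(xv, x_edges, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(yv, y_edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0, bins_per_axis, bins_per_axis)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  P <- counts / length(xv)
  G <- -log(P / max(P)) # empty bins: -log(0) = +Inf sentinel
  ls <- structure(
    list(x_edges = x_edges, y_edges = y_edges, P = P, G = G, basin = NULL),
    class = "landscape2d"
  )
  ls$basin <- basin_summary(ls)
  ls
}

#' Location of the free-energy basin
#'
#' Returns the bin(s) of minimum G (equivalently maximum probability) with
#' their edge intervals; ties are all reported.
#'
#' @param ls a `landscape2d`.
#' @return data.frame with one row per (tied) basin cell: `x_lo`, `x_hi`,
#'   `y_lo`, `y_hi`, `P`.
#' @export
basin_summary <- function(ls) {
  hits <- which(ls$P == max(ls$P), arr.ind = TRUE)
  data.frame(
    x_lo = ls$x_edges[hits[, 1]], x_hi = ls$x_edges[hits[, 1] + 1],
    y_lo = ls$y_edges[hits[, 2]], y_hi = ls$y_edges[hits[, 2] + 1],
    P = ls$P[hits]
  )
}

#' @export
print.landscape2d <- function(x, ...) {
  cat(
    "<landscape2d> ", nrow(x$P), "x", ncol(x$P), " bins; basin P = ",
    format(max(x$P), digits = 4), " at x in [",
    format(x$basin$x_lo[1], digits = 4), ", ",
    format(x$basin$x_hi[1], digits = 4), "], y in [",
    format(x$basin$y_lo[1], digits = 4), ", ",
    format(x$basin$y_hi[1], digits = 4), "]\n",
    sep = ""
  )
  invisible(x)
}

#' Export a landscape as a long table
#'
#' @param ls a `landscape2d`.
#' @return data.frame with `x_lo`, `x_hi`, `y_lo`, `y_hi`, `P`, `G` (one
#'   row per cell; `G` is `Inf` for empty cells).
#' @export
landscape_table <- function(ls) {
  nb <- nrow(ls$P)
  grid <- expand.grid(i = seq_len(nb), j = seq_len(nb))
  data.frame(
    x_lo = ls$x_edges[grid$i], x_hi = ls$x_edges[grid$i + 1],
    y_lo = ls$y_edges[grid$j], y_hi = ls$y_edges[grid$j + 1],
    P = ls$P[cbind(grid$i, grid$j)],
    G = ls$G[cbind(grid$i, grid$j)]
  )
}
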