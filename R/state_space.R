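#' Build a state-space grid from activation points
#'
#' Tallies (positive activation, negative activation) session points into the
#' occupancy counts of a state-space grid. With the default 0-4 activation
#' axes the grid has 5 x 5 = 25 cells; each coded session contributes one
#' unit of duration to its cell.
#'
#' @param x,y Integer vectors of equal length: positive (x) and negative (y)
#'   activation per session, each in 0..(n_cols-1) / 0..(n_rows-1).
#' @param n_rows,n_cols Grid extent, default 5 x 5.
#' @return Object of class `"ss_grid"`: list with `counts` (n_rows x n_cols
#'   matrix, rows indexed by y, columns by x, both zero-based), `D` (total
#'   observations), `n_cells`, and `points` (the input order, retained for
#'   trajectory export). A grid with `D = 0` is flagged `degenerate`.
#' @export
#' @examples
#' g <- build_grid(c(2, 2, 0), c(3, 3, 0))
#' g$D # 3
build_grid <- function(x, y, n_rows = 5, n_cols = 5) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("activation points contain missing values", call. = FALSE)
  }
  bad <- which(!(x %in% 0:(n_cols - 1)) | !(y %in% 0:(n_rows - 1)))
  if (length(bad)) {
    stop(sprintf(
      "activation point outside the %dx%d grid at position %d: (%s, %s)",
      n_rows, n_cols, bad[1], x[bad[1]], y[bad[1]]
    ), call. = FALSE)
  }
  counts <- matrix(0L, nrow = n_rows, ncol = n_cols,
    dimnames = list(y = 0:(n_rows - 1), x = 0:(n_cols - 1)))
  for (i in seq_along(x)) {
    counts[y[i] + 1L, x[i] + 1L] <- counts[y[i] + 1L, x[i] + 1L] + 1L
  }
  structure(
    list(
      counts = counts,
      D = length(x),
      n_cells = n_rows * n_cols,
      points = data.frame(x = as.integer(x), y = as.integer(y)),
      degenerate = length(x) < 2L
    ),
    class = "ss_grid"
  )
}

#' @export
print.ss_grid <- function(x, ...) {
  cat(sprintf("State-space grid: %d cells, D = %d session(s)%s\n",
    x$n_cells, x$D, if (x$degenerate) " [degenerate]" else ""))
  print(x$counts)
  invisible(x)
}

#' Grid dispersion
#'
#' Dispersion quantifies how widely a patient's session points spread across
#' the cells of the state-space grid in a treatment phase:
#' \deqn{1 - \frac{n \sum_i (d_i/D)^2 - 1}{n - 1}}
#' where \eqn{d_i} is the number of sessions in cell \eqn{i}, \eqn{D} the
#' total number of sessions in the phase, and \eqn{n} the total number of
#' grid cells (occupied or not; 25 for the 5x5 activation grid). The value
#' is 0 when all sessions share one cell and grows as occupancy spreads;
#' \eqn{D} sessions in \eqn{D} distinct cells give \eqn{1 - (n/D - 1)/(n-1)}
#' (e.g. 0.868 for six spread sessions on the 25-cell grid), and the
#' maximum 1 is attained exactly when occupancy is uniform over the whole
#' grid (\eqn{D = n}).
#'
#' A single-session grid (`D = 1`) returns 0, consistent with the formula,
#' but carries the grid's degenerate flag.
#'
#' @param grid An `"ss_grid"` from [build_grid()].
#' @return Numeric dispersion in [0, 1], with attributes `D` and `n_cells`.
#' @export
#' @examples
#' dispersion(build_grid(rep(2, 8), rep(3, 8))) # 0
dispersion <- function(grid) {
  stopifnot(inherits(grid, "ss_grid"))
  if (grid$D < 1L) {
    stop("dispersion is undefined for an empty grid (D = 0)", call. = FALSE)
  }
  n <- grid$n_cells
  if (n < 2L) {
    stop("dispersion requires at least 2 grid cells", call. = FALSE)
  }
  p <- as.numeric(grid$counts) / grid$D
  value <- 1 - (n * sum(p^2) - 1) / (n - 1)
  # guard against representation error only; the formula stays in [0, 1]
  value <- min(max(value, 0), 1)
  structure(value, D = grid$D, n_cells = n)
}

#' Summarize grid occupancy
#'
#' @param grid An `"ss_grid"`.
#' @return List with `cells_visited` (count of distinct occupied cells),
#'   `modal_cell` (`c(x, y)` of the most occupied cell; ties broken by lowest
#'   x then lowest y), and `proportions` (occupancy proportion matrix summing
#'   to 1). An empty grid returns an empty summary.
#' @export
grid_summary <- function(grid) {
  stopifnot(inherits(grid, "ss_grid"))
  if (grid$D == 0L) {
    return(list(cells_visited = 0L, modal_cell = NULL, proportions = NULL))
  }
  counts <- grid$counts
  occ <- which(counts > 0, arr.ind = TRUE)
  # arr.ind columns: (row, col) = (y + 1, x + 1); tie-break lowest x then y
  xs <- occ[, 2L] - 1L
  ys <- occ[, 1L] - 1L
  cnt <- counts[occ]
  ord <- order(-cnt, xs, ys)
  list(
    cells_visited = nrow(occ),
    modal_cell = c(x = xs[ord[1]], y = ys[ord[1]]),
    proportions = counts / grid$D
  )
}
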