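#' Rectangular game board
#'
#' Defines the grid the game is played on. Cells are addressed by 0-based
#' `(row, col)` pairs; movement is 4-connected (north/east/south/west) with no
#' wraparound. The default 3x3 board is the smallest grid on which all the
#' message shapes handled by the package (simple pass, marked detour, zigzag)
#' can be expressed.
#'
#' @param n_rows,n_cols Number of rows and columns; each must be at least 2.
#' @return An object of class `tcg_board`.
#' @examples
#' tcg_board(3, 3)
#' @export
tcg_board <- function(n_rows = 3L, n_cols = 3L) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 2L || n_cols < 2L) {
    stop("board must have at least 2 rows and 2 columns", call. = FALSE)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols), class = "tcg_board")
}

#' @export
print.tcg_board <- function(x, ...) {
  cat(sprintf("<tcg_board %d x %d>\n", x$n_rows, x$n_cols))
  invisible(x)
}

n_cells <- function(board) board$n_rows * board$n_cols

#' Construct a grid cell
#'
#' @param row,col 0-based row and column indices.
#' @param board Optional [tcg_board()]; when supplied the cell is checked to
#'   lie on the board.
#' @return A length-2 integer vector `c(row, col)`.
#' @export
cell <- function(row, col, board = NULL) {
  out <- c(row = as.integer(row), col = as.integer(col))
  if (any(is.na(out)) || any(out < 0L)) {
    stop("cell indices must be non-negative integers", call. = FALSE)
  }
  if (!is.null(board)) assert_on_board(out, board)
  out
}

assert_on_board <- function(c1, board) {
  if (length(c1) != 2L || any(is.na(c1)) ||
      c1[1L] < 0L || c1[1L] >= board$n_rows ||
      c1[2L] < 0L || c1[2L] >= board$n_cols) {
    stop(sprintf("cell (%s) is not on a %d x %d board",
                 paste(c1, collapse = ","), board$n_rows, board$n_cols),
         call. = FALSE)
  }
  invisible(c1)
}

# 1-based linear id for a 0-based (row, col) cell; the inverse decodes ids
# back to cells. Used internally so walks are plain integer vectors.
cell_id <- function(c1, board) as.integer(c1[1L]) * board$n_cols + as.integer(c1[2L]) + 1L
id_to_cell <- function(id, board) {
  id0 <- as.integer(id) - 1L
  cbind(row = id0 %/% board$n_cols, col = id0 %% board$n_cols)
}

#' Manhattan (city-block) distance between two cells
#'
#' @param c1,c2 Cells as `c(row, col)` vectors.
#' @return Non-negative integer distance.
#' @examples
#' manhattan(cell(0, 1), cell(2, 2)) # 3
#' @export
manhattan <- function(c1, c2) {
  stopifnot(length(c1) == 2L, length(c2) == 2L)
  as.integer(abs(c1[1L] - c2[1L]) + abs(c1[2L] - c2[2L]))
}

# Absolute moves in the canonical deterministic order used throughout:
# north < east < south < west (row-1, col+1, row+1, col-1).
MOVE_NAMES <- c("north", "east", "south", "west")
MOVE_DELTA <- matrix(c(-1L, 0L, 0L, 1L, 1L, 0L, 0L, -1L),
                     nrow = 4L, byrow = TRUE,
                     dimnames = list(MOVE_NAMES, c("row", "col")))

cell_shift <- function(c1, dir) {
  d <- MOVE_DELTA[dir, ]
  c(row = c1[[1L]] + d[[1L]], col = c1[[2L]] + d[[2L]])
}

on_board <- function(c1, board) {
  c1[[1L]] >= 0L && c1[[1L]] < board$n_rows && c1[[2L]] >= 0L && c1[[2L]] < board$n_cols
}

#' Orthogonal neighbours of a cell
#'
#' @param c1 A cell on the board.
#' @param board A [tcg_board()].
#' @return An integer matrix with one `(row, col)` neighbour per line, in
#'   north, east, south, west order; corners have 2 rows, edges 3, interior
#'   cells 4. Never includes `c1` itself.
#' @export
neighbors <- function(c1, board) {
  assert_on_board(c1, board)
  out <- lapply(MOVE_NAMES, function(d) {
    nb <- cell_shift(c1, d)
    if (on_board(nb, board)) nb else NULL
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1L))])
}

# Precomputed per-id neighbour table: 4 x n_cells, slot [d, id] holds the id
# reached by move d from id, or 0 when that move leaves the board.
neighbor_table <- function(board) {
  nr <- board$n_rows
  nc <- board$n_cols
  ids <- seq_len(nr * nc)
  row <- (ids - 1L) %/% nc
  col <- (ids - 1L) %% nc
  tab <- matrix(0L, nrow = 4L, ncol = nr * nc, dimnames = list(MOVE_NAMES, NULL))
  tab[1L, ] <- ifelse(row > 0L, ids - nc, 0L)
  tab[2L, ] <- ifelse(col < nc - 1L, ids + 1L, 0L)
  tab[3L, ] <- ifelse(row < nr - 1L, ids + nc, 0L)
  tab[4L, ] <- ifelse(col > 0L, ids - 1L, 0L)
  tab
}

# Vector of manhattan distances from every cell id to `target`.
dist_to <- function(target, board) {
  ids <- seq_len(n_cells(board))
  xy <- id_to_cell(ids, board)
  abs(xy[, "row"] - target[[1L]]) + abs(xy[, "col"] - target[[2L]])
}
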