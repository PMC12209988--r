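#' Goal configuration for one trial
#'
#' A trial is defined by three pairwise-distinct cells: the Sender's start
#' `A`, the Sender's goal `Gs`, and the Receiver's (hidden) goal `Gr`. The
#' trial type is derived: *direct* when `Gr` lies on some shortest `A -> Gs`
#' path (the Sender can pass it at no extra cost), *indirect* otherwise.
#'
#' @param A,Gs,Gr Cells as `c(row, col)` vectors (see [cell()]).
#' @param board A [tcg_board()].
#' @return An object of class `tcg_config` with fields `A`, `Gs`, `Gr`,
#'   `board` and `trial_type`.
#' @examples
#' cfg <- goal_config(cell(0, 0), cell(2, 0), cell(1, 1))
#' trial_type(cfg) # "indirect": the detour via (1,1) costs two extra steps
#' @export
goal_config <- function(A, Gs, Gr, board = tcg_board()) {
  A <- cell(A[[1L]], A[[2L]], board)
  Gs <- cell(Gs[[1L]], Gs[[2L]], board)
  Gr <- cell(Gr[[1L]], Gr[[2L]], board)
  pts <- rbind(A, Gs, Gr)
  if (anyDuplicated(pts)) {
    stop("A, Gs and Gr must be pairwise distinct cells", call. = FALSE)
  }
  structure(
    list(A = A, Gs = Gs, Gr = Gr, board = board,
         trial_type = compute_trial_type(A, Gs, Gr)),
    class = "tcg_config"
  )
}

compute_trial_type <- function(A, Gs, Gr) {
  if (manhattan(A, Gr) + manhattan(Gr, Gs) == manhattan(A, Gs)) "direct" else "indirect"
}

#' Trial type of a goal configuration
#'
#' @param cfg A [goal_config()].
#' @return `"direct"` or `"indirect"`.
#' @export
trial_type <- function(cfg) {
  stopifnot(inherits(cfg, "tcg_config"))
  cfg$trial_type
}

#' @export
print.tcg_config <- function(x, ...) {
  cat(sprintf("<tcg_config %s | A=(%d,%d) Gs=(%d,%d) Gr=(%d,%d) on %d x %d>\n",
              x$trial_type, x$A[1L], x$A[2L], x$Gs[1L], x$Gs[2L],
              x$Gr[1L], x$Gr[2L], x$board$n_rows, x$board$n_cols))
  invisible(x)
}

#' @export
format.tcg_config <- function(x, ...) {
  sprintf("A=(%d,%d) Gs=(%d,%d) Gr=(%d,%d) [%s]",
          x$A[1L], x$A[2L], x$Gs[1L], x$Gs[2L], x$Gr[1L], x$Gr[2L], x$trial_type)
}

# All ordered triples of pairwise-distinct cells on the board, as a data.frame
# of ids plus the derived trial type. Shared by the generator and the
# exhaustive sweeps used in tests.
all_config_triples <- function(board) {
  ids <- seq_len(n_cells(board))
  xy <- id_to_cell(ids, board)
  grid <- expand.grid(A = ids, Gs = ids, Gr = ids, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$A != grid$Gs & grid$A != grid$Gr & grid$Gs != grid$Gr, , drop = FALSE]
  d <- function(i, j) abs(xy[i, "row"] - xy[j, "row"]) + abs(xy[i, "col"] - xy[j, "col"])
  direct <- d(grid$A, grid$Gr) + d(grid$Gr, grid$Gs) == d(grid$A, grid$Gs)
  grid$trial_type <- ifelse(direct, "direct", "indirect")
  rownames(grid) <- NULL
  grid
}

triple_to_config <- function(row, board) {
  goal_config(id_to_cell(row$A, board)[1L, ],
              id_to_cell(row$Gs, board)[1L, ],
              id_to_cell(row$Gr, board)[1L, ],
              board)
}

#' Sample a reproducible set of goal configurations
#'
#' Draws `n_direct` direct and `n_indirect` indirect configurations uniformly
#' without replacement from all ordered distinct-cell triples on the board.
#' The study design this emulates uses 20 direct and 10 indirect trials per
#' session.
#'
#' @param board A [tcg_board()].
#' @param n_direct,n_indirect Number of configurations of each type.
#' @param seed Integer seed; the same seed always returns the same list.
#' @return A list of [goal_config()] objects (direct ones first).
#' @examples
#' cfgs <- generate_configurations(tcg_board(3, 3), 2, 1, seed = 1)
#' vapply(cfgs, trial_type, character(1))
#' @export
generate_configurations <- function(board, n_direct, n_indirect, seed) {
  stopifnot(n_direct >= 0, n_indirect >= 0)
  triples <- all_config_triples(board)
  pool_d <- which(triples$trial_type == "direct")
  pool_i <- which(triples$trial_type == "indirect")
  if (length(pool_d) < n_direct || length(pool_i) < n_indirect) {
    stop(sprintf(
      "board too small: %d direct / %d indirect triples available, %d / %d requested",
      length(pool_d), length(pool_i), n_direct, n_indirect), call. = FALSE)
  }
  picks <- with_seed(seed, c(
    if (n_direct > 0) sample(pool_d, n_direct) else integer(0),
    if (n_indirect > 0) sample(pool_i, n_indirect) else integer(0)
  ))
  lapply(picks, function(i) triple_to_config(triples[i, , drop = FALSE], board))
}

#' Read and write goal-configuration files
#'
#' Configurations are serialised as JSON:
#' `{"board": {"rows": 3, "cols": 3}, "trials": [{"A": [r,c], "Gs": [r,c], "Gr": [r,c]}, ...]}`.
#' The reader validates every triple against the board and recomputes the
#' trial type rather than trusting the file.
#'
#' @param configs A list of [goal_config()] objects sharing one board.
#' @param path File path.
#' @return `read_configurations()` returns a list of [goal_config()];
#'   `write_configurations()` returns `path` invisibly.
#' @export
write_configurations <- function(configs, path) {
  stopifnot(length(configs) > 0L, all(vapply(configs, inherits, logical(1L), "tcg_config")))
  board <- configs[[1L]]$board
  payload <- list(
    board = list(rows = board$n_rows, cols = board$n_cols),
    trials = lapply(configs, function(cfg) {
      list(A = unname(cfg$A), Gs = unname(cfg$Gs), Gr = unname(cfg$Gr))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_configurations
#' @export
read_configurations <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file not found: %s", path), call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$board) || is.null(payload$trials)) {
    stop(sprintf("%s is not a configuration file (missing board/trials)", path), call. = FALSE)
  }
  board <- tcg_board(payload$board$rows, payload$board$cols)
  trials <- payload$trials
  if (is.data.frame(trials)) {
    lapply(seq_len(nrow(trials)), function(i) {
      goal_config(trials$A[[i]], trials$Gs[[i]], trials$Gr[[i]], board)
    })
  } else {
    lapply(trials, function(tr) goal_config(tr$A, tr$Gs, tr$Gr, board))
  }
}
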