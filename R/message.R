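#' Messages: ordered cell sequences
#'
#' A message is the Sender's full trajectory, an ordered sequence of at least
#' two cells in which consecutive cells are orthogonal neighbours. Its length
#' `L(m)` counts *states* (cells in the sequence, revisits included); the game
#' score is charged per *step*, i.e. `L(m) - 1` transitions. The set of
#' unique states `U(m)` can be smaller than `L(m)` when the path revisits a
#' cell.
#'
#' @param states An integer matrix with columns `row`, `col` (one state per
#'   line, 0-based), or a list of `c(row, col)` cells.
#' @param board A [tcg_board()].
#' @return An object of class `tcg_message`.
#' @examples
#' m <- tcg_message(rbind(c(0, 0), c(1, 0), c(1, 1), c(1, 0), c(2, 0)))
#' message_length(m)   # 5 states
#' n_unique_states(m)  # 4: (1,0) is visited twice
#' @export
tcg_message <- function(states, board = tcg_board()) {
  if (is.list(states)) states <- do.call(rbind, states)
  states <- matrix(as.integer(states), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(states) < 2L) stop("a message needs at least 2 states", call. = FALSE)
  apply(states, 1L, assert_on_board, board = board)
  steps <- abs(diff(states[, "row"])) + abs(diff(states[, "col"]))
  if (any(steps != 1L)) {
    stop("consecutive message states must be orthogonal neighbours", call. = FALSE)
  }
  structure(states, class = "tcg_message", board = board)
}

#' @export
print.tcg_message <- function(x, ...) {
  cells <- apply(unclass(x), 1L, function(s) sprintf("(%d,%d)", s[1L], s[2L]))
  cat(sprintf("<tcg_message L=%d |U|=%d> %s\n",
              message_length(x), n_unique_states(x), paste(cells, collapse = " -> ")))
  invisible(x)
}

#' @rdname tcg_message
#' @param m A `tcg_message`.
#' @export
message_length <- function(m) nrow(m)

#' @rdname tcg_message
#' @export
unique_states <- function(m) unique(matrix(as.integer(m), ncol = 2L,
                                           dimnames = list(NULL, c("row", "col"))))

#' @rdname tcg_message
#' @export
n_unique_states <- function(m) nrow(unique_states(m))

# id-vector view of a message (internal fast path).
message_ids <- function(m, board = attr(m, "board")) {
  as.integer(m[, 1L]) * board$n_cols + as.integer(m[, 2L]) + 1L
}

ids_to_message <- function(ids, board) {
  tcg_message(id_to_cell(ids, board), board)
}

#' Validate a message against a goal configuration
#'
#' A message is valid for a configuration when it starts at `A`, ends at
#' `Gs`, passes through `Gr` at least once, and every consecutive pair of
#' states is orthogonally adjacent.
#'
#' @param m A [tcg_message()] (or a raw state matrix; adjacency is then also
#'   checked).
#' @param cfg A [goal_config()].
#' @param strict If `TRUE`, raise an error naming the violated clause instead
#'   of returning `FALSE`.
#' @return `TRUE` or `FALSE`.
#' @export
validate_message <- function(m, cfg, strict = FALSE) {
  fail <- function(msg) {
    if (strict) stop(msg, call. = FALSE)
    FALSE
  }
  if (!inherits(m, "tcg_message")) {
    m <- tryCatch(tcg_message(m, cfg$board), error = function(e) NULL)
    if (is.null(m)) return(fail("states do not form an adjacent on-board path"))
  }
  s <- unclass(m)
  n <- nrow(s)
  if (!all(s[1L, ] == cfg$A)) return(fail("message must start at A"))
  if (!all(s[n, ] == cfg$Gs)) return(fail("message must end at Gs"))
  if (!any(s[, 1L] == cfg$Gr[1L] & s[, 2L] == cfg$Gr[2L])) {
    return(fail("message must pass through Gr"))
  }
  TRUE
}

#' Score of a message
#'
#' Each trial starts from a point endowment which is reduced by one point per
#' movement step the Sender takes, so a message with `L` states (i.e. `L - 1`
#' steps) scores `endowment - (L - 1)`.
#'
#' @param m A [tcg_message()].
#' @param endowment Starting points, 10 by default.
#' @return Integer score (may be negative if the path overruns the endowment).
#' @export
message_score <- function(m, endowment = 10L) {
  as.integer(endowment) - (message_length(m) - 1L)
}

#' Classify a message as Pass-by, Enter-exit or Wiggly
#'
#' The three message shapes are operationalised on revisit structure, with
#' precedence wiggly > enter-exit > pass-by:
#' * **wiggly** - the Receiver's goal `Gr` occurs at least twice in the
#'   sequence (the path shuttles in and out of the goal);
#' * **enter_exit** - some other state occurs at least twice (the path makes
#'   a side trip and backtracks);
#' * **pass_by** - the path is simple (no repeats), sweeping through `Gr` on
#'   the way.
#'
#' The `"other"` label is reserved for classifier variants and is unreachable
#' under this rule set.
#'
#' @param m A [tcg_message()], valid for `cfg`.
#' @param cfg A [goal_config()].
#' @return One of `"pass_by"`, `"enter_exit"`, `"wiggly"`.
#' @examples
#' cfg <- goal_config(cell(0, 0), cell(2, 0), cell(1, 1))
#' m <- tcg_message(rbind(c(0, 0), c(1, 0), c(1, 1), c(1, 0), c(2, 0)))
#' classify_message(m, cfg) # enter_exit: (1,0) is revisited, Gr only once
#' @export
classify_message <- function(m, cfg) {
  if (!validate_message(m, cfg)) {
    stop("cannot classify a message that is invalid for the configuration", call. = FALSE)
  }
  s <- unclass(m)
  gr_hits <- sum(s[, 1L] == cfg$Gr[1L] & s[, 2L] == cfg$Gr[2L])
  if (gr_hits >= 2L) return("wiggly")
  if (anyDuplicated(s) > 0L) return("enter_exit")
  "pass_by"
}

MESSAGE_CLASSES <- c("pass_by", "enter_exit", "wiggly", "other")

# JSON round-trip for embedding messages in CSV columns.
message_to_json <- function(m) {
  jsonlite::toJSON(unname(lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))))
}

message_from_json <- function(txt, board = tcg_board()) {
  states <- jsonlite::fromJSON(txt, simplifyMatrix = TRUE)
  tcg_message(states, board)
}
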