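# Bounded exhaustive enumeration of grid walks.
#
# The full message set of a configuration is infinite (walks may revisit
# cells indefinitely), so every consumer works with the truncation to
# L(m) <= max_states. Enumeration is a frontier expansion by depth with the
# moves of every partial walk tried in the canonical north < east < south <
# west order; completed walks are finally sorted lexicographically on their
# move sequences, which makes the ordering - and hence uniform sampling
# downstream - reproducible.

# Fast constructor for internally generated (already checked) paths.
new_tcg_message <- function(states, board) {
  structure(matrix(as.integer(states), ncol = 2L,
                   dimnames = list(NULL, c("row", "col"))),
            class = "tcg_message", board = board)
}

# Enumerate walks on `board` from `from`, optionally constrained to end at
# `to`, pass through `via`, and avoid `forbid` (all cells). Walks have at
# most `max_states` states. Returns a list with per-walk fields:
#   ids   - list of integer id vectors (the walks),
#   L     - integer state counts,
#   nuniq - integer unique-state counts,
#   moves - move strings over "1234" (N,E,S,W), lexicographically sorted.
# When `to` is given the search is pruned with an admissible remaining
# manhattan bound, so deep caps stay cheap on small boards.
enumerate_walks <- function(board, from, to = NULL, via = NULL, forbid = NULL,
                            max_states, node_budget = 2e6) {
  cap <- as.integer(max_states)
  nc <- n_cells(board)
  nbr <- neighbor_table(board)
  from_id <- cell_id(from, board)
  to_id <- if (!is.null(to)) cell_id(to, board) else NA_integer_
  via_id <- if (!is.null(via)) cell_id(via, board) else NA_integer_
  forbid_id <- if (!is.null(forbid)) cell_id(forbid, board) else NA_integer_

  use_mask <- nc <= 30L
  bit <- if (use_mask) as.integer(2^(seq_len(nc) - 1L)) else NULL
  dto <- if (!is.na(to_id)) dist_to(to, board) else NULL
  dvia <- if (!is.na(via_id)) dist_to(via, board) else NULL
  dvia_to <- if (!is.na(via_id) && !is.na(to_id)) manhattan(via, to) else 0L

  res_states <- list()
  res_moves <- list()
  res_mask <- list()
  res_len <- integer(0)

  cur <- from_id
  viaok <- is.na(via_id) | from_id == via_id
  mask <- if (use_mask) bit[from_id] else NULL
  moves <- ""
  states <- matrix(from_id, ncol = 1L)
  len <- 1L
  nodes <- 0L

  collect <- function(sel) {
    if (!any(sel)) return()
    k <- length(res_states) + 1L
    res_states[[k]] <<- states[sel, , drop = FALSE]
    res_moves[[k]] <<- moves[sel]
    res_mask[[k]] <<- if (use_mask) mask[sel] else NULL
    res_len <<- c(res_len, rep.int(len, sum(sel)))
  }

  if (cap >= 1L) {
    collect(if (is.na(to_id)) rep(TRUE, length(cur)) else (cur == to_id) & viaok)
  }

  while (len < cap && length(cur) > 0L) {
    n <- length(cur)
    idx <- rep(seq_len(n), each = 4L)
    mv <- rep.int(1:4, n)
    nxt <- nbr[cbind(mv, cur[idx])]
    keep <- nxt != 0L
    if (!is.na(forbid_id)) keep <- keep & nxt != forbid_id
    len1 <- len + 1L
    viaok1 <- viaok[idx] | (!is.na(via_id) & nxt == via_id)
    if (!is.na(to_id)) {
      bound <- ifelse(viaok1, dto[pmax(nxt, 1L)],
                      dvia[pmax(nxt, 1L)] + dvia_to)
      keep <- keep & (len1 + bound <= cap)
    }
    idx <- idx[keep]
    if (length(idx) == 0L) break
    nodes <- nodes + length(idx)
    if (nodes > node_budget) {
      stop(sprintf("walk enumeration exceeded the node budget (%g); lower max_states",
                   node_budget), call. = FALSE)
    }
    mv <- mv[keep]
    cur <- nxt[keep]
    viaok <- viaok1[keep]
    states <- cbind(states[idx, , drop = FALSE], cur)
    moves <- paste0(moves[idx], mv)
    if (use_mask) mask <- bitwOr(mask[idx], bit[cur])
    len <- len1
    collect(if (is.na(to_id)) rep(TRUE, length(cur)) else (cur == to_id) & viaok)
  }

  all_moves <- unlist(res_moves, use.names = FALSE) %||% character(0)
  ord <- order(all_moves, method = "radix")
  ids <- vector("list", length(all_moves))
  pos <- 0L
  for (k in seq_along(res_states)) {
    blk <- res_states[[k]]
    for (i in seq_len(nrow(blk))) {
      ids[[pos + i]] <- unname(blk[i, ])
    }
    pos <- pos + nrow(blk)
  }
  nuniq <- if (use_mask) {
    bit_count(unlist(res_mask, use.names = FALSE) %||% integer(0))
  } else {
    vapply(ids, function(w) length(unique(w)), integer(1L))
  }
  list(ids = ids[ord],
       L = res_len[ord],
       nuniq = nuniq[ord],
       moves = all_moves[ord])
}

#' Minimum message length through a state
#'
#' The shortest valid message that visits state `s` goes `A -> s -> Gs` along
#' shortest legs, so its length (in states) is
#' `manhattan(A, s) + manhattan(s, Gs) + 1`. This closed form drives the
#' Receivers' elimination rules: a state lies on some shorter observed-length
#' route exactly when its minimum via-length is smaller.
#'
#' @param s A cell on the board.
#' @param cfg A [goal_config()].
#' @return Positive integer number of states.
#' @export
min_via_states <- function(s, cfg) {
  assert_on_board(s, cfg$board)
  manhattan(cfg$A, s) + manhattan(s, cfg$Gs) + 1L
}

#' Enumerate all valid messages up to a length cap
#'
#' Produces every message for `cfg` (start at `A`, end at `Gs`, pass through
#' `Gr`, orthogonal steps) with at most `max_states` states, in a
#' deterministic lexicographic order of move sequences. The default cap is
#' the minimal valid length plus 4 extra states, enough to contain side trips
#' and zigzags around the goal while keeping the truncated set small.
#'
#' @param cfg A [goal_config()].
#' @param max_states Length cap in states; if below the minimal valid length
#'   an empty list is returned with a warning.
#' @return A list of [tcg_message()] objects.
#' @examples
#' cfg <- goal_config(cell(0, 0), cell(2, 0), cell(1, 1))
#' length(enumerate_messages(cfg, max_states = 5)) # 4 shortest via-walks
#' @export
enumerate_messages <- function(cfg, max_states = NULL) {
  min_l <- min_via_states(cfg$Gr, cfg)
  cap <- as.integer(max_states %||% (min_l + 4L))
  if (cap < min_l) {
    warning(sprintf("max_states = %d is below the minimal valid length %d; empty set",
                    cap, min_l))
    return(list())
  }
  walks <- enumerate_walks(cfg$board, cfg$A, to = cfg$Gs, via = cfg$Gr,
                           max_states = cap)
  lapply(walks$ids, function(w) new_tcg_message(id_to_cell(w, cfg$board), cfg$board))
}

# Shortest walk length (in states) from `from` to `to`, optionally avoiding
# one cell: plain breadth-first search on the board graph. Used for the
# goal-avoiding baseline of the level-2 Sender, where the detour can make
# the manhattan closed form invalid.
bfs_states <- function(board, from, to, forbid = NULL) {
  nbr <- neighbor_table(board)
  from_id <- cell_id(from, board)
  to_id <- cell_id(to, board)
  forbid_id <- if (!is.null(forbid)) cell_id(forbid, board) else 0L
  if (from_id == forbid_id || to_id == forbid_id) return(NA_integer_)
  dist <- rep(NA_integer_, n_cells(board))
  dist[from_id] <- 0L
  queue <- from_id
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    if (v == to_id) return(dist[v] + 1L)
    for (w in nbr[, v]) {
      if (w != 0L && w != forbid_id && is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  NA_integer_
}
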