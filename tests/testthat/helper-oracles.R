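# Independent oracles used across the suite. These deliberately take
# different algorithmic routes from the package internals: a naive recursive
# DFS for small enumerations, a (cell, visited-set) dynamic program for
# minimum-length / minimum-unique-state queries, and a plain recursive
# evaluator for the planner's policy tree.

oracle_board_nbrs <- function(board) {
  lapply(seq_len(board$n_rows * board$n_cols), function(id) {
    r <- (id - 1L) %/% board$n_cols
    c <- (id - 1L) %% board$n_cols
    out <- integer(0)
    for (d in list(c(-1L, 0L), c(0L, 1L), c(1L, 0L), c(0L, -1L))) {
      rr <- r + d[1L]; cc <- c + d[2L]
      if (rr >= 0L && rr < board$n_rows && cc >= 0L && cc < board$n_cols) {
        out <- c(out, rr * board$n_cols + cc + 1L)
      }
    }
    out
  })
}

oracle_id <- function(s, board) s[[1L]] * board$n_cols + s[[2L]] + 1L

oracle_popcount <- function(x) {
  out <- numeric(length(x))
  while (any(x > 0)) {
    out <- out + (x %% 2)
    x <- x %/% 2
  }
  out
}

# Naive depth-bounded recursive enumeration of valid messages (id vectors).
oracle_enumerate <- function(cfg, cap) {
  board <- cfg$board
  nbrs <- oracle_board_nbrs(board)
  a <- oracle_id(cfg$A, board); gs <- oracle_id(cfg$Gs, board); gr <- oracle_id(cfg$Gr, board)
  out <- list()
  rec <- function(path) {
    cur <- path[length(path)]
    if (cur == gs && gr %in% path) out[[length(out) + 1L]] <<- path
    if (length(path) >= cap) return()
    for (nb in nbrs[[cur]]) rec(c(path, nb))
  }
  rec(a)
  out
}

# (cell, visited-set) dynamic program from a start cell: the minimum number
# of walk states needed to realise each (endpoint, visited-set) pair.
# Memoised per start because it serves full-board sweeps.
.oracle_dp_cache <- new.env(parent = emptyenv())

oracle_reach_dp <- function(board, A, max_states = 12L) {
  n <- board$n_rows * board$n_cols
  stopifnot(n <= 12L)
  key <- paste(board$n_rows, board$n_cols, oracle_id(A, board), sep = "_")
  hit <- .oracle_dp_cache[[key]]
  if (!is.null(hit) && hit$max_states >= max_states) return(hit)

  nbrs <- oracle_board_nbrs(board)
  movetab <- matrix(0L, nrow = 4L, ncol = n)
  for (cl in seq_len(n)) movetab[seq_along(nbrs[[cl]]), cl] <- nbrs[[cl]]
  bits <- 2^(seq_len(n) - 1)
  first_len <- rep(NA_integer_, n * 2^n)
  a <- oracle_id(A, board)
  start <- bits[a] * n + a
  first_len[start] <- 1L
  frontier <- start
  len <- 1L
  while (len < max_states && length(frontier) > 0L) {
    cell <- ((frontier - 1) %% n) + 1
    mask <- (frontier - cell) / n
    nxt <- numeric(0)
    for (d in 1:4) {
      nb <- movetab[d, cell]
      ok <- nb > 0L
      if (!any(ok)) next
      m2 <- mask[ok] + ifelse(mask[ok] %/% bits[nb[ok]] %% 2 > 0, 0, bits[nb[ok]])
      st2 <- unique(m2 * n + nb[ok])
      new <- st2[is.na(first_len[st2])]
      first_len[new] <- len + 1L
      nxt <- c(nxt, new)
    }
    frontier <- nxt
    len <- len + 1L
  }
  out <- list(first_len = first_len, n = n, max_states = max_states)
  .oracle_dp_cache[[key]] <- out
  out
}

# Minimum message length and minimum unique-state count over valid messages
# (A -> Gs via Gr) with at most `cap` states, from the DP.
oracle_min_stats <- function(cfg, cap) {
  board <- cfg$board
  dp <- oracle_reach_dp(board, cfg$A, max_states = max(cap, 12L))
  n <- dp$n
  gs <- oracle_id(cfg$Gs, board); gr <- oracle_id(cfg$Gr, board)
  st <- which(!is.na(dp$first_len))
  lens <- dp$first_len[st]
  cell <- ((st - 1) %% n) + 1
  mask <- (st - cell) / n
  ok <- cell == gs & (mask %/% 2^(gr - 1)) %% 2 > 0 & lens <= cap
  if (!any(ok)) return(list(min_L = NA_integer_, min_U = NA_integer_))
  list(min_L = min(lens[ok]),
       min_U = as.integer(min(oracle_popcount(mask[ok]))))
}

# Independent brute-force policy-tree evaluation mirroring the planner's
# stated mathematics: edge score = base * discount^(depth-1) * reward, base
# switching from surprise to state-prior probability after the post-visit
# exit action, value = edge + max/sum over continuations.
oracle_tree_ev <- function(s, heading, steps, params, cfg,
                           component_mode = "full", reward_mode = "on",
                           aggregate = "max_path", needed = 1L, exited = FALSE,
                           depth = 1L) {
  post <- action_posterior(s, heading, params, cfg, component_mode)
  post_home <- action_posterior(s, heading, params, cfg, "state_only")
  acts <- names(post)
  landing <- attr(post, "landing")
  ev <- stats::setNames(numeric(length(acts)), acts)
  for (k in seq_along(acts)) {
    s2 <- landing[k, ]
    at_gr <- all(s2 == cfg$Gr)
    needed2 <- max(needed - as.integer(at_gr), 0L)
    r <- if (reward_mode == "off") 1 else {
      rem <- if (needed2 > 0L) manhattan(s2, cfg$Gr) + manhattan(cfg$Gr, cfg$Gs) else manhattan(s2, cfg$Gs)
      max(0, params$endowment - (steps + 1) - rem)
    }
    base <- if (!exited && component_mode != "state_only") -log2(post[[k]]) else post_home[[k]]
    val <- base * params$discount^(depth - 1L) * r
    if (depth < params$horizon) {
      child <- oracle_tree_ev(s2, acts[k], steps + 1L, params, cfg,
                              component_mode, reward_mode, aggregate,
                              needed2, exited || needed <= 0L, depth + 1L)
      val <- val + if (aggregate == "max_path") max(child) else sum(child)
    }
    ev[k] <- val
  }
  ev
}

# Shared small fixtures.
fixture_indirect <- function() goal_config(cell(0, 0), cell(2, 0), cell(1, 1))
fixture_direct <- function() goal_config(cell(0, 0), cell(2, 0), cell(1, 0))

msg_ids <- function(m, board) apply(unclass(m), 1L, oracle_id, board = board)

# All distinct-triple configurations of a board (list of goal_config).
all_configs <- function(board = tcg_board(3, 3)) {
  tri <- tcgsim:::all_config_triples(board)
  lapply(seq_len(nrow(tri)), function(i) {
    tcgsim:::triple_to_config(tri[i, , drop = FALSE], board)
  })
}
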