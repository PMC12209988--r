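#' Theory-of-Mind Sender message sets
#'
#' Each recursion depth of the mentalizing Sender selects from a different
#' subset of the valid messages for a configuration:
#'
#' * **Level 0** (no partner model): all messages of minimal length - the
#'   Sender only economises steps.
#' * **Level 1** (models a level-0 Receiver, who guesses uniformly among the
#'   visited states): all messages, within the length cap, attaining the
#'   minimal number of *unique* states - fewer visited states mean a better
#'   uniform guess.
#' * **Level 2** (models a level-1 Receiver, who eliminates states reachable
#'   by cheaper routes): first the *goal-avoiding* baseline - the shortest
#'   messages that skip `Gr` entirely - then the selection set: messages that
#'   do visit `Gr` and carry exactly one more unique state than that
#'   baseline, so the surplus state flags the goal.
#'
#' Minimisers are taken within the stated set over the capped enumeration.
#' The level-1 and level-2 sets are deliberately *not* additionally
#' length-minimised: the uniform draw ranges over all shapes (simple sweeps,
#' side trips, zigzags) achieving the unique-state optimum, which is what
#' makes the emitted message-type distribution mixed. Set
#' `tiebreak = "min_length"` to restrict either set to its shortest members.
#'
#' @param cfg A [goal_config()].
#' @param cap Length cap in states for the enumeration; defaults to the
#'   minimal valid message length plus 4.
#' @param tiebreak `"none"` (default) or `"min_length"`.
#' @return An object of class `tcg_message_set`: a list with fields `kind`,
#'   `level`, `messages`, `cap_used`, `min_length`, `min_unique`. For
#'   `build_M2()` a list with elements `direct` (goal-avoiding baseline) and
#'   `pass` (the selection set); `pass` can be empty when `Gr` is so far off
#'   every short route that no message attains baseline-plus-one unique
#'   states, which `run_session()` records as a sender failure.
#' @examples
#' cfg <- goal_config(cell(0, 0), cell(2, 0), cell(1, 1))
#' build_M0(cfg)           # the 4 shortest via-walks
#' build_M1(cfg)$min_unique # 4: one revisit beats any simple 5-state path
#' @name tom_sender_sets
NULL

new_message_set <- function(kind, level, ids, board, cap_used, min_length, min_unique) {
  structure(
    list(kind = kind, level = level,
         messages = lapply(ids, function(w) new_tcg_message(id_to_cell(w, board), board)),
         cap_used = as.integer(cap_used),
         min_length = as.integer(min_length),
         min_unique = as.integer(min_unique)),
    class = "tcg_message_set"
  )
}

#' @export
print.tcg_message_set <- function(x, ...) {
  cat(sprintf("<tcg_message_set %s | %d messages, cap %d, min L %d, min |U| %d>\n",
              x$kind, length(x$messages), x$cap_used, x$min_length, x$min_unique))
  invisible(x)
}

#' @export
length.tcg_message_set <- function(x) length(x$messages)

#' @rdname tom_sender_sets
#' @export
build_M0 <- function(cfg) {
  min_l <- min_via_states(cfg$Gr, cfg)
  walks <- enumerate_walks(cfg$board, cfg$A, to = cfg$Gs, via = cfg$Gr,
                           max_states = min_l)
  sel <- walks$L == min_l
  new_message_set("shortest", 0L, walks$ids[sel], cfg$board,
                  cap_used = min_l, min_length = min_l,
                  min_unique = min(walks$nuniq[sel]))
}

#' @rdname tom_sender_sets
#' @export
build_M1 <- function(cfg, cap = NULL, tiebreak = c("none", "min_length")) {
  tiebreak <- match.arg(tiebreak)
  min_l <- min_via_states(cfg$Gr, cfg)
  cap <- as.integer(cap %||% (min_l + 4L))
  if (cap < min_l) stop(sprintf("cap %d is below the minimal valid length %d", cap, min_l),
                        call. = FALSE)
  walks <- enumerate_walks(cfg$board, cfg$A, to = cfg$Gs, via = cfg$Gr,
                           max_states = cap)
  min_u <- min(walks$nuniq)
  sel <- walks$nuniq == min_u
  if (tiebreak == "min_length") sel <- sel & walks$L == min(walks$L[sel])
  new_message_set("fewest_unique", 1L, walks$ids[sel], cfg$board,
                  cap_used = cap, min_length = min(walks$L[sel]), min_unique = min_u)
}

#' @rdname tom_sender_sets
#' @export
build_M2 <- function(cfg, cap = NULL, tiebreak = c("none", "min_length")) {
  tiebreak <- match.arg(tiebreak)
  board <- cfg$board
  avoid_l <- bfs_states(board, cfg$A, cfg$Gs, forbid = cfg$Gr)
  if (is.na(avoid_l)) {
    stop("no route from A to Gs avoids Gr; configuration unsupported at level 2",
         call. = FALSE)
  }
  direct_walks <- enumerate_walks(board, cfg$A, to = cfg$Gs, forbid = cfg$Gr,
                                  max_states = avoid_l)
  dsel <- direct_walks$L == avoid_l
  min_u_direct <- min(direct_walks$nuniq[dsel])
  direct <- new_message_set("goal_avoiding", 2L, direct_walks$ids[dsel], board,
                            cap_used = avoid_l, min_length = avoid_l,
                            min_unique = min_u_direct)

  min_l <- min_via_states(cfg$Gr, cfg)
  cap <- as.integer(cap %||% (min_l + 4L))
  walks <- enumerate_walks(board, cfg$A, to = cfg$Gs, via = cfg$Gr,
                           max_states = cap)
  sel <- walks$nuniq == min_u_direct + 1L
  if (tiebreak == "min_length" && any(sel)) sel <- sel & walks$L == min(walks$L[sel])
  pass <- new_message_set("marked_detour", 2L, walks$ids[sel], board,
                          cap_used = cap,
                          min_length = if (any(sel)) min(walks$L[sel]) else NA_integer_,
                          min_unique = min_u_direct + 1L)
  list(direct = direct, pass = pass)
}

#' Message set for a Sender at a given mentalizing level
#'
#' Convenience dispatcher over [build_M0()], [build_M1()] and [build_M2()];
#' for level 2 the *pass* (selection) set is returned with the goal-avoiding
#' baseline attached as attribute `"direct"`.
#'
#' @inheritParams tom_sender_sets
#' @param level Mentalizing depth 0, 1 or 2.
#' @return A `tcg_message_set`.
#' @export
sender_message_set <- function(cfg, level, cap = NULL,
                               tiebreak = c("none", "min_length")) {
  level <- as.integer(level)
  switch(as.character(level),
         "0" = build_M0(cfg),
         "1" = build_M1(cfg, cap, tiebreak),
         "2" = {
           sets <- build_M2(cfg, cap, tiebreak)
           structure(sets$pass, direct = sets$direct)
         },
         stop("level must be 0, 1 or 2", call. = FALSE))
}

#' Uniform message selection
#'
#' The Sender draws uniformly at random from her message set.
#'
#' @param ms A `tcg_message_set`.
#' @param seed Optional integer seed for a reproducible draw; the global RNG
#'   stream is left untouched.
#' @return A [tcg_message()].
#' @export
select_message <- function(ms, seed = NULL) {
  stopifnot(inherits(ms, "tcg_message_set"))
  n <- length(ms$messages)
  if (n == 0L) stop(sprintf("message set '%s' is empty", ms$kind), call. = FALSE)
  if (n == 1L) return(ms$messages[[1L]])
  ms$messages[[with_seed(seed, sample.int(n, 1L))]]
}
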