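#' Receiver candidate sets and elimination decoders
#'
#' After observing the Sender's message `m*`, a Receiver at mentalizing
#' level k narrows the visited states down to a candidate set for his goal:
#'
#' * **Level 0**: every visited state except the start `A` and the Sender's
#'   goal `Gs` (both removed as cells, i.e. all their occurrences).
#' * **Level 1**: additionally eliminates any state that a step-minimising
#'   Sender could have communicated with a *shorter* message - states lying
#'   on some `A -> Gs` walk with fewer states than `m*`.
#' * **Level 2**: eliminates states communicable by a message with *fewer
#'   unique states* than `m*` (the level-1 Sender's currency).
#'
#' Each elimination rule is available in two computations. `"union"`
#' enumerates the simulated shorter messages explicitly (walks up to
#' `L(m*) - 1` states) and removes the union of their visited states, per
#' the defining rule. `"closed_form"` removes a state `s` when its minimum
#' via-length [min_via_states()] is below the observed length (level 1) or
#' the observed unique-state count (level 2). For level 1 the two are
#' provably identical. For level 2 they agree on simple observed messages
#' but can differ on revisit-heavy ones: a walk may cover `s` with fewer
#' unique states than `min_via_states(s)` whenever its two legs can share
#' cells, so the closed form is the stricter, better-behaved decoder and is
#' the default.
#'
#' An elimination rule can empty the candidate set (for level 2 this happens
#' systematically on direct trials, where `Gr` itself lies on cheap routes).
#' With `fallback = TRUE` (default) the Receiver then degrades level
#' 2 -> 1 -> 0, recording the level actually used in field `fallback_level`.
#'
#' @param m_star The observed [tcg_message()], valid for `cfg`.
#' @param cfg A [goal_config()].
#' @param mode `"closed_form"` (default) or `"union"`.
#' @param fallback Degrade to the next-lower rule on an empty set?
#' @return An object of class `tcg_candidates`: list with `candidates` (a
#'   `(row, col)` matrix, possibly 0-row), `level`, `mode`, `fallback_level`
#'   and the observed message.
#' @examples
#' cfg <- goal_config(cell(0, 0), cell(2, 0), cell(1, 1))
#' m <- tcg_message(rbind(c(0, 0), c(1, 0), c(1, 1), c(1, 0), c(2, 0)))
#' receiver_candidates(m, cfg, level = 0)$candidates # (1,0) and (1,1)
#' receiver_candidates(m, cfg, level = 1)$candidates # (1,1): (1,0) had a 3-state route
#' @name tom_receivers
NULL

new_candidates <- function(candidates, level, mode, fallback_level, m_star) {
  structure(list(candidates = candidates, level = level, mode = mode,
                 fallback_level = fallback_level, observed = m_star),
            class = "tcg_candidates")
}

#' @export
print.tcg_candidates <- function(x, ...) {
  cells <- apply(x$candidates, 1L, function(s) sprintf("(%d,%d)", s[1L], s[2L]))
  note <- if (x$fallback_level != x$level) sprintf(" (fell back to level %d)", x$fallback_level) else ""
  cat(sprintf("<tcg_candidates level %d%s> {%s}\n", x$level, note,
              paste(cells, collapse = ", ")))
  invisible(x)
}

# Unique states of m_star with A and Gs removed as cells.
base_candidates <- function(m_star, cfg) {
  u <- unique_states(m_star)
  drop <- (u[, 1L] == cfg$A[1L] & u[, 2L] == cfg$A[2L]) |
    (u[, 1L] == cfg$Gs[1L] & u[, 2L] == cfg$Gs[2L])
  u[!drop, , drop = FALSE]
}

# Union of unique states over simulated A -> Gs walks (no via constraint)
# with at most `max_states` states, filtered by `keep` on (L, nuniq).
simulated_union <- function(cfg, max_states, keep) {
  if (max_states < 1L) return(matrix(integer(0), ncol = 2L))
  walks <- enumerate_walks(cfg$board, cfg$A, to = cfg$Gs, max_states = max_states)
  sel <- keep(walks$L, walks$nuniq)
  ids <- unique(unlist(walks$ids[sel], use.names = FALSE))
  if (length(ids) == 0L) return(matrix(integer(0), ncol = 2L))
  id_to_cell(ids, cfg$board)
}

drop_rows <- function(x, drop) {
  if (nrow(drop) == 0L || nrow(x) == 0L) return(x)
  key <- paste(x[, 1L], x[, 2L])
  x[!key %in% paste(drop[, 1L], drop[, 2L]), , drop = FALSE]
}

#' @rdname tom_receivers
#' @export
tom0_candidates <- function(m_star, cfg) {
  stopifnot(validate_message(m_star, cfg))
  new_candidates(base_candidates(m_star, cfg), 0L, "exact", 0L, m_star)
}

#' @rdname tom_receivers
#' @export
tom1_candidates <- function(m_star, cfg, mode = c("closed_form", "union")) {
  mode <- match.arg(mode)
  stopifnot(validate_message(m_star, cfg))
  cand <- base_candidates(m_star, cfg)
  l_obs <- message_length(m_star)
  cand <- if (mode == "closed_form") {
    keep <- apply(cand, 1L, function(s) min_via_states(s, cfg) >= l_obs)
    cand[as.logical(keep), , drop = FALSE]
  } else {
    sim <- simulated_union(cfg, l_obs - 1L, function(L, nuniq) L < l_obs)
    drop_rows(cand, sim)
  }
  new_candidates(cand, 1L, mode, 1L, m_star)
}

#' @rdname tom_receivers
#' @export
tom2_candidates <- function(m_star, cfg, mode = c("closed_form", "union")) {
  mode <- match.arg(mode)
  stopifnot(validate_message(m_star, cfg))
  cand <- base_candidates(m_star, cfg)
  u_obs <- n_unique_states(m_star)
  l_obs <- message_length(m_star)
  cand <- if (mode == "closed_form") {
    keep <- apply(cand, 1L, function(s) min_via_states(s, cfg) >= u_obs)
    cand[as.logical(keep), , drop = FALSE]
  } else {
    sim <- simulated_union(cfg, l_obs - 1L, function(L, nuniq) nuniq < u_obs)
    drop_rows(cand, sim)
  }
  new_candidates(cand, 2L, mode, 2L, m_star)
}

#' @rdname tom_receivers
#' @param level Receiver mentalizing depth 0, 1 or 2.
#' @export
receiver_candidates <- function(m_star, cfg, level,
                                mode = c("closed_form", "union"),
                                fallback = TRUE) {
  mode <- match.arg(mode)
  level <- as.integer(level)
  stopifnot(level %in% 0:2)
  lv <- level
  repeat {
    cs <- switch(as.character(lv),
                 "0" = tom0_candidates(m_star, cfg),
                 "1" = tom1_candidates(m_star, cfg, mode),
                 "2" = tom2_candidates(m_star, cfg, mode))
    if (nrow(cs$candidates) > 0L || !fallback || lv == 0L) break
    lv <- lv - 1L
  }
  new_candidates(cs$candidates, level, mode, lv, m_star)
}

#' Uniform goal selection from a candidate set
#'
#' @param cs A `tcg_candidates` object with at least one candidate.
#' @param seed Optional integer seed for a reproducible draw.
#' @return A `c(row, col)` cell.
#' @export
select_goal <- function(cs, seed = NULL) {
  stopifnot(inherits(cs, "tcg_candidates"))
  n <- nrow(cs$candidates)
  if (n == 0L) stop("candidate set is empty; the receiver abstains", call. = FALSE)
  i <- if (n == 1L) 1L else with_seed(seed, sample.int(n, 1L))
  cs$candidates[i, ]
}

#' Analytic probability of a correct guess
#'
#' Under uniform selection the Receiver is correct with probability
#' `1 / |candidates|` when the true goal survived elimination, and 0 when it
#' was eliminated.
#'
#' @param cs A `tcg_candidates` object.
#' @param cfg The [goal_config()] the message was produced for.
#' @return A probability in `{0} U {1/k}`.
#' @export
p_correct <- function(cs, cfg) {
  stopifnot(inherits(cs, "tcg_candidates"))
  n <- nrow(cs$candidates)
  if (n == 0L) return(0)
  hit <- any(cs$candidates[, 1L] == cfg$Gr[1L] & cs$candidates[, 2L] == cfg$Gr[2L])
  if (hit) 1 / n else 0
}
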