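#' Parameters of the expectancy-violation (Surprise) Sender
#'
#' The Surprise Sender constructs its message step by step instead of
#' selecting it from a set. Expectations about the next step come from two
#' priors: a *movement* prior that favours continuing in the current heading
#' (straight-line kinetics), and a *state* prior that decays with distance
#' from the Sender's goal (progress expectation). Actions that violate these
#' expectations carry Shannon surprise, which the planner spends deliberately
#' to mark the Receiver's goal.
#'
#' @param lambda Probability of a backward move (expectation of a full
#'   reversal). Guidance range 0.001-0.3; 0 is allowed for analytic worked
#'   examples; values above 0.3 trigger a warning.
#' @param gamma Forward-to-turn odds: the ratio of the forward probability to
#'   the combined probability of the two turns. Guidance range 2-10 (with
#'   `gamma = 2`, forward is twice as likely as a turn: 2/3 vs 1/6 + 1/6);
#'   values outside it are allowed with a warning.
#' @param alpha Decay base of the state prior: a cell at manhattan distance
#'   `d` from the Sender's goal has unnormalised weight `alpha^-d`. Must be
#'   positive; `alpha = 1` is the flat (uninformative) prior.
#' @param tau Softmax inverse temperature, `>= 0`; 0 gives uniform action
#'   choice.
#' @param discount Per-depth discount `epsilon` in (0, 1]; lookahead step `i`
#'   is weighted `epsilon^(i-1)`, so the immediate step is undiscounted.
#' @param horizon Planning depth `H >= 1` of the policy tree.
#' @param endowment Starting points of a trial (default 10); also the hard
#'   step budget of message generation.
#' @return An object of class `tcg_surprise_params`.
#' @export
surprise_params <- function(lambda = 0.05, gamma = 3, alpha = 2, tau = 5,
                            discount = 0.9, horizon = 2L, endowment = 10L) {
  stopifnot(lambda >= 0, lambda < 1, gamma > 0, alpha > 0, tau >= 0,
            discount > 0, discount <= 1, horizon >= 1, endowment >= 1)
  if (lambda > 0.3) warning("lambda above the guidance band [0.001, 0.3]")
  if (gamma < 2 || gamma > 10) warning("gamma outside the guidance band [2, 10]")
  structure(list(lambda = lambda, gamma = gamma, alpha = alpha, tau = tau,
                 discount = discount, horizon = as.integer(horizon),
                 endowment = as.integer(endowment)),
            class = "tcg_surprise_params")
}

#' @export
print.tcg_surprise_params <- function(x, ...) {
  cat(sprintf(paste0("<tcg_surprise_params lambda=%g gamma=%g alpha=%g tau=%g ",
                     "discount=%g horizon=%d endowment=%d>\n"),
              x$lambda, x$gamma, x$alpha, x$tau, x$discount, x$horizon, x$endowment))
  invisible(x)
}

#' Read Surprise parameters from a YAML or JSON file
#'
#' Recognised keys: `lambda`, `gamma`, `alpha`, `tau`, `discount`,
#' `horizon`, `endowment`; missing keys take the package defaults.
#'
#' @param path Path to a YAML (or JSON) mapping.
#' @return A [surprise_params()] object.
#' @export
read_surprise_params <- function(path) {
  if (!file.exists(path)) stop(sprintf("parameter file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("lambda", "gamma", "alpha", "tau", "discount", "horizon", "endowment")
  extra <- setdiff(names(raw), known)
  if (length(extra)) warning(sprintf("ignoring unknown parameter keys: %s",
                                     paste(extra, collapse = ", ")))
  do.call(surprise_params, raw[intersect(names(raw), known)])
}

# Relative move names in a fixed order.
REL_MOVES <- c("forward", "left", "right", "back")

#' Movement prior over relative moves
#'
#' Given the current heading, the prior over the next relative move is
#' `p(back) = lambda`, `p(forward) = (gamma / (gamma + 1)) (1 - lambda)`,
#' `p(left) = p(right) = 0.5 (1 - gamma / (gamma + 1)) (1 - lambda)`; the
#' four probabilities sum to one and, for `gamma > 1` and small `lambda`,
#' are ordered forward > left = right > back. Before the first move there is
#' no heading and the prior is uniform.
#'
#' @param params A [surprise_params()].
#' @param heading One of `"north"`, `"east"`, `"south"`, `"west"`, `"none"`.
#' @return Named numeric vector over `forward`, `left`, `right`, `back`.
#' @examples
#' movement_prior(surprise_params(lambda = 0, gamma = 2)) # 2/3, 1/6, 1/6, 0
#' @export
movement_prior <- function(params, heading = "north") {
  stopifnot(inherits(params, "tcg_surprise_params"))
  heading <- match.arg(heading, c(MOVE_NAMES, "none"))
  if (heading == "none") {
    return(stats::setNames(rep(0.25, 4L), REL_MOVES))
  }
  lam <- params$lambda
  fwd <- params$gamma / (params$gamma + 1)
  c(forward = fwd * (1 - lam),
    left = 0.5 * (1 - fwd) * (1 - lam),
    right = 0.5 * (1 - fwd) * (1 - lam),
    back = lam)
}

# Relative move of absolute action `a` under `heading` (both move names).
relative_move <- function(a, heading) {
  turn <- (match(a, MOVE_NAMES) - match(heading, MOVE_NAMES)) %% 4L
  c("forward", "right", "back", "left")[turn + 1L]
}

#' State prior weight of a cell
#'
#' Unnormalised goal-distance prior `alpha^-d`, where `d` is the manhattan
#' distance from `s` to the Sender's goal. For `alpha > 1` the weight decays
#' with distance; `alpha = 1` is flat.
#'
#' @param s A cell.
#' @param Gs The Sender's goal cell.
#' @param alpha Positive decay base.
#' @return Positive weight (1 at the goal itself).
#' @export
state_prior <- function(s, Gs, alpha) {
  stopifnot(alpha > 0)
  alpha^(-manhattan(s, Gs))
}

#' Action posterior at a state
#'
#' Combines the movement prior of each available action with the state prior
#' of its landing cell and normalises over the available (on-board) actions.
#' Off-board actions get zero weight and are dropped from the normalisation.
#' `component_mode` supports the ablations: `"movement_only"` uses the
#' movement prior alone, `"state_only"` the state prior alone; with
#' `alpha = 1` the full posterior reduces exactly to `"movement_only"`.
#'
#' @param s Current cell.
#' @param heading Current heading (`"none"` before the first move, giving a
#'   uniform movement term).
#' @param params A [surprise_params()].
#' @param cfg A [goal_config()].
#' @param component_mode `"full"`, `"movement_only"` or `"state_only"`.
#' @return Named probability vector over the available absolute actions
#'   (subset of north, east, south, west), summing to 1, with the landing
#'   cells attached as attribute `"landing"`.
#' @export
action_posterior <- function(s, heading, params, cfg,
                             component_mode = c("full", "movement_only", "state_only")) {
  component_mode <- match.arg(component_mode)
  assert_on_board(s, cfg$board)
  heading <- match.arg(heading, c(MOVE_NAMES, "none"))
  landings <- lapply(MOVE_NAMES, function(a) cell_shift(s, a))
  avail <- vapply(landings, on_board, logical(1L), board = cfg$board)
  acts <- MOVE_NAMES[avail]
  landings <- landings[avail]
  move_w <- if (heading == "none") {
    rep(1, length(acts))
  } else {
    prior <- movement_prior(params, heading)
    vapply(acts, function(a) prior[[relative_move(a, heading)]], numeric(1L))
  }
  state_w <- vapply(landings, state_prior, numeric(1L),
                    Gs = cfg$Gs, alpha = params$alpha)
  w <- switch(component_mode,
              full = move_w * state_w,
              movement_only = move_w,
              state_only = state_w)
  p <- w / sum(w)
  names(p) <- acts
  attr(p, "landing") <- do.call(rbind, landings)
  p
}

#' Shannon surprise of an action probability
#'
#' @param p Probability in (0, 1].
#' @return Surprise in bits, `-log2(p)`.
#' @export
shannon_surprise <- function(p) {
  if (any(p <= 0 | p > 1)) {
    stop("surprise is defined for probabilities in (0, 1]; excluded actions never enter planning",
         call. = FALSE)
  }
  -log2(p)
}

#' Reward of landing in a state
#'
#' The points that remain from the endowment if the Sender, having used
#' `steps_elapsed` steps and now taking one more into `s_next`, finished the
#' trial from there along a shortest route. While the communicative visit to
#' the Receiver's goal is still pending (`gr_pending = TRUE`) the completion
#' routes via that goal, so
#' `endowment - (steps_elapsed + 1) - (d(s_next, Gr) + d(Gr, Gs))`;
#' afterwards it is `endowment - (steps_elapsed + 1) - d(s_next, Gs)`. Both
#' are floored at 0: exhausted points cannot go negative.
#'
#' @param s_next Landing cell.
#' @param steps_elapsed Steps already taken before this action.
#' @param cfg A [goal_config()].
#' @param params A [surprise_params()] (supplies the endowment).
#' @param gr_pending Does the remaining task still include visiting the
#'   Receiver's goal?
#' @return Non-negative points.
#' @export
step_reward <- function(s_next, steps_elapsed, cfg, params, gr_pending = FALSE) {
  stopifnot(steps_elapsed >= 0)
  rem <- if (gr_pending) {
    manhattan(s_next, cfg$Gr) + manhattan(cfg$Gr, cfg$Gs)
  } else {
    manhattan(s_next, cfg$Gs)
  }
  max(0, params$endowment - (steps_elapsed + 1) - rem)
}

#' Softmax action probabilities
#'
#' @param ev Named vector of finite expected values.
#' @param tau Inverse temperature, `>= 0`; `tau = 0` gives the uniform
#'   distribution.
#' @return Named probability vector summing to 1 (numerically stabilised by
#'   max-shift).
#' @export
softmax_policy <- function(ev, tau) {
  stopifnot(all(is.finite(ev)), tau >= 0)
  z <- exp(tau * (ev - max(ev)))
  z / sum(z)
}

#' Finite-horizon expected values of the available actions
#'
#' Builds the policy tree of depth `horizon` rooted at `s` (branching over
#' the available actions at every node) and scores each edge at depth `i`
#' with `discount^(i-1) * reward * base`. While the planned path is still
#' signalling, `base` is the Shannon surprise of the action under the
#' `component_mode` posterior and the reward routes via the Receiver's goal;
#' once the path has completed its `gr_visits_needed` visits to that goal
#' *and taken one further (still surprise-scored) action leaving it*, all
#' deeper edges switch to the homing rule, `base` = state-prior posterior
#' probability with the plain goal-distance reward. Calling with
#' `phase = "homing"` scores every edge with the homing rule. In
#' `component_mode = "state_only"` there is no expectancy channel at all and
#' every edge is probability-following (the pure navigation model).
#'
#' The value of an immediate action is its edge score plus the best
#' achievable sum along one continuation path (`aggregate = "max_path"`, a
#' finite-horizon backup); the `"sum_all_paths"` variant adds up the scores
#' of the whole subtree instead.
#'
#' @param s Current cell.
#' @param heading Current heading (or `"none"`).
#' @param steps_elapsed Steps already taken (drives the reward).
#' @param phase `"signal"` or `"homing"`.
#' @param params A [surprise_params()].
#' @param cfg A [goal_config()].
#' @param component_mode Posterior used for surprise (see
#'   [action_posterior()]).
#' @param reward_mode `"on"` or `"off"` (`"off"` sets every reward to 1,
#'   isolating the prior structure).
#' @param aggregate `"max_path"` (default) or `"sum_all_paths"`.
#' @param gr_visits_needed In the signal phase, how many (further) visits to
#'   `Gr` the planned path must make before it may switch to homing.
#' @return Named numeric vector of expected values over the available
#'   actions.
#' @export
action_values <- function(s, heading, steps_elapsed = 0L,
                          phase = c("signal", "homing"), params, cfg,
                          component_mode = c("full", "movement_only", "state_only"),
                          reward_mode = c("on", "off"),
                          aggregate = c("max_path", "sum_all_paths"),
                          gr_visits_needed = 1L) {
  phase <- match.arg(phase)
  component_mode <- match.arg(component_mode)
  reward_mode <- match.arg(reward_mode)
  aggregate <- match.arg(aggregate)
  homing_root <- phase == "homing" || component_mode == "state_only"

  # `needed`: pending visits to Gr along this planned path; `exited`: has the
  # path already taken its post-visit exit action (=> homing scores below).
  recurse <- function(s, heading, steps, depth, needed, exited) {
    surprise_edge <- !exited && component_mode != "state_only"
    p_model <- action_posterior(s, heading, params, cfg, component_mode)
    p_home <- if (!surprise_edge) action_posterior(s, heading, params, cfg, "state_only")
    acts <- names(p_model)
    landing <- attr(p_model, "landing")
    disc <- params$discount^(depth - 1L)
    ev <- stats::setNames(numeric(length(acts)), acts)
    for (k in seq_along(acts)) {
      s2 <- landing[k, ]
      at_gr <- s2[1L] == cfg$Gr[1L] && s2[2L] == cfg$Gr[2L]
      needed2 <- max(needed - as.integer(at_gr), 0L)
      r <- if (reward_mode == "off") 1 else {
        step_reward(s2, steps, cfg, params, gr_pending = needed2 > 0L)
      }
      base <- if (surprise_edge) shannon_surprise(p_model[[k]]) else p_home[[k]]
      cont <- 0
      if (depth < params$horizon) {
        child <- recurse(s2, acts[k], steps + 1L, depth + 1L, needed2,
                         exited || needed <= 0L)
        cont <- if (aggregate == "max_path") max(child) else sum(child)
      }
      ev[k] <- base * disc * r + cont
    }
    ev
  }

  recurse(s, heading, as.integer(steps_elapsed), 1L,
          if (homing_root) 0L else as.integer(gr_visits_needed),
          homing_root)
}

#' Generate a message with the Surprise Sender
#'
#' Two phases. *Signalling*: from the start, actions are chosen by softmax
#' (or argmax) over the policy-tree expected values of [action_values()],
#' which trade the Shannon surprise of a move against the points its
#' completion would leave; the phase persists until the token has visited
#' the Receiver's goal `switch_after_visits` times and then taken one
#' further surprise-chosen action leaving it (so a backtracking exit - the
#' most surprising move - is available to mark the goal). The Sender then
#' switches permanently to *homing*: single-step state-prior-times-reward
#' maximisation, i.e. a shortest route to her own goal (ties broken toward
#' the goal, then in north, east, south, west order). In
#' `component_mode = "state_only"` there is no expectancy channel and the
#' whole trajectory is prior-following navigation. Generation stops after
#' `endowment` steps; an incomplete message is flagged truncated.
#'
#' @param cfg A [goal_config()].
#' @param params A [surprise_params()].
#' @param seed Seed for the softmax draws when `policy = "sample"`.
#' @param policy `"argmax"` (deterministic, ties to the first action in
#'   north, east, south, west order) or `"sample"`.
#' @param component_mode,reward_mode Passed to [action_values()];
#'   `"movement_only"` (zigzagging expectancy violations with no goal pull)
#'   and `"state_only"` (direct navigation with no signalling) are the two
#'   diagnostic ablations.
#' @param switch_after_visits Visits to `Gr` required before homing; values
#'   above 1 let the Sender shuttle in and out of the goal (zigzag
#'   signalling).
#' @param aggregate Passed to [action_values()].
#' @return A [tcg_message()] with attributes `truncated` (logical),
#'   `surprise_bits` (per-step surprise under the model's posterior),
#'   `phase` (1 = signalling, 2 = homing, per step) and `switch_index` (the
#'   step after which homing began, or `NA`).
#' @export
surprise_message <- function(cfg, params = surprise_params(), seed = NULL,
                             policy = c("argmax", "sample"),
                             component_mode = c("full", "movement_only", "state_only"),
                             reward_mode = c("on", "off"),
                             switch_after_visits = 1L,
                             aggregate = c("max_path", "sum_all_paths")) {
  policy <- match.arg(policy)
  component_mode <- match.arg(component_mode)
  reward_mode <- match.arg(reward_mode)
  aggregate <- match.arg(aggregate)
  with_seed(seed, {
    state <- cfg$A
    heading <- "none"
    steps <- 0L
    needed <- as.integer(switch_after_visits)
    path <- list(state)
    h_bits <- numeric(0)
    phase_log <- integer(0)
    max_steps <- params$endowment
    pure_navigation <- component_mode == "state_only"

    take <- function(a, landing_row, p_model, phase_id) {
      state <<- landing_row
      heading <<- a
      steps <<- steps + 1L
      path[[steps + 1L]] <<- state
      h_bits <<- c(h_bits, shannon_surprise(p_model))
      phase_log <<- c(phase_log, phase_id)
    }

    # Phase 1: signalling (skipped entirely by the pure navigation model).
    switch_index <- NA_integer_
    while (!pure_navigation && steps < max_steps) {
      exit_step <- needed <= 0L
      ev <- action_values(state, heading, steps, phase = "signal",
                          params = params, cfg = cfg,
                          component_mode = component_mode,
                          reward_mode = reward_mode, aggregate = aggregate,
                          gr_visits_needed = max(needed, 0L))
      post <- action_posterior(state, heading, params, cfg, component_mode)
      k <- if (policy == "argmax") {
        which.max(ev)
      } else {
        sample.int(length(ev), 1L, prob = softmax_policy(ev, params$tau))
      }
      take(names(ev)[k], attr(post, "landing")[k, ], post[[k]], 1L)
      if (exit_step) {
        switch_index <- steps
        break
      }
      if (state[1L] == cfg$Gr[1L] && state[2L] == cfg$Gr[2L]) needed <- needed - 1L
    }
    if (pure_navigation) switch_index <- 0L

    # Phase 2: homing along the state prior.
    homing <- pure_navigation || !is.na(switch_index)
    while (homing && !all(state == cfg$Gs) && steps < max_steps) {
      post_home <- action_posterior(state, heading, params, cfg, "state_only")
      post_model <- action_posterior(state, heading, params, cfg, component_mode)
      landing <- attr(post_home, "landing")
      r <- vapply(seq_len(nrow(landing)), function(k) {
        if (reward_mode == "off") 1 else step_reward(landing[k, ], steps, cfg, params)
      }, numeric(1L))
      ev1 <- as.numeric(post_home) * r
      k <- order(-ev1, -as.numeric(post_home), seq_along(ev1))[1L]
      take(names(post_home)[k], landing[k, ], post_model[[k]], 2L)
    }

    visited_gr <- any(vapply(path, function(s) all(s == cfg$Gr), logical(1L)))
    m <- new_tcg_message(do.call(rbind, path), cfg$board)
    attr(m, "truncated") <- !(all(state == cfg$Gs) && visited_gr)
    attr(m, "surprise_bits") <- h_bits
    attr(m, "phase") <- phase_log
    attr(m, "switch_index") <- switch_index
    m
  })
}
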