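#' Run a simulated Sender-Receiver session
#'
#' Plays every configuration in `configs` (optionally several replications,
#' each in a freshly shuffled trial order) with one Sender model and one
#' model Receiver, and records a per-trial table: the emitted message, its
#' class, length, unique-state count and score, the Receiver's decoded goal,
#' whether it was correct, and the analytic probability of a correct uniform
#' guess. Sender failures (an empty selection set, or a truncated
#' constructed message) are recorded as failed rows rather than aborting the
#' session. All randomness is drawn from per-trial substreams derived from
#' `seed`, so the full table is reproducible.
#'
#' The Receiver here is a model agent standing in for the human Receivers of
#' the original task; the `p_correct_analytic` column is the exact uniform
#' guessing probability given the candidate set, and `correct` is one seeded
#' realisation of it.
#'
#' @param model `"tom0"`, `"tom1"`, `"tom2"` or `"surprise"`.
#' @param configs A list of [goal_config()] objects.
#' @param receiver_level Mentalizing depth of the decoding Receiver (0-2).
#' @param n_reps Replications of the configuration set.
#' @param seed Master seed.
#' @param cap Enumeration cap for the level-1/2 Senders (default: minimal
#'   length + 4).
#' @param params [surprise_params()] for the Surprise Sender.
#' @param policy,component_mode,reward_mode,switch_after_visits Passed to
#'   [surprise_message()] when `model = "surprise"`.
#' @param receiver_mode Elimination computation, `"closed_form"` or
#'   `"union"`.
#' @param endowment Trial endowment used for scoring.
#' @return A `data.frame` of class `tcg_trials`, one row per trial.
#' @examples
#' cfgs <- generate_configurations(tcg_board(3, 3), 4, 2, seed = 1)
#' tr <- run_session("tom0", cfgs, receiver_level = 0, seed = 7)
#' summary(tr)
#' @export
run_session <- function(model, configs, receiver_level = 0L, n_reps = 1L,
                        seed = 1L, cap = NULL, params = surprise_params(),
                        policy = "sample", component_mode = "full",
                        reward_mode = "on", switch_after_visits = 1L,
                        receiver_mode = "closed_form", endowment = 10L) {
  model <- match.arg(model, c("tom0", "tom1", "tom2", "surprise"))
  stopifnot(length(configs) > 0L)
  n_cfg <- length(configs)
  n_trials <- n_cfg * n_reps
  seeds <- derive_seeds(seed, 3L * n_trials + n_reps)
  order_seeds <- seeds[seq_len(n_reps)]
  trial_seeds <- matrix(seeds[-seq_len(n_reps)], ncol = 3L)

  rows <- vector("list", n_trials)
  t <- 0L
  for (rep in seq_len(n_reps)) {
    ord <- with_seed(order_seeds[rep], sample.int(n_cfg))
    for (i in ord) {
      t <- t + 1L
      cfg <- configs[[i]]
      s_send <- trial_seeds[t, 1L]
      s_recv <- trial_seeds[t, 2L]
      rows[[t]] <- run_trial(model, cfg, receiver_level, rep, i,
                             s_send, s_recv, cap, params, policy,
                             component_mode, reward_mode, switch_after_visits,
                             receiver_mode, endowment)
    }
  }
  out <- do.call(rbind, rows)
  out$trial_id <- seq_len(nrow(out))
  attr(out, "master_seed") <- seed
  class(out) <- c("tcg_trials", "data.frame")
  out
}

run_trial <- function(model, cfg, receiver_level, rep, config_id,
                      seed_sender, seed_receiver, cap, params, policy,
                      component_mode, reward_mode, switch_after_visits,
                      receiver_mode, endowment) {
  fmt <- function(s) sprintf("%d,%d", s[1L], s[2L])
  base <- data.frame(
    trial_id = NA_integer_, rep = rep, config_id = config_id, model = model,
    A = fmt(cfg$A), Gs = fmt(cfg$Gs), Gr = fmt(cfg$Gr),
    trial_type = cfg$trial_type,
    message = NA_character_, message_class = NA_character_,
    L = NA_integer_, n_unique = NA_integer_, score = NA_integer_,
    set_size = NA_integer_, truncated = FALSE, failure = NA_character_,
    receiver_level = receiver_level, receiver_fallback = NA_integer_,
    n_candidates = NA_integer_, decoded_goal = NA_character_,
    correct = NA, p_correct_analytic = NA_real_,
    seed_sender = seed_sender, seed_receiver = seed_receiver,
    stringsAsFactors = FALSE
  )

  msg <- NULL
  res <- tryCatch({
    if (model == "surprise") {
      m <- surprise_message(cfg, params, seed = seed_sender, policy = policy,
                            component_mode = component_mode,
                            reward_mode = reward_mode,
                            switch_after_visits = switch_after_visits)
      base$truncated <- isTRUE(attr(m, "truncated"))
      if (base$truncated) {
        base$failure <- "truncated"
        base$message <- as.character(message_to_json(m))
        NULL
      } else m
    } else {
      set <- sender_message_set(cfg, level = as.integer(substring(model, 4L)), cap = cap)
      base$set_size <- length(set$messages)
      if (length(set$messages) == 0L) {
        base$failure <- "empty_message_set"
        NULL
      } else {
        select_message(set, seed = seed_sender)
      }
    }
  }, error = function(e) {
    base$failure <<- conditionMessage(e)
    NULL
  })
  msg <- res
  if (is.null(msg)) return(base)

  base$message <- as.character(message_to_json(msg))
  base$message_class <- classify_message(msg, cfg)
  base$L <- message_length(msg)
  base$n_unique <- n_unique_states(msg)
  base$score <- message_score(msg, endowment)

  cs <- receiver_candidates(msg, cfg, level = receiver_level,
                            mode = receiver_mode, fallback = TRUE)
  base$receiver_fallback <- cs$fallback_level
  base$n_candidates <- nrow(cs$candidates)
  base$p_correct_analytic <- p_correct(cs, cfg)
  if (nrow(cs$candidates) > 0L) {
    g <- select_goal(cs, seed = seed_receiver)
    base$decoded_goal <- sprintf("%d,%d", g[1L], g[2L])
    base$correct <- all(g == cfg$Gr)
  } else {
    base$correct <- FALSE
  }
  base
}

#' Summarise a session: message-type frequencies and accuracy
#'
#' Per model, the fraction of (non-failed) trials in each message class, the
#' realised and analytic decoding accuracy per class, and overall accuracy.
#'
#' @param records A `tcg_trials` table (rows from several models may be
#'   concatenated with `rbind`).
#' @return An object of class `tcg_session_summary` with data.frame fields
#'   `class_freq`, `class_accuracy`, `model_accuracy`, and counts `n_trials`
#'   and `n_failed`.
#' @export
summarize_session <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  ok <- !is.na(records$message_class)
  rec <- records[ok, , drop = FALSE]
  n_failed <- sum(!ok)
  if (nrow(rec) == 0L) stop("no successful trials to summarise", call. = FALSE)

  freq <- as.data.frame(table(model = rec$model, class = rec$message_class),
                        stringsAsFactors = FALSE)
  names(freq)[3L] <- "n"
  tot <- stats::ave(freq$n, freq$model, FUN = sum)
  freq$freq <- freq$n / tot
  freq <- freq[freq$n > 0L, , drop = FALSE]
  rownames(freq) <- NULL

  acc_by <- function(split) {
    parts <- split(rec, split, drop = TRUE)
    out <- lapply(parts, function(d) {
      data.frame(n = nrow(d),
                 accuracy = mean(d$correct, na.rm = TRUE),
                 p_correct = mean(d$p_correct_analytic, na.rm = TRUE))
    })
    cbind(do.call(rbind, lapply(strsplit(names(parts), "\\."), function(x) {
      stats::setNames(as.data.frame(as.list(x), stringsAsFactors = FALSE),
                      if (length(x) == 2L) c("model", "class") else "model")
    })), do.call(rbind, out), row.names = NULL)
  }

  structure(
    list(class_freq = freq,
         class_accuracy = acc_by(list(rec$model, rec$message_class)),
         model_accuracy = acc_by(list(rec$model)),
         n_trials = nrow(records), n_failed = n_failed),
    class = "tcg_session_summary"
  )
}

#' @export
print.tcg_session_summary <- function(x, ...) {
  cat(sprintf("TCG session summary: %d trials (%d failed/truncated)\n",
              x$n_trials, x$n_failed))
  cat("\nMessage-class frequencies:\n")
  print(x$class_freq, row.names = FALSE)
  cat("\nDecoding accuracy by class (realised and analytic):\n")
  print(x$class_accuracy, row.names = FALSE)
  cat("\nOverall model accuracy:\n")
  print(x$model_accuracy, row.names = FALSE)
  invisible(x)
}

#' @export
summary.tcg_trials <- function(object, ...) summarize_session(object)

#' Read and write trial tables
#'
#' Trial tables are plain CSV with the message embedded as a JSON string in
#' one column (one row per trial).
#'
#' @param records A `tcg_trials` data.frame.
#' @param path File path.
#' @export
write_trials <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop(sprintf("trials file not found: %s", path), call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("tcg_trials", "data.frame")
  out
}
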