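test_that("movement prior reproduces the worked odds and the analytic identity", {
  p <- movement_prior(surprise_params(lambda = 0, gamma = 2), "north")
  expect_equal(unname(p), c(2 / 3, 1 / 6, 1 / 6, 0))
  p1 <- suppressWarnings(movement_prior(surprise_params(lambda = 0, gamma = 1), "east"))
  expect_equal(unname(p1), c(1 / 2, 1 / 4, 1 / 4, 0))
  p2 <- movement_prior(surprise_params(lambda = 0.1, gamma = 2), "south")
  expect_equal(unname(p2), c(0.6, 0.15, 0.15, 0.1))

  # sum-to-one identity over a parameter sweep, and the stated ordering
  grid <- expand.grid(lambda = seq(0, 0.9, by = 0.1), gamma = c(1.5, 2, 3, 5, 10))
  for (i in seq_len(nrow(grid))) {
    lam <- grid$lambda[i]; gam <- grid$gamma[i]
    pr <- suppressWarnings(movement_prior(surprise_params(lambda = lam, gamma = gam)))
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    if (gam > 1 && lam < pr[["left"]]) {
      expect_true(pr[["forward"]] > pr[["left"]] &&
                    pr[["left"]] == pr[["right"]] && pr[["right"]] > pr[["back"]])
    }
  }
  expect_equal(unname(movement_prior(surprise_params(), "none")), rep(0.25, 4))
})

test_that("state prior decays geometrically with goal distance", {
  gs <- cell(2, 0)
  expect_equal(state_prior(gs, gs, alpha = 2), 1)
  expect_equal(state_prior(cell(0, 0), gs, alpha = 2), 0.25)
  expect_equal(state_prior(cell(0, 2), gs, alpha = 1), 1)
  expect_error(state_prior(cell(0, 0), gs, alpha = 0))
})

test_that("action posterior normalises, drops walls, and reduces under a flat prior", {
  cfg <- fixture_indirect()
  params <- surprise_params()
  for (h in c("none", "north", "east")) {
    for (mode in c("full", "movement_only", "state_only")) {
      p <- action_posterior(cell(1, 1), h, params, cfg, mode)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_length(p, 4L)
    }
  }
  corner <- action_posterior(cell(0, 0), "none", params, cfg, "movement_only")
  expect_length(corner, 2L)                       # walls dropped
  expect_equal(unname(as.numeric(corner)), c(0.5, 0.5))

  flat <- surprise_params(alpha = 1)
  expect_equal(as.numeric(action_posterior(cell(1, 0), "south", flat, cfg, "full")),
               as.numeric(action_posterior(cell(1, 0), "south", flat, cfg, "movement_only")),
               tolerance = 1e-12)
})

test_that("surprise is the binary log loss", {
  expect_equal(shannon_surprise(1), 0)
  expect_equal(shannon_surprise(0.5), 1)
  expect_equal(shannon_surprise(0.25), 2)
  expect_error(shannon_surprise(0), "\\(0, 1\\]")
})

test_that("rewards count remaining points under optimal completion", {
  cfg <- fixture_indirect()
  params <- surprise_params()
  expect_equal(step_reward(cell(1, 0), 3, cfg, params), 10 - 4 - 1)
  expect_equal(step_reward(cell(0, 2), 3, cfg, params), 10 - 4 - 4)
  expect_equal(step_reward(cfg$Gs, 9, cfg, params), 0)
  # monotone nonincreasing in elapsed steps
  r <- vapply(0:9, step_reward, numeric(1L), s_next = cell(1, 1), cfg = cfg, params = params)
  expect_true(all(diff(r) <= 0))
  # pending communicative visit routes the completion via Gr
  expect_equal(step_reward(cell(2, 0), 1, cfg, params, gr_pending = TRUE), 10 - 2 - 4)
})

test_that("softmax matches the closed form and degenerates to uniform", {
  expect_equal(unname(softmax_policy(c(a = 1, b = 0), tau = 1)),
               c(exp(1), 1) / (exp(1) + 1))
  expect_equal(unname(softmax_policy(c(1, 1, 1), tau = 5)), rep(1 / 3, 3))
  expect_equal(unname(softmax_policy(c(3, -2, 7), tau = 0)), rep(1 / 3, 3))
  expect_equal(sum(softmax_policy(c(1000, 999, 0), tau = 10)), 1)  # stabilised
})

test_that("policy-tree values equal the brute-force recursion and collapse at depth 1", {
  cfg <- fixture_indirect()
  for (H in 1:3) {
    for (agg in c("max_path", "sum_all_paths")) {
      params <- surprise_params(horizon = H)
      for (st in list(list(cell(0, 0), "none", 0L), list(cell(1, 0), "south", 1L),
                      list(cell(1, 1), "east", 2L))) {
        got <- action_values(st[[1L]], st[[2L]], st[[3L]], "signal", params, cfg,
                             aggregate = agg)
        want <- oracle_tree_ev(st[[1L]], st[[2L]], st[[3L]], params, cfg, aggregate = agg)
        expect_equal(got, want, tolerance = 1e-12,
                     info = sprintf("H=%d agg=%s", H, agg))
      }
    }
  }
  # depth 1 equals the single-step expected value
  p1 <- surprise_params(horizon = 1)
  ev <- action_values(cell(1, 0), "south", 1L, "signal", p1, cfg)
  post <- action_posterior(cell(1, 0), "south", p1, cfg)
  manual <- vapply(seq_along(post), function(k) {
    s2 <- attr(post, "landing")[k, ]
    pending <- !all(s2 == cfg$Gr)
    shannon_surprise(post[[k]]) * step_reward(s2, 1L, cfg, p1, gr_pending = pending)
  }, numeric(1L))
  expect_equal(unname(ev), unname(manual), tolerance = 1e-12)
})

test_that("with full lookahead the argmax at the goal's neighbour turns into the goal", {
  cfg <- fixture_indirect()
  params <- surprise_params()   # gamma 3, lambda 0.05, alpha 2, H 2
  ev <- action_values(cell(1, 0), "south", 1L, "signal", params, cfg)
  expect_equal(names(which.max(ev)), "east")           # into (1,1), not onward south
  want <- oracle_tree_ev(cell(1, 0), "south", 1L, params, cfg)
  expect_equal(names(which.max(want)), "east")
})

test_that("discounting at 1 weighs all depths equally", {
  cfg <- fixture_indirect()
  pa <- surprise_params(discount = 1, horizon = 3)
  got <- action_values(cell(0, 0), "none", 0L, "signal", pa, cfg)
  want <- oracle_tree_ev(cell(0, 0), "none", 0L, pa, cfg)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the full model emits the canonical enter-exit message and homes optimally", {
  cfg <- fixture_indirect()
  m <- surprise_message(cfg, policy = "argmax")
  expect_false(attr(m, "truncated"))
  expect_true(validate_message(m, cfg))
  expect_equal(classify_message(m, cfg), "enter_exit")
  expect_identical(unclass(m)[, 1L], c(0L, 1L, 1L, 1L, 2L))
  # homing suffix is a shortest route from the switch state
  sw <- attr(m, "switch_index")
  s_switch <- unclass(m)[sw + 1L, ]
  expect_identical(message_length(m) - 1L - sw, manhattan(s_switch, cfg$Gs))
  # surprise spike sits at the goal entry
  h <- attr(m, "surprise_bits")
  expect_equal(which.max(h), 2L)
})

test_that("ablations reproduce their diagnostic patterns", {
  cfg <- fixture_indirect()
  # movement priors alone, no reward: zigzagging, inefficient termination
  mz <- surprise_message(cfg, policy = "argmax", component_mode = "movement_only",
                         reward_mode = "off")
  s <- unclass(mz)
  dirs <- paste(diff(s[, 1L]), diff(s[, 2L]))
  expect_gt(sum(dirs[-1L] != dirs[-length(dirs)]), 2L)   # repeated reversals
  expect_gt(message_length(mz), min_via_states(cfg$Gr, cfg))
  # with the goal off the zigzag course the step budget runs out entirely
  cfg_far <- goal_config(cell(0, 0), cell(2, 0), cell(2, 2))
  mz2 <- surprise_message(cfg_far, policy = "argmax", component_mode = "movement_only",
                          reward_mode = "off")
  expect_true(attr(mz2, "truncated"))
  expect_identical(message_length(mz2), surprise_params()$endowment + 1L)

  # state priors alone: a minimal direct path with no revisits (and no signal)
  md <- surprise_message(cfg, policy = "argmax", component_mode = "state_only")
  sd <- unclass(md)
  expect_identical(nrow(sd), manhattan(cfg$A, cfg$Gs) + 1L)
  expect_identical(anyDuplicated(sd), 0L)
  expect_identical(unname(sd[nrow(sd), ]), unname(as.integer(cfg$Gs)))
})

test_that("seeded sampling is reproducible and leaves the global RNG alone", {
  cfg <- fixture_indirect()
  before <- withr::with_seed(1, runif(1))
  m1 <- surprise_message(cfg, seed = 5, policy = "sample")
  m2 <- surprise_message(cfg, seed = 5, policy = "sample")
  expect_identical(unclass(m1), unclass(m2))
  m3 <- surprise_message(cfg, seed = 6, policy = "sample")
  expect_true(validate_message(m3, cfg) || attr(m3, "truncated"))
  after <- withr::with_seed(1, runif(1))
  expect_identical(before, after)
})

test_that("letting the planner revisit the goal before homing yields wiggles", {
  cfg <- fixture_indirect()
  m <- surprise_message(cfg, policy = "argmax", switch_after_visits = 2L)
  s <- unclass(m)
  gr_hits <- sum(s[, 1L] == cfg$Gr[1L] & s[, 2L] == cfg$Gr[2L])
  expect_gte(gr_hits, 2L)
  if (!attr(m, "truncated")) expect_equal(classify_message(m, cfg), "wiggly")
})
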