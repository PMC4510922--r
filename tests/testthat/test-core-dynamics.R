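test_that("bounceback signals combine by noisy-OR over firing rules", {
  # 4-variable system; units at X=1: (1,1) and (3,0)
  X <- rep(0L, 8L)
  X[unit_index(1, 1)] <- 1L
  X[unit_index(3, 0)] <- 1L
  r <- bounceback_rule(c(unit_index(1, 1), unit_index(3, 0)),
                       unit_index(4, 1), "CLAUSE")
  s <- compute_signals(X, list(r), 1.0)
  expect_equal(s[unit_index(4, 1)], 1.0)
  expect_equal(sum(s), 1.0)  # no other unit blocked

  # condition not fully met -> no firing anywhere
  X2 <- rep(0L, 8L)
  X2[unit_index(1, 1)] <- 1L
  expect_equal(compute_signals(X2, list(r), 1.0), rep(0, 8))

  # two rules on one target at 0.5 each -> 1 - 0.5^2
  r2 <- bounceback_rule(unit_index(2, 0), unit_index(4, 1), "CLAUSE")
  X3 <- X
  X3[unit_index(2, 0)] <- 1L
  s3 <- compute_signals(X3, list(r, r2), 0.5)
  expect_equal(s3[unit_index(4, 1)], 0.75)

  # empty condition fires unconditionally
  r3 <- bounceback_rule(integer(0), unit_index(1, 0), "CLAUSE")
  expect_equal(compute_signals(rep(-1L, 8L), list(r3), 1.0)[unit_index(1, 0)], 1.0)

  # missing intensity entry for a present rule type is a configuration error
  expect_error(compute_signals(X, list(r), c(CONTRA = 1.0)), "intensity")
})

test_that("resource supply follows the interpolated probability", {
  cfg <- amoeba_config(p_free = 1, p_blocked = 0)
  set.seed(1)
  expect_equal(supply_resources(rep(0, 50), cfg), rep(1L, 50))
  expect_equal(supply_resources(rep(1, 50), cfg), rep(0L, 50))
  # s = 0.5 with these endpoints: empirical frequency ~ Binom(n, 0.5)
  set.seed(2)
  draws <- supply_resources(rep(0.5, 10000), cfg)
  expect_gt(mean(draws), 0.5 - 4 * sqrt(0.25 / 10000))
  expect_lt(mean(draws), 0.5 + 4 * sqrt(0.25 / 10000))
})

test_that("accumulation saturates at both ends", {
  X <- c(-1L, -1L, 0L, 0L, 1L, 1L)
  R <- c(0L, 1L, 0L, 1L, 0L, 1L)
  expect_equal(update_X(X, R), c(-1L, 0L, -1L, 1L, 0L, 1L))
})

test_that("assignment decoding commits one-sided variables and keeps memory", {
  # (X_{i,0}, X_{i,1}) per variable: committed 0, ambiguous both-up, committed 1
  X <- c(1L, -1L, 1L, 1L, 0L, 1L)
  prev <- c(1L, 1L, 0L)
  expect_equal(decode_assignment(X, prev), c(0L, 1L, 1L))
})

test_that("stability requires expressed variables, unblocked ups, blocked downs", {
  rules <- compile_bounceback_rules(demo_f)
  for (sol in demo_solutions) {
    X <- clean_X(bits(sol))
    s <- compute_signals(X, rules, 1.0)
    expect_true(is_stable(X, s))
  }
  # a committed non-solution has a fully violated clause -> blocked up unit
  X <- clean_X(c(0L, 0L, 0L, 0L))
  s <- compute_signals(X, rules, 1.0)
  expect_false(is_stable(X, s))
  # vacuous blocking: no rules, everything up
  expect_true(is_stable(rep(1L, 8L), rep(0, 8L)))
  # a variable squeezed down on both sides does not express a value
  X2 <- clean_X(c(1L, 1L, 1L, 1L))
  X2[unit_index(2, 0)] <- -1L
  X2[unit_index(2, 1)] <- -1L
  s2 <- rep(1, 8L)
  s2[X2 == 1L] <- 0
  expect_false(is_stable(X2, s2))
})

test_that("a step is deterministic given the seed and saturates from below", {
  rules <- compile_bounceback_rules(demo_f)
  cfg <- amoeba_config(max_steps = 10)
  st <- amoeba_state(4, c(0L, 1L, 0L, 1L))
  set.seed(3); a <- amoeba_step(st, rules, 1.0, cfg)
  set.seed(3); b <- amoeba_step(st, rules, 1.0, cfg)
  expect_identical(a, b)

  # zero rules, p_free = 1: X climbs -1 -> 0 -> 1 in exactly 2 steps
  cfg1 <- amoeba_config(p_free = 1, p_blocked = 0)
  st <- list(X = rep(-1L, 8L), x = c(0L, 0L, 0L, 0L), t = 0L)
  st <- amoeba_step(st, list(), 1.0, cfg1)$state
  expect_equal(st$X, rep(0L, 8L))
  st <- amoeba_step(st, list(), 1.0, cfg1)$state
  expect_equal(st$X, rep(1L, 8L))
})

test_that("the compiled run agrees step-for-step with the pure R dynamics", {
  rules <- compile_bounceback_rules(demo_f)
  cfg <- amoeba_config(max_steps = 300)
  x0 <- c(1L, 0L, 0L, 1L)
  traj <- local({ set.seed(99)
    amoeba_run(rules, 4, cfg, x0 = x0, stop = "never") })
  set.seed(99)
  st <- amoeba_state(4, x0)
  xs <- matrix(0L, 300, 4); stb <- logical(300)
  for (t in 1:300) {
    out <- amoeba_step(st, rules, 1.0, cfg)
    stb[t] <- out$stable; st <- out$state; xs[t, ] <- out$assignment
  }
  expect_identical(unname(trajectory_assignments(traj, 1:299)), xs[1:299, ])
  expect_identical(traj$X_final, st$X)
  expect_identical(traj$stable, stb)  # both flag the state being left
})

test_that("unit values stay in {-1,0,1} along random trajectories", {
  for (seed in 1:5) {
    f <- generate_uniform_3sat(8, 30, seed = seed)
    rules <- compile_bounceback_rules(f)
    traj <- amoeba_run(rules, 8, amoeba_config(max_steps = 500, seed = seed),
                       stop = "never")
    expect_true(all(traj$X_final %in% -1:1))
    expect_true(all(traj$event_assignments %in% 0:1))
  }
})

test_that("raising any rule-type intensity never lowers a target's signal", {
  set.seed(10)
  for (rep in 1:20) {
    n <- 5L
    rules <- lapply(1:8, function(k) {
      cond <- sample.int(2L * n, sample(0:3, 1))
      tgt <- sample(setdiff(seq_len(2L * n), cond), 1)
      bounceback_rule(cond, tgt, sample(c("A", "B"), 1))
    })
    X <- sample(-1:1, 2L * n, replace = TRUE)
    lo <- c(A = 0.3, B = 0.5)
    hi <- c(A = 0.7, B = 0.5)
    s_lo <- compute_signals(X, rules, lo)
    s_hi <- compute_signals(X, rules, hi)
    expect_true(all(s_hi >= s_lo - 1e-12))
    # affine supply probability is decreasing in s, so blocking is monotone
    cfg <- amoeba_config()
    p_lo <- (1 - s_lo) * cfg$p_free + s_lo * cfg$p_blocked
    p_hi <- (1 - s_hi) * cfg$p_free + s_hi * cfg$p_blocked
    expect_true(all(p_hi <= p_lo + 1e-12))
  }
})

test_that("run records events, visits and first-target bookkeeping", {
  rules <- compile_bounceback_rules(demo_f)
  traj <- amoeba_run(rules, 4, amoeba_config(max_steps = 20000, seed = 8),
                     target = list(type = "cnf", clauses = demo_f$clauses),
                     stop = "never")
  expect_equal(traj$steps, 20000L)
  expect_false(is.na(traj$first_target_step))
  # reconstructed assignment at the first target step satisfies f
  a <- trajectory_assignments(traj, traj$first_target_step)
  expect_true(sat_verify(demo_f, as.integer(a)))
  # long run transitions among several solutions
  vis <- trajectory_visits(traj, function(x) sat_verify(demo_f, x))
  expect_gte(length(unique(vis$state)), 2L)
  expect_true(all(vis$state %in% demo_solutions))
  expect_true(all(vis$dwell >= traj$config$stability_window))
  # max_steps = 1 produces a single evaluated state
  t1 <- amoeba_run(rules, 4, amoeba_config(max_steps = 1, seed = 8),
                   stop = "never")
  expect_equal(t1$steps, 1L)
})
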