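#' Solver configuration for the amoeba dynamics
#'
#' Holds the stochastic resource-supply parameters and run-control settings
#' shared by both frontends. An unblocked unit receives a resource with
#' probability `p_free`; a fully blocked unit (combined bounceback signal
#' s = 1) with probability `p_blocked`. Intermediate signals interpolate:
#' \eqn{p(s) = (1 - s) p_{free} + s \, p_{blocked}}.
#'
#' @param p_free supply probability for an unblocked unit, in \[0, 1\].
#'   The default 0.88 keeps enough spontaneous churn that blocked-in
#'   variables are released by their neighbourhood instead of freezing
#'   the search (see the methods vignette for the calibration).
#' @param p_blocked supply probability for a fully blocked unit; must be
#'   strictly less than `p_free`. Near-absolute blocking (default 0.002)
#'   preserves commitment to expressed values while keeping the
#'   fluctuation-driven escapes that let the search leave local traps.
#' @param max_steps step budget for a run.
#' @param stability_window number of consecutive steps a constraint-
#'   satisfying decoded state must persist to be logged as a metastable
#'   visit.
#' @param seed optional integer seed applied (via [set.seed()]) at the start
#'   of any run using this config; `NULL` leaves the RNG stream untouched.
#' @return an object of class `amoeba_config`.
#' @export
amoeba_config <- function(p_free = 0.88, p_blocked = 0.002,
                          max_steps = 10000L, stability_window = 3L,
                          seed = NULL) {
  stopifnot(p_free >= 0, p_free <= 1, p_blocked >= 0, p_blocked <= 1,
            p_blocked < p_free, max_steps >= 1, stability_window >= 1)
  structure(list(p_free = p_free, p_blocked = p_blocked,
                 max_steps = as.integer(max_steps),
                 stability_window = as.integer(stability_window),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "amoeba_config")
}

#' Combined bounceback signals for the current unit state
#'
#' A rule fires when every unit in its condition has X = 1 (an empty
#' condition always fires). Multiple firing rules on one target combine by
#' noisy-OR of their type intensities:
#' \eqn{s = 1 - \prod_r (1 - \sigma_r)}, which reduces to a plain OR when
#' all intensities are 1.
#'
#' @param X integer vector of unit values in \{-1, 0, 1\}, length 2N.
#' @param rules list of [bounceback_rule()] objects.
#' @param intensities scalar or type-named numeric vector, see
#'   [rule_intensities()].
#' @return numeric vector of per-unit signals in \[0, 1\], length 2N.
#' @export
compute_signals <- function(X, rules, intensities = 1.0) {
  sig <- rule_intensities(rules, intensities)
  keep <- rep(1.0, length(X))
  at_one <- X == 1L
  for (k in seq_along(rules)) {
    r <- rules[[k]]
    if (all(at_one[r$condition])) keep[r$target] <- keep[r$target] * (1 - sig[k])
  }
  1 - keep
}

#' Sample one round of stochastic resource supply
#'
#' Each unit independently receives a resource (R = 1) with probability
#' \eqn{(1 - s) p_{free} + s \, p_{blocked}} given its combined bounceback
#' signal s. Draws come from the current R RNG stream, so [set.seed()]
#' makes the supply sequence reproducible.
#'
#' @param signals per-unit signals in \[0, 1\].
#' @param config an [amoeba_config()].
#' @return integer vector of 0/1 supplies, parallel to `signals`.
#' @export
supply_resources <- function(signals, config) {
  p <- (1 - signals) * config$p_free + signals * config$p_blocked
  as.integer(runif(length(signals)) < p)
}

#' Saturating accumulation of supplied resources
#'
#' Each unit's X moves one step toward +1 on supply and one step toward -1
#' on starvation, saturating at the interval ends.
#'
#' @param X integer vector in \{-1, 0, 1\}.
#' @param R integer 0/1 supply vector.
#' @return updated X, values still in \{-1, 0, 1\}.
#' @export
update_X <- function(X, R) {
  up <- R == 1L & X < 1L
  down <- R == 0L & X > -1L
  X + as.integer(up) - as.integer(down)
}

#' Decode unit values into a variable assignment
#'
#' Variable i takes value v when unit (i, v) is fully activated (X = 1)
#' while its opponent (i, 1 - v) is at or below 0; otherwise it keeps its
#' previous value, so ambiguous unit pairs leave the assignment unchanged.
#'
#' @param X integer vector of unit values, length 2N.
#' @param previous previous assignment, integer 0/1 vector of length N.
#' @return integer 0/1 assignment of length N.
#' @export
decode_assignment <- function(X, previous) {
  n <- length(previous)
  X0 <- X[seq(1L, 2L * n, by = 2L)]
  X1 <- X[seq(2L, 2L * n, by = 2L)]
  out <- as.integer(previous)
  out[X0 == 1L & X1 <= 0L] <- 0L
  out[X1 == 1L & X0 <= 0L] <- 1L
  out
}

#' Stability criterion for a unit state
#'
#' A state is stable when (a) every fully activated unit (X = 1) is
#' unblocked (s = 0), (b) every unit at or below 0 is blocked (s > 0),
#' and (c) every variable expresses a value, i.e. has at least one unit
#' at X = 1. Condition (c) excludes states in which a variable is
#' squeezed down on both sides by blocking from other variables: such
#' states persist for a while, but their decoded value is a stale memory
#' of the readout rule rather than something the unit state expresses.
#' With the full rule set (mutual suppression included) and binary
#' intensities, stable states then coincide exactly with
#' constraint-satisfying assignments. Under continuous intensities
#' "blocked" means any positive combined signal.
#'
#' @param X integer vector of unit values.
#' @param signals per-unit combined signals from [compute_signals()],
#'   computed from the same `X`.
#' @return logical scalar.
#' @export
is_stable <- function(X, signals) {
  n <- length(X) %/% 2L
  expressed <- X[seq(1L, 2L * n, by = 2L)] == 1L | X[seq(2L, 2L * n, by = 2L)] == 1L
  all(expressed) && all((X == 1L & signals == 0) | (X <= 0L & signals > 0))
}

#' Initial state of the unit system
#'
#' All X start at 0 (neutral volume displacement); the initial decoded
#' assignment is drawn uniformly at random unless supplied.
#'
#' @param n_vars number of variables N.
#' @param x0 optional initial assignment (integer 0/1 length N).
#' @return list with elements `X` (length 2N, all 0), `x` (length N),
#'   `t = 0`.
#' @export
amoeba_state <- function(n_vars, x0 = NULL) {
  if (is.null(x0)) x0 <- as.integer(runif(n_vars) < 0.5)
  stopifnot(length(x0) == n_vars, all(x0 %in% c(0L, 1L)))
  list(X = rep(0L, 2L * n_vars), x = as.integer(x0), t = 0L)
}

#' One synchronous step of the amoeba dynamics
#'
#' Signals are computed from X(t), the stability flag refers to the state
#' being left, resources are sampled, X advances, and the assignment is
#' re-decoded from the new X. Fully synchronous semantics: every quantity
#' at t + 1 depends only on the state at t.
#'
#' @param state list as returned by [amoeba_state()] or a previous step.
#' @param rules list of [bounceback_rule()]s.
#' @param intensities scalar or type-named intensity map.
#' @param config an [amoeba_config()].
#' @return list with `state` (advanced one step), `assignment` (the decoded
#'   assignment of the new state) and `stable` (stability of the state that
#'   was left).
#' @export
amoeba_step <- function(state, rules, intensities, config) {
  s <- compute_signals(state$X, rules, intensities)
  stable <- is_stable(state$X, s)
  R <- supply_resources(s, config)
  Xn <- update_X(state$X, R)
  xn <- decode_assignment(Xn, state$x)
  list(state = list(X = Xn, x = xn, t = state$t + 1L),
       assignment = xn, stable = stable)
}

target_spec_parts <- function(target, n_vars) {
  if (is.null(target))
    return(list(type = 0L, flat = integer(0), off = 0L, sums = integer(0)))
  if (identical(target$type, "cnf")) {
    cl <- target$clauses
    list(type = 1L,
         flat = as.integer(unlist(cl)),
         off = c(0L, cumsum(vapply(cl, length, 1L))),
         sums = integer(0))
  } else if (identical(target$type, "valence")) {
    gr <- target$groups
    list(type = 2L,
         flat = as.integer(unlist(gr)),
         off = c(0L, cumsum(vapply(gr, length, 1L))),
         sums = as.integer(target$sums))
  } else stop("unknown target type: ", target$type)
}

#' Run the amoeba dynamics and record the trajectory
#'
#' Iterates the synchronous dynamics for up to `config$max_steps` steps,
#' recording the decoded assignment (compressed to change events), the
#' per-step stability flag, the first step at which the target predicate
#' holds, and the first step at which a target-satisfying assignment has
#' persisted for `config$stability_window` consecutive steps.
#'
#' @param rules list of [bounceback_rule()]s.
#' @param n_vars number of variables N.
#' @param config an [amoeba_config()]; if it carries a `seed`, the RNG is
#'   seeded before the initial assignment is drawn.
#' @param intensities scalar or type-named intensity map.
#' @param target `NULL`, or `list(type = "cnf", clauses = <list of signed
#'   literal vectors>)`, or `list(type = "valence", groups = <list of
#'   variable-index vectors>, sums = <required group sums>)`.
#' @param x0,X0 optional initial assignment / unit values (defaults:
#'   uniform random assignment, all-zero X).
#' @param stop `"never"` runs the full budget, `"first"` stops at the first
#'   target-satisfying decoded assignment, `"window"` stops once such an
#'   assignment has persisted for the stability window.
#' @param record logical; record events and stability flags (disable for
#'   benchmark runs where only the stopping step matters).
#' @return an object of class `amoeba_trajectory`: a list with `steps`,
#'   `first_target_step`, `first_window_step` (`NA` when censored; 0-based
#'   step indices), `found` (the window-persistent assignment or `NULL`),
#'   `x_final`, `X_final`, `event_steps`, `event_assignments` (one row per
#'   change), `stable` (per-step logical) and `n_vars`.
#' @export
amoeba_run <- function(rules, n_vars, config = amoeba_config(),
                       intensities = 1.0, target = NULL,
                       x0 = NULL, X0 = NULL,
                       stop = c("never", "first", "window"),
                       record = TRUE) {
  stop <- match.arg(stop)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(x0)) x0 <- as.integer(runif(n_vars) < 0.5)
  if (is.null(X0)) X0 <- rep(0L, 2L * n_vars)
  stopifnot(length(x0) == n_vars, length(X0) == 2L * n_vars,
            all(X0 %in% -1:1))
  sig <- rule_intensities(rules, intensities)
  cond <- lapply(rules, function(r) r$condition)
  cond_flat <- as.integer(unlist(cond))
  cond_off <- c(0L, cumsum(vapply(cond, length, 1L)))
  tgt <- vapply(rules, function(r) r$target, 1L)
  ts <- target_spec_parts(target, n_vars)
  res <- amoeba_run_cpp(as.integer(n_vars), cond_flat, cond_off, tgt, sig,
                        config$p_free, config$p_blocked,
                        config$max_steps, config$stability_window,
                        as.integer(x0), as.integer(X0),
                        ts$type, ts$flat, ts$off, ts$sums,
                        match(stop, c("never", "first", "window")) - 1L,
                        record)
  res$first_target_step <- if (res$first_target_step < 0) NA_integer_
                           else res$first_target_step
  res$first_window_step <- if (res$first_window_step < 0) NA_integer_
                           else res$first_window_step
  if (is.na(res$first_window_step)) res$found <- NULL
  res$n_vars <- as.integer(n_vars)
  res$config <- config
  class(res) <- "amoeba_trajectory"
  res
}

#' @export
print.amoeba_trajectory <- function(x, ...) {
  cat(sprintf("amoeba trajectory: %d vars, %d steps\n", x$n_vars, x$steps))
  cat(sprintf("  first target step: %s\n", format(x$first_target_step)))
  cat(sprintf("  first %d-step persistent target: %s\n",
              x$config$stability_window, format(x$first_window_step)))
  if (!is.null(x$found))
    cat("  found: ", paste(x$found, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Reconstruct per-step decoded assignments from a recorded trajectory
#'
#' @param traj an `amoeba_trajectory` recorded with `record = TRUE`.
#' @param steps 0-based step indices (default all steps).
#' @return integer matrix, one row per requested step.
#' @export
trajectory_assignments <- function(traj, steps = seq_len(traj$steps) - 1L) {
  stopifnot(!is.null(traj$event_steps))
  seg <- findInterval(steps, traj$event_steps)
  stopifnot(all(seg >= 1L))
  traj$event_assignments[seg, , drop = FALSE]
}

#' Distinct assignments observed at stable steps
#'
#' Returns the set of decoded assignments seen at steps where the stability
#' criterion held, one row per distinct assignment (with visit counts).
#'
#' @param traj a recorded `amoeba_trajectory`.
#' @return list with `assignments` (integer matrix) and `steps_stable`
#'   (total number of stable steps).
#' @export
stable_assignments <- function(traj) {
  stopifnot(!is.null(traj$stable))
  idx <- which(traj$stable) - 1L
  if (length(idx) == 0L)
    return(list(assignments = matrix(0L, 0L, traj$n_vars), steps_stable = 0L))
  a <- trajectory_assignments(traj, idx)
  keys <- apply(a, 1L, paste, collapse = "")
  list(assignments = a[!duplicated(keys), , drop = FALSE],
       steps_stable = length(idx))
}

#' Segment a trajectory into metastable visits
#'
#' A visit is a maximal run of a constant, predicate-satisfying decoded
#' assignment lasting at least `window` steps. Dwell time is the run
#' length in steps.
#'
#' @param traj a recorded `amoeba_trajectory`.
#' @param satisfies function taking an integer assignment vector and
#'   returning `TRUE` when it is constraint-satisfying.
#' @param window minimum persistence; defaults to the trajectory config's
#'   stability window.
#' @return data.frame with columns `state` (assignment as a bit string),
#'   `enter_step` (0-based) and `dwell`.
#' @export
trajectory_visits <- function(traj, satisfies,
                              window = traj$config$stability_window) {
  stopifnot(!is.null(traj$event_steps))
  starts <- traj$event_steps
  ends <- c(starts[-1L], traj$steps)  # exclusive
  dwell <- ends - starts
  keep <- dwell >= window
  if (!any(keep))
    return(data.frame(state = character(0), enter_step = integer(0),
                      dwell = integer(0), stringsAsFactors = FALSE))
  idx <- which(keep)
  sat <- vapply(idx, function(k) isTRUE(satisfies(traj$event_assignments[k, ])),
                logical(1))
  idx <- idx[sat]
  data.frame(
    state = apply(traj$event_assignments[idx, , drop = FALSE], 1L,
                  paste, collapse = ""),
    enter_step = starts[idx],
    dwell = dwell[idx],
    stringsAsFactors = FALSE)
}
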