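#' Monte Carlo benchmark of amoeba search against WalkSAT
#'
#' Full factorial instances x algorithms x trials. Every trial gets its
#' own derived seed, so any row of the result can be replayed in
#' isolation. A trial's iteration count is the 0-based step at which the
#' decoded assignment first satisfies the formula (amoeba) or the number
#' of flips used (WalkSAT); censored trials carry the budget value with
#' `solved = FALSE`.
#'
#' @param instances list of `cnf_formula` objects, or `NULL` to generate
#'   `n_instances` satisfiable uniform random 3-SAT instances. For
#'   generated instances with more than 24 variables satisfiability is
#'   established pragmatically by a generous WalkSAT presolve (unsolved
#'   candidates are discarded), which slightly favours easier instances.
#' @param n_vars,n_instances,n_clauses generator settings (defaults: 50
#'   variables at the M = round(4.26 N) phase-transition ratio).
#' @param algorithms subset of `c("amoeba", "walksat")`.
#' @param trials Monte Carlo trials per instance and algorithm.
#' @param budget_amoeba step budget per amoeba trial.
#' @param budget_walksat flip budget per WalkSAT trial.
#' @param config amoeba solver parameters (its `max_steps`/`seed` are
#'   ignored in favour of `budget_amoeba` and per-trial seeds).
#' @param seed master seed for instance generation and the per-trial seed
#'   list.
#' @param presolve_budget WalkSAT flips used to certify satisfiability of
#'   generated instances when brute force is out of reach.
#' @return data.frame with columns `instance`, `algorithm`, `trial`,
#'   `seed`, `solved`, `iterations`; the generated instances are attached
#'   as attribute `"instances"`.
#' @export
run_benchmark <- function(instances = NULL, n_vars = 50L, n_instances = 20L,
                          n_clauses = round(4.26 * n_vars),
                          algorithms = c("amoeba", "walksat"),
                          trials = 100L, budget_amoeba = 100000L,
                          budget_walksat = 1000000L,
                          config = amoeba_config(), seed = NULL,
                          presolve_budget = 2000000L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(instances)) {
    instances <- list()
    while (length(instances) < n_instances) {
      f <- generate_uniform_3sat(n_vars, n_clauses)
      ok <- if (n_vars <= 24L) isTRUE(is_satisfiable(f))
            else walksat_run(f, presolve_budget)$solved
      if (ok) instances[[length(instances) + 1L]] <- f
    }
  } else {
    for (f in instances)
      if (f$n_vars <= 24L && !isTRUE(is_satisfiable(f)))
        stop("benchmark instances must be satisfiable")
  }
  n_cells <- length(instances) * length(algorithms) * trials
  seeds <- sample.int(.Machine$integer.max - 1L, n_cells)
  rows <- vector("list", n_cells)
  k <- 0L
  for (ins in seq_along(instances)) {
    f <- instances[[ins]]
    rules <- compile_bounceback_rules(f)
    tgt <- list(type = "cnf", clauses = f$clauses)
    for (alg in algorithms) for (tr in seq_len(trials)) {
      k <- k + 1L
      s <- seeds[k]
      if (alg == "amoeba") {
        cfg <- config
        cfg$max_steps <- as.integer(budget_amoeba)
        cfg$seed <- s
        traj <- amoeba_run(rules, f$n_vars, cfg, target = tgt,
                           stop = "first", record = FALSE)
        solved <- !is.na(traj$first_target_step)
        iters <- if (solved) traj$first_target_step else budget_amoeba
      } else {
        res <- walksat_run(f, budget_walksat, seed = s)
        solved <- res$solved
        iters <- if (solved) res$flips else budget_walksat
      }
      rows[[k]] <- data.frame(instance = ins, algorithm = alg, trial = tr,
                              seed = s, solved = solved, iterations = iters)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "instances") <- instances
  out
}

#' Summarise a benchmark table per algorithm
#'
#' @param results data.frame from [run_benchmark()].
#' @return data.frame with per-algorithm trial counts, solve rate, and
#'   mean/median iterations (censored trials included at the budget
#'   value).
#' @export
summarize_benchmark <- function(results) {
  algs <- unique(results$algorithm)
  do.call(rbind, lapply(algs, function(a) {
    r <- results[results$algorithm == a, ]
    data.frame(algorithm = a, trials = nrow(r),
               solve_rate = mean(r$solved),
               censored = sum(!r$solved),
               mean_iterations = mean(r$iterations),
               median_iterations = median(r$iterations))
  }))
}

#' Metastable solution-transition statistics on a multi-solution formula
#'
#' Runs long trajectories of the amoeba dynamics (never stopping at a
#' solution), segments each into metastable visits — maximal runs of a
#' constant satisfying assignment lasting at least the stability window —
#' and aggregates dwell times and the matrix of transition counts between
#' consecutive visits. Row-normalising the counts gives empirical
#' transition probabilities between solutions.
#'
#' @param formula a `cnf_formula` with at least two solutions (checked by
#'   the brute-force oracle when feasible).
#' @param config an [amoeba_config()]; `max_steps` is the per-run length.
#' @param intensities intensity map (default binary).
#' @param seeds integer vector, one seed per run.
#' @return object of class `transition_summary`: list with `states`
#'   (solutions as bit strings), `visits` (count of visits per state),
#'   `dwell` (total dwell steps per state), `counts` and `probs`
#'   (transition matrices), `total_steps`.
#' @examples
#' f <- amoeba_demo_formula()
#' ts <- transition_analysis(f, amoeba_config(max_steps = 20000), seeds = 1:2)
#' ts$counts
#' @export
transition_analysis <- function(formula, config = amoeba_config(),
                                intensities = 1.0, seeds = 1:10) {
  if (formula$n_vars <= 24L) {
    sols <- brute_force_solutions(formula)
    if (nrow(sols) < 2L)
      stop("transition analysis needs a formula with >= 2 solutions")
    states <- sort(apply(sols, 1L, paste, collapse = ""))
  } else states <- NULL
  rules <- compile_bounceback_rules(formula)
  sat_fun <- function(x) sat_verify(formula, x)
  all_visits <- list()
  for (s in seeds) {
    cfg <- config; cfg$seed <- as.integer(s)
    traj <- amoeba_run(rules, formula$n_vars, cfg, intensities,
                       target = list(type = "cnf", clauses = formula$clauses),
                       stop = "never", record = TRUE)
    vis <- trajectory_visits(traj, sat_fun)
    vis$run <- s
    all_visits[[length(all_visits) + 1L]] <- vis
  }
  vis <- do.call(rbind, all_visits)
  if (is.null(states)) states <- sort(unique(vis$state))
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(states, states))
  for (run in unique(vis$run)) {
    v <- vis$state[vis$run == run]
    if (length(v) > 1L) for (r in seq_len(length(v) - 1L))
      counts[v[r], v[r + 1L]] <- counts[v[r], v[r + 1L]] + 1L
  }
  dep <- rowSums(counts)
  probs <- counts / ifelse(dep > 0L, dep, 1L)
  structure(list(
    states = states,
    visits = vapply(states, function(st) sum(vis$state == st), 1L),
    dwell = vapply(states, function(st) sum(vis$dwell[vis$state == st]), 1),
    counts = counts, probs = probs,
    total_steps = config$max_steps * length(seeds)),
    class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("metastable transition summary over", x$total_steps, "steps\n")
  cat("visits per solution:\n")
  for (st in x$states)
    cat(sprintf("  %s  visits %6d  dwell %10.0f\n",
                st, x$visits[[st]], x$dwell[[st]]))
  cat("transition counts:\n")
  print(x$counts)
  invisible(x)
}
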