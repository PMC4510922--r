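#' One WalkSAT step
#'
#' The pure random-walk variant: pick one unsatisfied clause uniformly at
#' random, pick one of its variables uniformly at random, and flip it. If
#' the assignment already satisfies the formula the state is returned
#' unchanged with attribute `noop = TRUE`.
#'
#' @param formula a `cnf_formula`.
#' @param state list with `assignment` (integer 0/1 vector) and `flips`
#'   (non-negative integer), as produced by [walksat_init()].
#' @return updated state; exactly one bit differs unless `noop`.
#' @export
walksat_step <- function(formula, state) {
  unsat <- which(!vapply(formula$clauses, function(cl)
    any((cl > 0L) == (state$assignment[abs(cl)] == 1L)), logical(1)))
  if (length(unsat) == 0L) {
    attr(state, "noop") <- TRUE
    return(state)
  }
  cl <- formula$clauses[[unsat[sample.int(length(unsat), 1L)]]]
  v <- abs(cl[sample.int(length(cl), 1L)])
  state$assignment[v] <- 1L - state$assignment[v]
  state$flips <- state$flips + 1L
  attr(state, "noop") <- FALSE
  state
}

#' Initial WalkSAT state with a uniform random assignment
#'
#' @param n_vars number of variables.
#' @return list with `assignment` and `flips = 0`.
#' @export
walksat_init <- function(n_vars) {
  list(assignment = as.integer(runif(n_vars) < 0.5), flips = 0L)
}

#' Run WalkSAT to a solution or a flip budget
#'
#' Starts from a uniform random assignment and iterates the pure
#' random-walk step. `greedy_p > 0` mixes in classic break-count-greedy
#' variable picks with that probability (disabled by default: the baseline
#' is the pure walk).
#'
#' @param formula a `cnf_formula`.
#' @param max_flips flip budget (at least 1).
#' @param seed optional seed.
#' @param greedy_p probability of a greedy (minimum break count) pick.
#' @return list with `solved`, `flips` (flips used; equals the budget when
#'   censored) and `assignment`. A reported solution always passes
#'   [sat_verify()].
#' @examples
#' f <- amoeba_demo_formula()
#' walksat_run(f, max_flips = 10000, seed = 1)$solved
#' @export
walksat_run <- function(formula, max_flips, seed = NULL, greedy_p = 0) {
  stopifnot(max_flips >= 1)
  if (!is.null(seed)) set.seed(seed)
  x0 <- as.integer(runif(formula$n_vars) < 0.5)
  cl <- formula$clauses
  res <- walksat_run_cpp(formula$n_vars, as.integer(unlist(cl)),
                         c(0L, cumsum(vapply(cl, length, 1L))),
                         as.integer(max_flips), x0, greedy_p)
  if (res$solved) stopifnot(sat_verify(formula, res$assignment))
  res
}
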