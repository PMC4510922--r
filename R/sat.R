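#' Construct a CNF formula
#'
#' Clauses are integer vectors of signed DIMACS-style literals: `3` means
#' \eqn{x_3}, `-3` means \eqn{\neg x_3}.
#'
#' @param n_vars number of variables N.
#' @param clauses list of non-empty integer vectors of signed literals with
#'   absolute values in `1..n_vars`.
#' @return an object of class `cnf_formula`.
#' @export
cnf_formula <- function(n_vars, clauses) {
  n_vars <- as.integer(n_vars)
  clauses <- lapply(clauses, as.integer)
  for (cl in clauses) {
    if (length(cl) == 0L) stop("empty clause")
    if (any(cl == 0L) || any(abs(cl) > n_vars))
      stop("literal out of range 1..", n_vars)
    if (anyDuplicated(abs(cl))) stop("duplicate variable within a clause")
  }
  structure(list(n_vars = n_vars, clauses = clauses), class = "cnf_formula")
}

#' @export
print.cnf_formula <- function(x, ...) {
  cat(sprintf("CNF formula: %d variables, %d clauses\n",
              x$n_vars, length(x$clauses)))
  invisible(x)
}

#' A small worked SAT instance with three solutions
#'
#' A 4-variable, 9-clause 3-CNF instance whose satisfying assignments are
#' exactly (1,1,1,1), (1,1,1,0) and (0,1,1,0). Because its solutions sit at
#' Hamming distances 1 and 2 from each other it is a convenient test bed
#' for metastable-transition statistics.
#'
#' @return a `cnf_formula`.
#' @examples
#' f <- amoeba_demo_formula()
#' brute_force_solutions(f)
#' @export
amoeba_demo_formula <- function() {
  cnf_formula(4L, list(
    c(-1L, 3L, -4L), c(1L, -2L, 3L), c(1L, 2L, 3L),
    c(1L, 2L, 4L), c(1L, -3L, -4L), c(-2L, 3L, 4L),
    c(2L, -3L, -4L), c(2L, -3L, 4L), c(2L, 3L, 4L)))
}

#' Read a DIMACS CNF file
#'
#' Accepts the standard dialect: optional `c` comment lines, a
#' `p cnf N M` header, then whitespace-separated signed literals with each
#' clause terminated by `0` (clauses may span lines). Duplicate literals
#' within a clause are dropped; a clause containing both a literal and its
#' negation is a tautology and is removed with a warning.
#'
#' @param path file path, or a character vector of lines when `text = TRUE`.
#' @param text logical; treat `path` as literal text.
#' @return a `cnf_formula`.
#' @export
parse_dimacs <- function(path, text = FALSE) {
  lines <- if (text) unlist(strsplit(path, "\n", fixed = TRUE))
           else readLines(path, warn = FALSE)
  n_vars <- NA_integer_; n_clauses <- NA_integer_
  clauses <- list(); cur <- integer(0)
  for (ln in seq_along(lines)) {
    s <- trimws(lines[[ln]])
    if (s == "" || startsWith(s, "c") || startsWith(s, "%")) next
    if (startsWith(s, "p")) {
      m <- strsplit(s, "\\s+")[[1]]
      if (length(m) != 4L || m[2] != "cnf")
        stop("malformed DIMACS header at line ", ln, ": ", s)
      n_vars <- as.integer(m[3]); n_clauses <- as.integer(m[4])
      next
    }
    if (is.na(n_vars)) stop("clause before 'p cnf' header at line ", ln)
    toks <- suppressWarnings(as.integer(strsplit(s, "\\s+")[[1]]))
    if (anyNA(toks)) stop("non-integer token at line ", ln, ": ", s)
    for (tk in toks) {
      if (tk == 0L) {
        if (length(cur) == 0L) stop("empty clause at line ", ln)
        if (any(abs(cur) > n_vars))
          stop("literal index exceeds declared variable count at line ", ln)
        cur <- unique(cur)
        if (any(cur %in% -cur)) {
          warning("tautological clause dropped at line ", ln)
        } else clauses[[length(clauses) + 1L]] <- cur
        cur <- integer(0)
      } else cur <- c(cur, tk)
    }
  }
  if (length(cur) > 0L) stop("unterminated clause at end of file (missing 0)")
  if (is.na(n_vars)) stop("no 'p cnf' header found")
  cnf_formula(n_vars, clauses)
}

#' Write a formula in DIMACS CNF format
#'
#' @param formula a `cnf_formula`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dimacs <- function(formula, path) {
  lines <- c(sprintf("p cnf %d %d", formula$n_vars, length(formula$clauses)),
             vapply(formula$clauses,
                    function(cl) paste(c(cl, 0L), collapse = " "), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Compile a CNF formula into bounceback rules
#'
#' For each clause and each literal \eqn{\ell} in it, one `CLAUSE` rule is
#' emitted whose condition is the set of units asserting that every *other*
#' literal of the clause is violated, and whose target is the unit that
#' would violate \eqn{\ell} itself: when all other literals have failed,
#' the last variable is pushed away from breaking the clause. Unit clauses
#' yield an unconditional (empty-condition) block on their violating unit.
#' With `include_contra`, each variable additionally gets the two mutual
#' suppression rules \eqn{\{(i,v)\} \Rightarrow (i, 1-v)} of type `CONTRA`,
#' which drive opposing units apart so the decoded assignment can commit.
#'
#' @param formula a `cnf_formula`.
#' @param include_contra logical; emit the 2N `CONTRA` rules (default TRUE).
#' @return list of [bounceback_rule()]s.
#' @examples
#' f <- cnf_formula(4, list(c(-1, 3, -4)))
#' compile_bounceback_rules(f, include_contra = FALSE)
#' @export
compile_bounceback_rules <- function(formula, include_contra = TRUE) {
  rules <- list()
  for (cl in formula$clauses) {
    vars <- abs(cl)
    want <- as.integer(cl > 0L)           # value making each literal true
    viol <- unit_index(vars, 1L - want)   # unit asserting literal violated
    for (k in seq_along(cl)) {
      rules[[length(rules) + 1L]] <-
        bounceback_rule(viol[-k], viol[k], "CLAUSE")
    }
  }
  if (include_contra) {
    for (i in seq_len(formula$n_vars)) for (v in c(0L, 1L)) {
      rules[[length(rules) + 1L]] <-
        bounceback_rule(unit_index(i, v), unit_index(i, 1L - v), "CONTRA")
    }
  }
  rules
}

#' Evaluate an assignment against a formula
#'
#' @param formula a `cnf_formula`.
#' @param assignment integer 0/1 vector of length `n_vars`.
#' @return `TRUE` iff every clause contains at least one satisfied literal
#'   (an empty conjunction is `TRUE`).
#' @export
sat_verify <- function(formula, assignment) {
  stopifnot(length(assignment) == formula$n_vars,
            all(assignment %in% c(0L, 1L)))
  for (cl in formula$clauses) {
    if (!any((cl > 0L) == (assignment[abs(cl)] == 1L))) return(FALSE)
  }
  TRUE
}

bit_matrix <- function(codes, n_vars) {
  out <- matrix(0L, length(codes), n_vars)
  for (i in seq_len(n_vars))
    out[, i] <- as.integer(bitwAnd(codes, bitwShiftL(1L, i - 1L)) != 0L)
  out
}

satisfied_rows <- function(formula, bits) {
  ok <- rep(TRUE, nrow(bits))
  for (cl in formula$clauses) {
    cl_ok <- rep(FALSE, nrow(bits))
    for (lit in cl)
      cl_ok <- cl_ok | (bits[, abs(lit)] == as.integer(lit > 0L))
    ok <- ok & cl_ok
  }
  ok
}

#' Enumerate all satisfying assignments by brute force
#'
#' Exhaustive oracle over all \eqn{2^N} assignments, intended for small
#' instances (guarded at N <= 24, evaluated in blocks).
#'
#' @param formula a `cnf_formula` with `n_vars <= 24`.
#' @param first_only logical; stop at the first block containing a solution
#'   (satisfiability check rather than full enumeration).
#' @return integer 0/1 matrix with one satisfying assignment per row
#'   (columns = variables, in increasing variable order of the low bits).
#' @examples
#' brute_force_solutions(amoeba_demo_formula())
#' @export
brute_force_solutions <- function(formula, first_only = FALSE) {
  n <- formula$n_vars
  if (n > 24L) stop("brute force limited to n_vars <= 24 (got ", n, ")")
  total <- 2^n
  block <- as.integer(min(total, 65536))
  sols <- list()
  start <- 0
  while (start < total) {
    codes <- as.integer(seq(start, min(start + block, total) - 1))
    bits <- bit_matrix(codes, n)
    hit <- satisfied_rows(formula, bits)
    if (any(hit)) {
      sols[[length(sols) + 1L]] <- bits[hit, , drop = FALSE]
      if (first_only) break
    }
    start <- start + block
  }
  if (length(sols) == 0L) matrix(0L, 0L, n) else do.call(rbind, sols)
}

is_satisfiable <- function(formula) {
  if (formula$n_vars <= 24L)
    nrow(brute_force_solutions(formula, first_only = TRUE)) > 0L
  else NA
}

#' Generate a uniform random 3-SAT instance
#'
#' Each clause draws 3 distinct variables uniformly and gives each a
#' uniform random polarity, emulating the uniform random 3-SAT benchmark
#' class. The default clause count sits at the satisfiability phase
#' transition ratio M/N = 4.26.
#'
#' @param n_vars number of variables (at least 3).
#' @param n_clauses number of clauses; default `round(4.26 * n_vars)`.
#' @param require_satisfiable logical; rejection-sample until the instance
#'   is satisfiable. Guaranteed (by the brute-force oracle) only for
#'   `n_vars <= 24`; for larger instances the guarantee is skipped with a
#'   message (use [walksat_run()] as a pragmatic presolve filter instead).
#' @param seed optional seed.
#' @return a `cnf_formula`.
#' @export
generate_uniform_3sat <- function(n_vars, n_clauses = round(4.26 * n_vars),
                                  require_satisfiable = FALSE, seed = NULL) {
  stopifnot(n_vars >= 3L)
  if (!is.null(seed)) set.seed(seed)
  gen <- function() {
    cls <- lapply(seq_len(n_clauses), function(j) {
      vars <- sample.int(n_vars, 3L)
      signs <- sample(c(-1L, 1L), 3L, replace = TRUE)
      vars * signs
    })
    cnf_formula(n_vars, cls)
  }
  f <- gen()
  if (require_satisfiable) {
    if (n_vars > 24L) {
      message("n_vars > 24: satisfiability not verified for generated instance")
    } else {
      while (!isTRUE(is_satisfiable(f))) f <- gen()
    }
  }
  f
}

#' Format an assignment as a bit string or DIMACS v-line
#'
#' @param assignment integer 0/1 vector.
#' @return `assignment_string()` gives e.g. `"1110"`; `dimacs_v_line()`
#'   gives e.g. `"v 1 2 3 -4 0"`.
#' @export
assignment_string <- function(assignment) paste(assignment, collapse = "")

#' @rdname assignment_string
#' @export
dimacs_v_line <- function(assignment) {
  lits <- ifelse(assignment == 1L, seq_along(assignment), -seq_along(assignment))
  paste("v", paste(lits, collapse = " "), "0")
}

#' Solve a SAT instance with the amoeba dynamics
#'
#' Compiles the formula into bounceback rules and runs the concurrent
#' stochastic dynamics until the decoded assignment satisfies the formula
#' or the step budget is exhausted.
#'
#' @param formula a `cnf_formula`.
#' @param config an [amoeba_config()].
#' @param intensities scalar or type-named intensity map (default: binary
#'   blocking, intensity 1 for all rule types).
#' @param include_contra include the `CONTRA` mutual-suppression rules.
#' @param record keep the full trajectory record.
#' @return list with `solved`, `assignment`, `steps` (0-based first
#'   satisfying step; `NA` when censored at the budget) and `trajectory`.
#' @examples
#' f <- amoeba_demo_formula()
#' res <- amoeba_sat(f, amoeba_config(max_steps = 5000, seed = 42))
#' res$solved
#' @export
amoeba_sat <- function(formula, config = amoeba_config(),
                       intensities = 1.0, include_contra = TRUE,
                       record = FALSE) {
  rules <- compile_bounceback_rules(formula, include_contra)
  traj <- amoeba_run(rules, formula$n_vars, config, intensities,
                     target = list(type = "cnf", clauses = formula$clauses),
                     stop = "first", record = record)
  solved <- !is.na(traj$first_target_step)
  assignment <- if (solved) traj$x_final else NULL
  if (solved) stopifnot(sat_verify(formula, assignment))
  list(solved = solved, assignment = assignment,
       steps = traj$first_target_step, trajectory = traj)
}
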