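# Shared fixtures: all built in code at test time.

demo_f <- amoeba_demo_formula()
demo_solutions <- c("0110", "1110", "1111")

# Clean committed unit state expressing an assignment: the adopted unit of
# each variable at 1, its opponent at -1.
clean_X <- function(assignment) {
  n <- length(assignment)
  X <- rep(-1L, 2L * n)
  X[unit_index(seq_len(n), assignment)] <- 1L
  X
}

bits <- function(s) as.integer(strsplit(s, "")[[1]])

# Independent clause-by-clause evaluator used as an oracle for sat_verify.
verify_oracle <- function(formula, x) {
  for (cl in formula$clauses) {
    ok <- FALSE
    for (lit in cl) {
      v <- abs(lit)
      if ((lit > 0 && x[v] == 1) || (lit < 0 && x[v] == 0)) ok <- TRUE
    }
    if (!ok) return(FALSE)
  }
  TRUE
}
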