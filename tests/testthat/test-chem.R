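test_that("atom multisets parse from strings and reject unsupported elements", {
  expect_equal(parse_atoms("N:2,H:6"), c(N = 2L, H = 6L))
  expect_equal(parse_atoms(c(H = 2)), c(H = 2L))
  expect_error(parse_atoms("Xx:1"), "unsupported element")
  expect_error(parse_atoms("N:a"), "malformed")
})

test_that("bond systems enumerate slots as pairs times capped bond order", {
  sys <- bond_system(c(N = 2, H = 6))
  # 3 N-N slots + 12 N-H + 15 H-H = 30 slots, 60 units
  expect_equal(sys$n_slots, 30L)
  nn <- sys$slots[sys$slots$a == 1 & sys$slots$b == 2, ]
  expect_equal(nrow(nn), 3L)
  expect_equal(nn$slot_index, 1:3)
  hh <- sys$slots[sys$slots$a > 2, ]
  expect_equal(nrow(hh), 15L)

  expect_equal(bond_system(c(H = 2))$n_slots, 1L)
  expect_error(bond_system(c(H = 1)), "at least 2")
})

test_that("octet rule compilation produces the expected rule families and counts", {
  sys <- bond_system(c(N = 2, H = 6))
  rules <- compile_chem_rules(sys)
  types <- vapply(rules, function(r) r$type, "")
  # each N: C(9,4)*4 excess, C(9,7)*7 deficit; each H (7 slots, valence 1):
  # C(7,2)*2 = 42 excess, C(7,7)*7 = 7 deficit
  expect_equal(sum(types == "OCTET_EXCESS"), 2L * 504L + 6L * 42L)
  expect_equal(sum(types == "OCTET_DEFICIT"), 2L * 252L + 6L * 7L)
  expect_equal(sum(types == "SLOT_ORDER"), 3L)   # N-N slot pairs only
  expect_equal(sum(types == "CONTRA"), 60L)

  # 2 H: a single slot cannot exceed valence 1, but is forced on
  sys2 <- bond_system(c(H = 2))
  rules2 <- compile_chem_rules(sys2)
  t2 <- vapply(rules2, function(r) r$type, "")
  expect_equal(sum(t2 == "OCTET_EXCESS"), 0L)
  def <- rules2[t2 == "OCTET_DEFICIT"]
  expect_length(def, 2L)                           # one force per H atom
  for (r in def) {
    expect_length(r$condition, 0L)                 # unconditional force
    expect_equal(r$target, unit_index(1, 0))
  }
})

test_that("molecule decoding conserves atoms and labels compositions", {
  sys <- bond_system(c(N = 2, H = 6))
  # triple N-N bond plus three disjoint H-H bonds
  x_fig2 <- realize_composition(sys, "3xH2 + N2")
  expect_equal(decode_molecules(sys, x_fig2), c(H2 = 3L, N2 = 1L))
  bt <- bond_table(sys, x_fig2)
  expect_equal(bt[1, 2], 3L)                       # N#N
  expect_equal(sum(bt) / 2, 6L)                    # 6 bonds in total

  x_fig3 <- realize_composition(sys, "2xH3N")
  expect_equal(decode_molecules(sys, x_fig3), c(H3N = 2L))

  expect_equal(decode_molecules(sys, rep(0L, 30)), c(H = 6L, N = 2L))

  # conservation under random assignments
  set.seed(12)
  for (rep in 1:25) {
    a <- sample(0:1, 30, replace = TRUE)
    comp <- decode_molecules(sys, a)
    # count atoms element-wise by expanding each formula
    counts <- c(H = 0L, N = 0L)
    for (k in seq_along(comp)) {
      f <- names(comp)[k]
      for (mm in regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]) {
        el <- gsub("[0-9]", "", mm)
        n <- suppressWarnings(as.integer(gsub("[^0-9]", "", mm)))
        if (is.na(n)) n <- 1L
        counts[el] <- counts[el] + n * comp[k]
      }
    }
    expect_equal(counts, c(H = 6L, N = 2L))
  }
})

test_that("the backtracking oracle finds exactly the valid compositions", {
  cs <- enumerate_valid_compositions(bond_system(c(N = 2, H = 6)))
  expect_setequal(cs$labels,
                  c("3xH2 + N2", "2xH2 + H2N2", "H2 + H4N2", "2xH3N"))
  # representatives decode to their own composition
  for (k in seq_along(cs$labels))
    expect_equal(composition_label(
      decode_molecules(bond_system(c(N = 2, H = 6)), cs$assignments[k, ])),
      cs$labels[k])

  expect_equal(enumerate_valid_compositions(bond_system(c(H = 2)))$labels, "H2")
  expect_setequal(enumerate_valid_compositions(bond_system(c(N = 2, H = 4)))$labels,
                  c("2xH2 + N2", "H2 + H2N2", "H4N2"))
})

test_that("valence-complete tables are stable and violating ones are not", {
  sys <- bond_system(c(N = 2, H = 6))
  rules <- compile_chem_rules(sys)
  for (lab in c("3xH2 + N2", "2xH3N")) {
    a <- realize_composition(sys, lab)
    X <- clean_X(a)
    s <- compute_signals(X, rules, 1.0)
    expect_true(is_stable(X, s))
  }
  # all bonds off: every atom under-bonded
  X0 <- clean_X(rep(0L, 30))
  expect_false(is_stable(X0, compute_signals(X0, rules, 1.0)))
  # over-bonded: N#N plus an extra N-H on each side of the fig-2 table
  a <- realize_composition(sys, "3xH2 + N2")
  free_nh <- which(sys$slots$a <= 2 & sys$slots$b > 2 & a == 0L)[1]
  a2 <- a; a2[free_nh] <- 1L
  X2 <- clean_X(a2)
  expect_false(is_stable(X2, compute_signals(X2, rules, 1.0)))
})

test_that("unrealizable compositions are rejected", {
  sys <- bond_system(c(N = 2, H = 4))
  expect_error(realize_composition(sys, "2xH3N"), "not realizable")
})

test_that("Monte Carlo chemistry stays within the oracle support", {
  sys <- bond_system(c(H = 4))
  res <- run_chem(sys, config = amoeba_config(max_steps = 2000, seed = 13),
                  trials = 30)
  found <- names(res$counts)[res$counts > 0]
  expect_true(all(found %in% c(res$labels, "(censored)")))
  expect_equal(sum(res$counts), 30L)
  # starting exactly at a valence-complete composition with binary blocking
  sys2 <- bond_system(c(H = 2))
  r2 <- run_chem(sys2, intensities = 1.0,
                 config = amoeba_config(max_steps = 500, seed = 14),
                 init = c(H2 = 1), trials = 20)
  expect_gt(r2$freq[["H2"]], 0.8)
})

test_that("transition logging aggregates dwell and composition moves", {
  sys <- bond_system(c(N = 2, H = 4))
  res <- run_chem(sys, chem_intensity_sets()$hot,
                  config = amoeba_config(max_steps = 3000, seed = 15),
                  init = c(H2 = 2, N2 = 1), trials = 10, transitions = TRUE)
  expect_true(all(rownames(res$transitions) == res$labels))
  expect_true(sum(res$dwell) > 0)
  expect_true(sum(res$transitions) >= 0)
  expect_equal(sum(res$counts), 10L)
})
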