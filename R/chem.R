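VALENCE <- c(H = 1L, C = 4L, N = 3L, O = 2L)

#' Parse an atom multiset
#'
#' @param x either a named integer vector like `c(N = 2, H = 6)` or a
#'   string like `"N:2,H:6"`.
#' @return named integer vector of element counts.
#' @export
parse_atoms <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    parts <- strsplit(trimws(strsplit(x, ",")[[1]]), ":")
    el <- vapply(parts, `[`, "", 1L)
    ct <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    if (anyNA(ct)) stop("malformed atom multiset: ", x)
    x <- setNames(ct, trimws(el))
  }
  x <- setNames(as.integer(x), names(x))
  bad <- setdiff(names(x), names(VALENCE))
  if (length(bad) > 0L)
    stop("unsupported element(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(names(VALENCE), collapse = ", "), ")")
  if (any(x < 0L) || sum(x) < 1L) stop("atom counts must be non-negative")
  x[x > 0L]
}

#' Build the bond-slot system for an atom multiset
#'
#' Every unordered atom pair gets `min(valence_a, valence_b, 3)` bond
#' slots; each slot is one potential unit-order bond, so multiple slots on
#' the same pair encode double and triple bonds. Each slot maps to one
#' SAT-style variable (with its paired 0/1 units), letting the core
#' dynamics run unchanged on chemistry. Ordering is deterministic: atoms
#' in input order, pairs lexicographic, slot indices ascending.
#'
#' @param atoms an atom multiset accepted by [parse_atoms()], with at
#'   least two atoms.
#' @return an object of class `bond_system`: list with `atoms`
#'   (data.frame: atom_id, element, valence), `slots` (data.frame: var,
#'   a, b, slot_index) and `n_slots`.
#' @examples
#' sys <- bond_system(c(N = 2, H = 6))
#' sys$n_slots  # 30 slots, hence 60 units
#' @export
bond_system <- function(atoms) {
  atoms <- parse_atoms(atoms)
  el <- rep(names(atoms), atoms)
  n <- length(el)
  if (n < 2L) stop("need at least 2 atoms")
  at <- data.frame(atom_id = seq_len(n), element = el,
                   valence = unname(VALENCE[el]), stringsAsFactors = FALSE)
  rows <- list()
  var <- 0L
  for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
    mo <- min(at$valence[a], at$valence[b], 3L)
    for (k in seq_len(mo)) {
      var <- var + 1L
      rows[[var]] <- data.frame(var = var, a = a, b = b, slot_index = k)
    }
  }
  structure(list(atoms = at, slots = do.call(rbind, rows), n_slots = var),
            class = "bond_system")
}

#' @export
print.bond_system <- function(x, ...) {
  cat(sprintf("bond system: %d atoms (%s), %d slots (%d units)\n",
              nrow(x$atoms),
              paste(sprintf("%s:%d", names(table(x$atoms$element)),
                            as.integer(table(x$atoms$element))),
                    collapse = ", "),
              x$n_slots, 2L * x$n_slots))
  invisible(x)
}

incident_slots <- function(system, atom_id) {
  system$slots$var[system$slots$a == atom_id | system$slots$b == atom_id]
}

#' Compile octet-rule bounceback rules for a bond system
#'
#' Four rule families render the exact-valence (octet) constraint:
#' \describe{
#'   \item{OCTET_EXCESS}{for each atom with valence v, every (v+1)-subset
#'     of its incident slots blocks each member's "bond on" unit when the
#'     other v are on: bonds are capped at the valence.}
#'   \item{OCTET_DEFICIT}{dually, once an atom has only just enough
#'     undecided slots left to reach its valence, their "bond off" units
#'     are blocked: bonds are forced up to the valence. When an atom's
#'     slot count equals its valence this degenerates to an unconditional
#'     (empty-condition) block forcing every incident bond.}
#'   \item{SLOT_ORDER}{within a pair, a higher-order slot is blocked while
#'     a lower one is off, collapsing states that differ only by which
#'     slot carries a given bond order (symmetry breaking; optional).}
#'   \item{CONTRA}{per-slot mutual suppression of the paired 0/1 units,
#'     as in the SAT frontend.}
#' }
#'
#' @param system a [bond_system()].
#' @param include_contra emit `CONTRA` rules (default TRUE).
#' @param slot_order emit `SLOT_ORDER` symmetry-breaking rules (default
#'   TRUE; disable for fidelity experiments).
#' @return list of [bounceback_rule()]s.
#' @export
compile_chem_rules <- function(system, include_contra = TRUE,
                               slot_order = TRUE) {
  rules <- list()
  add <- function(cond, target, type)
    rules[[length(rules) + 1L]] <<- bounceback_rule(cond, target, type)
  for (a in system$atoms$atom_id) {
    inc <- incident_slots(system, a)
    v <- system$atoms$valence[a]
    if (length(inc) > 16L)
      stop("atom ", a, " has ", length(inc),
           " incident slots; refusing subset enumeration beyond 16")
    if (length(inc) >= v + 1L) {
      subs <- combn(inc, v + 1L)
      for (j in seq_len(ncol(subs))) {
        T_ <- subs[, j]
        for (i in T_)
          add(unit_index(setdiff(T_, i), 1L), unit_index(i, 1L),
              "OCTET_EXCESS")
      }
    }
    k <- length(inc) - v + 1L
    if (k >= 1L) {
      subs <- combn(inc, k)
      for (j in seq_len(ncol(subs))) {
        U <- subs[, j]
        for (i in U)
          add(unit_index(setdiff(U, i), 0L), unit_index(i, 0L),
              "OCTET_DEFICIT")
      }
    }
  }
  if (slot_order) {
    sl <- system$slots
    for (key in unique(paste(sl$a, sl$b))) {
      vars <- sl$var[paste(sl$a, sl$b) == key]
      if (length(vars) > 1L) {
        for (i in seq_len(length(vars) - 1L)) for (j in seq((i + 1L), length(vars)))
          add(unit_index(vars[i], 0L), unit_index(vars[j], 1L), "SLOT_ORDER")
      }
    }
  }
  if (include_contra) {
    for (i in seq_len(system$n_slots)) for (v in c(0L, 1L))
      add(unit_index(i, v), unit_index(i, 1L - v), "CONTRA")
  }
  rules
}

hill_formula <- function(elements) {
  counts <- table(elements)
  els <- names(counts)
  ord <- if ("C" %in% els) c("C", "H", sort(setdiff(els, c("C", "H"))))
         else sort(els)
  ord <- ord[ord %in% els]
  paste0(ord, ifelse(counts[ord] > 1L, counts[ord], ""), collapse = "")
}

#' Decode a slot assignment into a molecular composition
#'
#' Atoms joined by at least one active slot form a molecule (connected
#' component); each component is reported as a Hill-notation formula and
#' the result is the multiset of formulas. Note Hill notation sorts
#' carbon-free formulas alphabetically, so ammonia reads `H3N`.
#'
#' @param system a [bond_system()].
#' @param assignment integer 0/1 vector over slot variables.
#' @return named integer vector: formula -> molecule count (sorted by
#'   formula).
#' @examples
#' sys <- bond_system(c(H = 2))
#' decode_molecules(sys, 1L)  # c(H2 = 1)
#' @export
decode_molecules <- function(system, assignment) {
  stopifnot(length(assignment) == system$n_slots)
  n <- nrow(system$atoms)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  on <- which(assignment == 1L)
  for (k in on) {
    ra <- find(system$slots$a[k]); rb <- find(system$slots$b[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, 1L)
  comps <- split(system$atoms$element, roots)
  formulas <- vapply(comps, hill_formula, "")
  tab <- table(formulas)
  setNames(as.integer(tab), names(tab))
}

#' Bond-order table of a slot assignment
#'
#' The atoms-by-atoms grid of bond orders (count of active slots per
#' pair), mirroring the tabular layout in which bonding states are usually
#' displayed.
#'
#' @param system a [bond_system()].
#' @param assignment integer 0/1 vector over slots.
#' @return symmetric integer matrix with element labels.
#' @export
bond_table <- function(system, assignment) {
  n <- nrow(system$atoms)
  m <- matrix(0L, n, n,
              dimnames = list(paste0(system$atoms$element, system$atoms$atom_id),
                              paste0(system$atoms$element, system$atoms$atom_id)))
  on <- which(assignment == 1L)
  for (k in on) {
    a <- system$slots$a[k]; b <- system$slots$b[k]
    m[a, b] <- m[a, b] + 1L; m[b, a] <- m[b, a] + 1L
  }
  m
}

#' Label a molecular composition
#'
#' @param composition named integer vector as returned by
#'   [decode_molecules()].
#' @return single string like `"3xH2 + N2"`.
#' @export
composition_label <- function(composition) {
  composition <- composition[sort(names(composition))]
  paste(ifelse(composition > 1L,
               paste0(composition, "x", names(composition)),
               names(composition)),
        collapse = " + ")
}

#' Enumerate all valence-complete compositions of a bond system
#'
#' Backtracking oracle over the slot variables: finds every assignment in
#' which each atom's bond count equals its valence, pruned by remaining
#' capacity and canonicalised within pairs (a higher slot is only used on
#' top of lower ones), then reduced to distinct formula multisets.
#'
#' @param system a [bond_system()] with at most 12 atoms.
#' @return object of class `composition_set`: list with `labels`,
#'   `compositions` (list of named integer vectors) and `assignments`
#'   (one representative 0/1 slot assignment per composition, as rows).
#' @examples
#' enumerate_valid_compositions(bond_system(c(H = 2)))$labels
#' @export
enumerate_valid_compositions <- function(system) {
  if (nrow(system$atoms) > 12L)
    stop("enumeration limited to 12 atoms (got ", nrow(system$atoms), ")")
  ns <- system$n_slots
  sl <- system$slots
  val <- system$atoms$valence
  n_atoms <- nrow(system$atoms)
  # remaining undecided incident slots per atom, counted from slot k on
  inc_after <- matrix(0L, ns + 1L, n_atoms)
  for (k in rev(seq_len(ns))) {
    inc_after[k, ] <- inc_after[k + 1L, ]
    inc_after[k, sl$a[k]] <- inc_after[k, sl$a[k]] + 1L
    inc_after[k, sl$b[k]] <- inc_after[k, sl$b[k]] + 1L
  }
  found <- new.env(parent = emptyenv())
  assignment <- integer(ns)
  deg <- integer(n_atoms)
  recurse <- function(k) {
    if (k > ns) {
      comp <- decode_molecules(system, assignment)
      lab <- composition_label(comp)
      if (is.null(found[[lab]]))
        found[[lab]] <- list(composition = comp, assignment = assignment)
      return(invisible(NULL))
    }
    a <- sl$a[k]; b <- sl$b[k]
    for (bit in c(0L, 1L)) {
      if (bit == 1L) {
        if (deg[a] >= val[a] || deg[b] >= val[b]) next
        # canonical slot use: slot j > 1 only on top of slot j - 1
        if (sl$slot_index[k] > 1L && assignment[k - 1L] == 0L) next
      }
      assignment[k] <<- bit
      if (bit == 1L) { deg[a] <<- deg[a] + 1L; deg[b] <<- deg[b] + 1L }
      # feasibility: every atom must still be able to reach its valence
      ok <- all(deg + inc_after[k + 1L, ] >= val)
      if (ok) recurse(k + 1L)
      if (bit == 1L) { deg[a] <<- deg[a] - 1L; deg[b] <<- deg[b] - 1L }
    }
    assignment[k] <<- 0L
    invisible(NULL)
  }
  recurse(1L)
  labs <- sort(ls(found))
  structure(list(
    labels = labs,
    compositions = lapply(labs, function(l) found[[l]]$composition),
    assignments = if (length(labs) == 0L) matrix(0L, 0L, ns)
                  else do.call(rbind, lapply(labs, function(l) found[[l]]$assignment))),
    class = "composition_set")
}

#' @export
print.composition_set <- function(x, ...) {
  cat("valid compositions (", length(x$labels), "):\n", sep = "")
  for (l in x$labels) cat("  ", l, "\n", sep = "")
  invisible(x)
}

#' Realize a composition as a slot assignment
#'
#' @param system a [bond_system()].
#' @param composition named integer vector (formula -> count) or a
#'   composition label string.
#' @return integer 0/1 slot assignment decoding to the composition.
#' @export
realize_composition <- function(system, composition) {
  lab <- if (is.character(composition) && is.null(names(composition)))
    composition else composition_label(composition)
  cs <- enumerate_valid_compositions(system)
  k <- match(lab, cs$labels)
  if (is.na(k))
    stop("composition '", lab, "' is not realizable on this system; valid: ",
         paste(cs$labels, collapse = "; "))
  cs$assignments[k, ]
}

#' Named default intensity parameter sets
#'
#' Two contrasting bounceback-intensity sets for the chemistry frontend,
#' exploiting the temperature analogy: lowering the intensities injects
#' more aggressive probabilistic fluctuations, i.e. heats the system up.
#' `cool` blocks all rule families at 0.95; `hot` blocks them at 0.2.
#' The hot system has trouble holding a high-order N-N bond against the
#' churn, so (for example, starting from N2 + 2 H2) it settles into
#' hydrogenated N-N compositions more often than the cool one, shifting
#' the first-found distribution measurably.
#'
#' @return named list of type-keyed intensity vectors.
#' @export
chem_intensity_sets <- function() {
  mk <- function(s) c(OCTET_EXCESS = s, OCTET_DEFICIT = s,
                      SLOT_ORDER = s, CONTRA = s)
  list(cool = mk(0.95), hot = mk(0.2))
}

chem_target <- function(system) {
  list(type = "valence",
       groups = lapply(system$atoms$atom_id,
                       function(a) incident_slots(system, a)),
       sums = system$atoms$valence)
}

#' Monte Carlo exploration of metastable molecular compositions
#'
#' Runs the amoeba dynamics repeatedly on a bond system and aggregates the
#' distribution of first-found valence-complete compositions (a trial's
#' first find is the first composition whose decoded assignment persists
#' for the stability window). With `transitions = TRUE` each trial runs
#' its full step budget and composition-to-composition visits, dwell times
#' and transition counts are logged.
#'
#' @param system a [bond_system()].
#' @param intensities type-named intensity map (see
#'   [chem_intensity_sets()]) or a scalar.
#' @param config an [amoeba_config()]; `max_steps` is the per-trial budget
#'   and `seed` (if set) seeds the whole experiment.
#' @param init `NULL` for a uniform random initial bond assignment, or a
#'   composition (named vector or label) realized via
#'   [realize_composition()].
#' @param trials number of Monte Carlo trials.
#' @param transitions log dwell/transition statistics (slower).
#' @param rules optional precompiled rule list (default
#'   [compile_chem_rules()]).
#' @return object of class `chem_run`: list with `counts` (first-found
#'   counts per valid composition, plus `"(censored)"`), `freq`, `trials`,
#'   `labels`, and when requested `dwell` (total steps per composition)
#'   and `transitions` (square count matrix over compositions).
#' @examples
#' sys <- bond_system(c(H = 2))
#' run_chem(sys, config = amoeba_config(max_steps = 200, seed = 1),
#'          trials = 20)$counts
#' @export
run_chem <- function(system, intensities = chem_intensity_sets()$cool,
                     config = amoeba_config(), init = NULL, trials = 500L,
                     transitions = FALSE, rules = NULL) {
  if (is.null(rules)) rules <- compile_chem_rules(system)
  if (!is.null(config$seed)) set.seed(config$seed)
  x0 <- if (is.null(init)) NULL else realize_composition(system, init)
  cs <- enumerate_valid_compositions(system)
  tgt <- chem_target(system)
  sums <- tgt$sums
  groups <- tgt$groups
  valence_ok <- function(x)
    all(vapply(seq_along(groups),
               function(g) sum(x[groups[[g]]]) == sums[g], logical(1)))
  labs <- cs$labels
  counts <- setNames(integer(length(labs) + 1L), c(labs, "(censored)"))
  dwell <- setNames(numeric(length(labs)), labs)
  trans <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  cfg <- config; cfg$seed <- NULL  # one stream for the whole experiment
  for (tr in seq_len(trials)) {
    traj <- amoeba_run(rules, system$n_slots, cfg, intensities,
                       target = tgt, x0 = x0,
                       stop = if (transitions) "never" else "window",
                       record = transitions)
    if (transitions) {
      vis <- trajectory_visits(traj, valence_ok)
      if (nrow(vis) > 0L) {
        vlab <- vapply(seq_len(nrow(vis)), function(r) {
          a <- as.integer(strsplit(vis$state[r], "")[[1]])
          composition_label(decode_molecules(system, a))
        }, "")
        counts[[vlab[1L]]] <- counts[[vlab[1L]]] + 1L
        for (r in seq_len(nrow(vis))) dwell[[vlab[r]]] <-
          dwell[[vlab[r]]] + vis$dwell[r]
        if (nrow(vis) > 1L) for (r in seq_len(nrow(vis) - 1L))
          trans[vlab[r], vlab[r + 1L]] <- trans[vlab[r], vlab[r + 1L]] + 1L
      } else counts[["(censored)"]] <- counts[["(censored)"]] + 1L
    } else {
      if (!is.null(traj$found)) {
        lab <- composition_label(decode_molecules(system, traj$found))
        counts[[lab]] <- counts[[lab]] + 1L
      } else counts[["(censored)"]] <- counts[["(censored)"]] + 1L
    }
  }
  out <- list(counts = counts, freq = counts / trials, trials = trials,
              labels = labs)
  if (transitions) { out$dwell <- dwell; out$transitions <- trans }
  structure(out, class = "chem_run")
}

#' @export
print.chem_run <- function(x, ...) {
  cat("first-found composition distribution over", x$trials, "trials:\n")
  for (l in names(x$counts))
    cat(sprintf("  %-20s %5d  (%.3f)\n", l, x$counts[[l]], x$freq[[l]]))
  invisible(x)
}
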