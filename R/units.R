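#' Unit indexing for the 2N-unit amoeba system
#'
#' An N-variable system is represented by 2N units, one per (variable,
#' value) pair. Unit \code{(i, v)} corresponds to the hypothesis
#' \eqn{x_i = v}. Units are stored in a flat vector ordered
#' \code{(1,0), (1,1), (2,0), (2,1), ...}, so unit \code{(i, v)} sits at
#' index \code{2 * (i - 1) + v + 1}.
#'
#' @param i variable index (1-based), vectorised.
#' @param v value tag, 0 or 1, vectorised.
#' @param u flat unit index (1-based), vectorised.
#' @return `unit_index()` returns flat indices; `unit_var()` and
#'   `unit_tag()` invert the mapping.
#' @examples
#' unit_index(3, 1)    # 6
#' unit_var(6)         # 3
#' unit_tag(6)         # 1
#' @export
unit_index <- function(i, v) {
  stopifnot(all(i >= 1L), all(v %in% c(0L, 1L)))
  2L * (as.integer(i) - 1L) + as.integer(v) + 1L
}

#' @rdname unit_index
#' @export
unit_var <- function(u) (as.integer(u) - 1L) %/% 2L + 1L

#' @rdname unit_index
#' @export
unit_tag <- function(u) (as.integer(u) - 1L) %% 2L

#' Construct a bounceback rule
#'
#' A bounceback rule is a conditional suppression: when every unit in
#' `condition` is fully activated (X = 1), resource supply to `target` is
#' blocked with the intensity assigned to the rule's type. A rule with an
#' empty condition fires unconditionally (used for forced constraints such
#' as unit clauses and bonds an atom cannot avoid).
#'
#' @param condition integer vector of flat unit indices that must all have
#'   X = 1 for the rule to fire; may be empty.
#' @param target flat unit index whose resource supply is suppressed.
#' @param type character label naming the rule family (e.g. `"CLAUSE"`,
#'   `"CONTRA"`, `"OCTET_EXCESS"`, `"OCTET_DEFICIT"`, `"SLOT_ORDER"`); the
#'   intensity map assigns one blocking strength per type.
#' @return an object of class `bounceback_rule`.
#' @export
bounceback_rule <- function(condition, target, type) {
  condition <- as.integer(condition)
  target <- as.integer(target)
  stopifnot(length(target) == 1L, !target %in% condition,
            is.character(type), length(type) == 1L)
  structure(list(condition = condition, target = target, type = type),
            class = "bounceback_rule")
}

#' @export
print.bounceback_rule <- function(x, ...) {
  fmt <- function(u) sprintf("(%d,%d)", unit_var(u), unit_tag(u))
  cond <- if (length(x$condition) == 0L) "TRUE"
          else paste(vapply(x$condition, fmt, ""), collapse = " & ")
  cat(sprintf("[%s] %s => block %s\n", x$type, cond, fmt(x$target)))
  invisible(x)
}

#' Resolve per-rule intensities from a type-keyed intensity map
#'
#' @param rules list of [bounceback_rule()] objects.
#' @param intensities either a single number in \[0, 1\] applied to every
#'   rule type, or a named numeric vector keyed by rule type. Every type
#'   present in `rules` must have an entry.
#' @return numeric vector of per-rule intensities, parallel to `rules`.
#' @export
rule_intensities <- function(rules, intensities = 1.0) {
  types <- vapply(rules, function(r) r$type, "")
  if (is.null(names(intensities))) {
    stopifnot(length(intensities) == 1L)
    out <- rep(as.numeric(intensities), length(rules))
  } else {
    missing <- setdiff(unique(types), names(intensities))
    if (length(missing) > 0L)
      stop("no intensity given for rule type(s): ", paste(missing, collapse = ", "))
    out <- as.numeric(intensities[types])
  }
  if (any(out < 0 | out > 1)) stop("intensities must lie in [0, 1]")
  out
}
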