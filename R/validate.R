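# ---- diagnostics ------------------------------------------------------------

diag_df <- function(severity = character(), line = integer(), message = character()) {
  data.frame(severity = severity, line = as.integer(line), message = message,
             stringsAsFactors = FALSE)
}

diag_add <- function(d, severity, line, message) {
  rbind(d, diag_df(severity, line, message))
}

diag_errors <- function(d) d[d$severity == "error", , drop = FALSE]

# ---- semantic validation ----------------------------------------------------

#' Validate a model
#'
#' Checks every referential and structural invariant of the representation:
#' all ids used anywhere resolve in the symbol table with the right kind,
#' rule targets are unique and non-constant, event assignments target
#' non-constant symbols, constraint and flux bounds are ordered, reactions
#' have at least one participant, confidence intervals are ordered, layout
#' coordinates are finite and attached to known ids. A model is exportable
#' iff this returns no error rows. The check is side-effect-free and
#' idempotent.
#'
#' @param model an [rxn_model].
#' @return A data frame of diagnostics with columns `severity`
#'   (`"error"`/`"warning"`), `line`, `message`; zero rows when clean.
#' @export
rxn_validate <- function(model) {
  stopifnot(inherits(model, "rxn_model"))
  d <- diag_df()
  syms <- model$symbols
  kind_of <- function(id) if (is.null(syms[[id]])) NA_character_ else syms[[id]]$kind
  is_const <- function(id) !is.null(syms[[id]]) && isTRUE(syms[[id]]$is_const)

  check_math <- function(node, line, where) {
    for (id in unique(math_symbols(node))) {
      if (is.na(kind_of(id))) {
        d <<- diag_add(d, "error", line, sprintf("undeclared symbol '%s' in %s", id, where))
      }
    }
  }

  for (s in syms) {
    if (s$substance_only && s$kind != "species") {
      d <- diag_add(d, "error", 1L, sprintf("substanceOnly on non-species '%s'", s$id))
    }
    if (!is.null(s$compartment)) {
      if (!identical(kind_of(s$compartment), "compartment")) {
        d <- diag_add(d, "error", 1L, sprintf(
          "compartment '%s' of species '%s' is not a compartment", s$compartment, s$id))
      }
    }
    if (!is.null(s$initial_value) && is.numeric(s$initial_value) &&
        !is.finite(s$initial_value)) {
      d <- diag_add(d, "error", 1L, sprintf("non-finite initial value for '%s'", s$id))
    }
  }

  for (r in model$reactions) {
    if (length(r$reactants) == 0 && length(r$products) == 0) {
      d <- diag_add(d, "error", r$line, sprintf("reaction '%s' has no participants", r$id))
    }
    for (ref in c(r$reactants, r$products)) {
      if (!identical(kind_of(ref$species), "species")) {
        d <- diag_add(d, "error", r$line, sprintf(
          "reaction '%s' references '%s', which is not a species", r$id, ref$species))
      }
      if (!is.null(ref$stoich) && (!is.finite(ref$stoich) || ref$stoich <= 0)) {
        d <- diag_add(d, "error", r$line, sprintf(
          "reaction '%s': stoichiometry for '%s' must be > 0", r$id, ref$species))
      }
      if (!is.null(ref$stoich_id) && !identical(kind_of(ref$stoich_id), "stoichiometry")) {
        d <- diag_add(d, "error", r$line, sprintf(
          "reaction '%s': '%s' is not a stoichiometry id", r$id, ref$stoich_id))
      }
    }
    check_math(r$kinetic_math, r$line, sprintf("rate law of '%s'", r$id))
  }

  rule_targets <- character(0)
  for (ru in model$rules) {
    if (ru$rule_kind == "algebraic") {
      if (!is.null(ru$target)) {
        d <- diag_add(d, "error", ru$line, "algebraic rule cannot have a target")
      }
    } else {
      if (is.null(ru$target)) {
        d <- diag_add(d, "error", ru$line, sprintf("%s rule without target", ru$rule_kind))
      } else {
        if (is.na(kind_of(ru$target))) {
          d <- diag_add(d, "error", ru$line, sprintf("rule targets undeclared '%s'", ru$target))
        } else if (is_const(ru$target)) {
          d <- diag_add(d, "error", ru$line, sprintf(
            "%s rule targets constant symbol '%s'", ru$rule_kind, ru$target))
        }
        if (ru$target %in% rule_targets) {
          d <- diag_add(d, "error", ru$line, sprintf(
            "'%s' is the target of more than one rule", ru$target))
        }
        rule_targets <- c(rule_targets, ru$target)
      }
    }
    check_math(ru$math, ru$line, "rule")
  }

  for (ia in model$initial_assignments) {
    if (is.na(kind_of(ia$target))) {
      d <- diag_add(d, "error", ia$line, sprintf(
        "initial assignment targets undeclared '%s'", ia$target))
    }
    check_math(ia$math, ia$line, "initial assignment")
  }

  for (e in model$events) {
    if (length(e$assignments) == 0) {
      d <- diag_add(d, "error", e$line, sprintf("event '%s' has no assignments", e$id))
    }
    for (a in e$assignments) {
      if (is.na(kind_of(a$target))) {
        d <- diag_add(d, "error", e$line, sprintf(
          "event '%s' assigns to undeclared '%s'", e$id, a$target))
      } else if (is_const(a$target)) {
        d <- diag_add(d, "error", e$line, sprintf(
          "event '%s' assigns to constant symbol '%s'", e$id, a$target))
      }
      check_math(a$math, e$line, "event assignment")
    }
    check_math(e$trigger, e$line, "event trigger")
    if (!is.null(e$priority)) check_math(e$priority, e$line, "event priority")
  }

  for (cn in model$constraints) {
    if (is.na(kind_of(cn$symbol))) {
      d <- diag_add(d, "error", cn$line, sprintf("constraint on undeclared '%s'", cn$symbol))
    }
    if (is.numeric(cn$lower) && is.numeric(cn$upper) && cn$lower > cn$upper) {
      d <- diag_add(d, "error", cn$line, sprintf(
        "constraint on '%s': lower bound %s exceeds upper bound %s",
        cn$symbol, fmt_num(cn$lower), fmt_num(cn$upper)))
    }
  }

  for (fb in model$flux_bounds) {
    if (!identical(kind_of(fb$reaction), "reaction")) {
      d <- diag_add(d, "error", fb$line, sprintf(
        "flux bound on '%s', which is not a reaction", fb$reaction))
    }
    if (fb$lower > fb$upper) {
      d <- diag_add(d, "error", fb$line, sprintf(
        "flux bound on '%s': lower %s exceeds upper %s",
        fb$reaction, fmt_num(fb$lower), fmt_num(fb$upper)))
    }
  }

  for (ob in model$objectives) {
    if (length(ob$terms) == 0) {
      d <- diag_add(d, "error", ob$line, "objective with no terms")
    }
    for (t in ob$terms) {
      if (!identical(kind_of(t$reaction), "reaction")) {
        d <- diag_add(d, "error", ob$line, sprintf(
          "objective references '%s', which is not a reaction", t$reaction))
      }
    }
  }

  for (an in model$annotations) {
    if (an$element != "model" && is.na(kind_of(an$element))) {
      d <- diag_add(d, "error", an$line, sprintf("annotation on undeclared '%s'", an$element))
    }
    if (!(an$qualifier %in% ALL_QUALIFIERS)) {
      d <- diag_add(d, "error", an$line, sprintf("unknown qualifier '%s'", an$qualifier))
    }
  }
  for (nt in model$notes) {
    if (nt$element != "model" && is.na(kind_of(nt$element))) {
      d <- diag_add(d, "error", nt$line, sprintf("notes on undeclared '%s'", nt$element))
    }
  }

  for (u in model$uncertainty) {
    if (is.na(kind_of(u$element))) {
      d <- diag_add(d, "error", u$line, sprintf(
        "uncertainty statistic on undeclared '%s'", u$element))
    }
    if (u$stat == "confidenceInterval") {
      if (length(u$value) != 2 || u$value[1] > u$value[2]) {
        d <- diag_add(d, "error", u$line, sprintf(
          "confidenceInterval for '%s' needs ordered (lo, hi)", u$element))
      }
    } else if (length(u$value) != 1) {
      d <- diag_add(d, "error", u$line, sprintf(
        "%s for '%s' needs a single value", u$stat, u$element))
    }
  }

  lay <- model$layout
  for (coll in c("positions", "sizes")) {
    for (id in names(lay[[coll]])) {
      if (is.na(kind_of(id))) {
        d <- diag_add(d, "error", 1L, sprintf("layout %s on undeclared '%s'", coll, id))
      }
      if (!all(is.finite(lay[[coll]][[id]]))) {
        d <- diag_add(d, "error", 1L, sprintf("non-finite layout %s for '%s'", coll, id))
      }
    }
  }
  for (id in names(lay$curves)) {
    if (!identical(kind_of(id), "reaction")) {
      d <- diag_add(d, "error", 1L, sprintf("curve points on '%s', which is not a reaction", id))
    }
    if (!all(is.finite(lay$curves[[id]])) || length(lay$curves[[id]]) %% 2 != 0) {
      d <- diag_add(d, "error", 1L, sprintf("malformed curve points for '%s'", id))
    }
  }

  d
}
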