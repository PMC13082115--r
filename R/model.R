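# ---- model container --------------------------------------------------------

SYMBOL_KINDS <- c("species", "parameter", "compartment", "reaction",
                  "event", "rule", "stoichiometry", "model")

# MIRIAM-style qualifier vocabulary; `notes` is handled separately.
MODEL_QUALIFIERS <- c("is", "isDerivedFrom", "isDescribedBy", "isInstanceOf",
                      "hasInstance", "origin", "created", "creator")
BIOL_QUALIFIERS <- c("is", "isVersionOf", "hasPart", "isPartOf",
                     "isDescribedBy", "hasProperty", "isPropertyOf",
                     "hasTaxon", "isDerivedFrom")
ALL_QUALIFIERS <- union(MODEL_QUALIFIERS, BIOL_QUALIFIERS)

UNCERT_STATS <- c("mean", "standardDeviation", "variance", "confidenceInterval")

AUTO_ID_RE <- "^_[JE][0-9]+$"

#' Create an empty model
#'
#' The model is the hierarchical in-memory representation bridging the text
#' language and SBML: a flat symbol table (species, parameters, compartments,
#' reactions, ...) plus statement collections (reactions, rules, events,
#' constraints, flux bounds, objectives, annotations, uncertainty statistics,
#' layout). It has reference semantics: parser and declaration operations
#' mutate it in place.
#'
#' @param id model identifier (default `"__main"`).
#' @return An object of class `rxn_model`.
#' @examples
#' m <- rxn_model("m1")
#' rxn_declare(m, "S1", "species")
#' @export
rxn_model <- function(id = "__main") {
  m <- new.env(parent = emptyenv())
  m$id <- id
  m$symbols <- list()
  m$reactions <- list()
  m$events <- list()
  m$rules <- list()
  m$initial_assignments <- list()
  m$constraints <- list()
  m$flux_bounds <- list()
  m$objectives <- list()
  m$annotations <- list()
  m$notes <- list()
  m$uncertainty <- list()
  m$layout <- list(enabled = FALSE, positions = list(), sizes = list(),
                   curves = list(), style_template = NULL)
  m$n_auto_rxn <- 0L
  m$n_auto_event <- 0L
  class(m) <- "rxn_model"
  m
}

#' @export
print.rxn_model <- function(x, ...) {
  cat(sprintf("<rxn_model '%s'>\n", x$id))
  kinds <- vapply(x$symbols, function(s) s$kind, "")
  if (length(kinds)) {
    tab <- table(kinds)
    cat("  symbols: ", paste(sprintf("%s %s", tab, names(tab)), collapse = ", "), "\n")
  } else cat("  symbols: none\n")
  cat(sprintf(
    "  %d reaction(s), %d rule(s), %d event(s), %d constraint(s), %d flux bound(s), %d objective(s)\n",
    length(x$reactions), length(x$rules), length(x$events),
    length(x$constraints), length(x$flux_bounds), length(x$objectives)
  ))
  if (isTRUE(x$layout$enabled)) cat("  layout: on\n")
  invisible(x)
}

conflict_err <- function(msg) {
  structure(
    class = c("rxn_conflict_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

new_symbol <- function(id, kind, explicit) {
  list(id = id, kind = kind, declared_explicitly = explicit,
       is_const = FALSE, is_boundary = FALSE, substance_only = FALSE,
       compartment = NULL, initial_value = NULL)
}

#' Declare or promote a symbol
#'
#' Implements implicit declaration with a deterministic kind-promotion
#' ladder: an identifier first seen in a mathematical expression defaults to
#' `parameter`; a structural role (appearing on a reaction side, in
#' coefficient position, after `in`, as a rule/event/reaction label) promotes
#' it to the corresponding kind. Structural kinds never yield to `parameter`,
#' two different structural kinds conflict, and promotions away from explicit
#' declarations are errors.
#'
#' @param model an [rxn_model].
#' @param id identifier.
#' @param kind one of `species`, `parameter`, `compartment`, `reaction`,
#'   `event`, `rule`, `stoichiometry`, `model`.
#' @param explicit was the declaration written out by the user (as opposed to
#'   inferred from a structural role)?
#' @return The (possibly promoted) symbol entry, invisibly.
#' @export
rxn_declare <- function(model, id, kind, explicit = FALSE) {
  stopifnot(inherits(model, "rxn_model"), kind %in% SYMBOL_KINDS)
  if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", id)) {
    stop(conflict_err(sprintf("'%s' is not a valid identifier", id)))
  }
  if (id == "time") {
    stop(conflict_err("'time' is reserved for simulation time and cannot be declared"))
  }
  cur <- model$symbols[[id]]
  if (is.null(cur)) {
    entry <- new_symbol(id, kind, explicit)
    model$symbols[[id]] <- entry
    return(invisible(entry))
  }
  if (cur$kind == kind) {
    cur$declared_explicitly <- cur$declared_explicitly || explicit
    model$symbols[[id]] <- cur
    return(invisible(cur))
  }
  # math references (implicit parameter) never demote a structural kind
  if (kind == "parameter" && !explicit) return(invisible(cur))
  if (cur$kind == "parameter" && !cur$declared_explicitly) {
    cur$kind <- kind
    cur$declared_explicitly <- explicit
    model$symbols[[id]] <- cur
    return(invisible(cur))
  }
  stop(conflict_err(sprintf(
    "'%s' is already declared as %s%s and cannot be redeclared as %s",
    id, if (cur$declared_explicitly) "" else "implicit ", cur$kind, kind
  )))
}

symbol_kind <- function(model, id) {
  s <- model$symbols[[id]]
  if (is.null(s)) NA_character_ else s$kind
}

set_symbol_field <- function(model, id, field, value) {
  s <- model$symbols[[id]]
  stopifnot(!is.null(s))
  s[[field]] <- value
  model$symbols[[id]] <- s
  invisible(s)
}

# declare every bare symbol referenced in a math tree as an implicit parameter
declare_math_refs <- function(model, node) {
  if (is.null(node)) return(invisible(NULL))
  for (id in unique(math_symbols(node))) {
    if (is.null(model$symbols[[id]])) rxn_declare(model, id, "parameter")
  }
  invisible(NULL)
}

next_auto_reaction_id <- function(model) {
  id <- paste0("_J", model$n_auto_rxn)
  model$n_auto_rxn <- model$n_auto_rxn + 1L
  id
}

next_auto_event_id <- function(model) {
  id <- paste0("_E", model$n_auto_event)
  model$n_auto_event <- model$n_auto_event + 1L
  id
}

# ---- record constructors ----------------------------------------------------

species_ref <- function(species, stoich = NULL, stoich_id = NULL) {
  stopifnot(xor(is.null(stoich), is.null(stoich_id)) || (is.null(stoich) && is.null(stoich_id)))
  if (is.null(stoich) && is.null(stoich_id)) stoich <- 1
  list(species = species, stoich = stoich, stoich_id = stoich_id)
}

new_reaction <- function(id, reactants, products, kinetic_math = NULL,
                         reversible = TRUE, auto_id = FALSE, line = 1L) {
  list(id = id, auto_id = auto_id, reactants = reactants, products = products,
       kinetic_math = kinetic_math, reversible = reversible, line = line)
}

new_event <- function(id, trigger, assignments, priority = NULL,
                      auto_id = FALSE, line = 1L) {
  list(id = id, auto_id = auto_id, trigger = trigger, priority = priority,
       assignments = assignments,
       persistent = TRUE, initial_value_trigger = TRUE,
       use_values_from_trigger_time = TRUE, line = line)
}

new_rule <- function(rule_kind, target = NULL, math, id = NULL, line = 1L) {
  stopifnot(rule_kind %in% c("assignment", "rate", "algebraic"))
  list(rule_kind = rule_kind, id = id, target = target, math = math, line = line)
}

# ---- finalization defaults --------------------------------------------------

LAYOUT_DEFAULT_SIZE <- c(80, 40)
LAYOUT_GRID_PITCH <- 150
LAYOUT_GRID_COLS <- 5L

# Applied after parsing or SBML import so both origins compare equal:
# missing layout sizes default to an 80x40 box; an enabled layout with no
# coordinates gets a deterministic row-major grid over species.
finalize_model <- function(model) {
  lay <- model$layout
  if (length(lay$positions) > 0 || length(lay$curves) > 0 ||
      length(lay$sizes) > 0 || !is.null(lay$style_template)) {
    model$layout$enabled <- TRUE
  }
  if (isTRUE(model$layout$enabled) && length(model$layout$positions) == 0) {
    sp <- names(model$symbols)[vapply(model$symbols, function(s) s$kind == "species", TRUE)]
    for (i in seq_along(sp)) {
      col <- (i - 1L) %% LAYOUT_GRID_COLS
      row <- (i - 1L) %/% LAYOUT_GRID_COLS
      model$layout$positions[[sp[i]]] <- c(col * LAYOUT_GRID_PITCH, row * LAYOUT_GRID_PITCH)
    }
  }
  for (id in names(model$layout$positions)) {
    if (is.null(model$layout$sizes[[id]])) {
      model$layout$sizes[[id]] <- LAYOUT_DEFAULT_SIZE
    }
  }
  # a later flux-bound statement for the same reaction replaces the earlier
  if (length(model$flux_bounds) > 1) {
    rids <- vapply(model$flux_bounds, function(f) f$reaction, "")
    model$flux_bounds <- model$flux_bounds[!duplicated(rids, fromLast = TRUE)]
  }
  invisible(model)
}
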