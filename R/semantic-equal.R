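# ---- semantic equality ------------------------------------------------------

# Canonical signature strings for each collection; auto-generated ids
# (_J0, _E1, ...) are masked so models that differ only in generated labels
# compare equal, and statement order is erased by sorting.

mask_auto <- function(id) {
  if (is.null(id)) return("")
  if (grepl(AUTO_ID_RE, id)) "*" else id
}

sig_math <- function(node) if (is.null(node)) "" else math_render(node)

sig_ref <- function(ref) {
  coef <- if (!is.null(ref$stoich_id)) ref$stoich_id else fmt_num(ref$stoich)
  paste0(coef, " ", ref$species)
}

sig_pair_map <- function(lst) {
  # named list of numeric vectors -> sorted "id:(a,b)" strings
  out <- vapply(names(lst), function(id) {
    paste0(id, ":(", paste(vapply(lst[[id]], fmt_num, ""), collapse = ","), ")")
  }, "")
  sort(unname(out))
}

model_signatures <- function(m) {
  syms <- lapply(m$symbols, function(s) {
    # reaction/event/rule symbols are carried by their statements
    if (s$kind %in% c("reaction", "event", "rule")) return(NULL)
    init <- if (is.null(s$initial_value)) "" else fmt_num(s$initial_value)
    paste0(s$id, "|", s$kind, "|const=", s$is_const, "|bnd=", s$is_boundary,
           "|amt=", s$substance_only, "|comp=", s$compartment %||% "",
           "|init=", init)
  })
  syms <- sort(unlist(syms, use.names = FALSE) %||% character(0))

  reactions <- sort(vapply(m$reactions, function(r) {
    paste0(mask_auto(r$id), ": ",
           paste(vapply(r$reactants, sig_ref, ""), collapse = " + "), " -> ",
           paste(vapply(r$products, sig_ref, ""), collapse = " + "),
           "; ", sig_math(r$kinetic_math), " rev=", r$reversible)
  }, "") %||% character(0))

  events <- sort(vapply(m$events, function(e) {
    paste0(mask_auto(e$id), ": at ", sig_math(e$trigger),
           " prio=", sig_math(e$priority), ": ",
           paste(vapply(e$assignments, function(a)
             paste0(a$target, " = ", sig_math(a$math)), ""), collapse = ", "),
           " [", e$persistent, e$initial_value_trigger,
           e$use_values_from_trigger_time, "]")
  }, "") %||% character(0))

  rules <- sort(vapply(m$rules, function(r) {
    switch(r$rule_kind,
      algebraic = paste0("alg ", mask_auto(r$id %||% ""), ": 0 = ", sig_math(r$math)),
      assignment = paste0(r$target, " := ", sig_math(r$math)),
      rate = paste0(r$target, "' = ", sig_math(r$math))
    )
  }, "") %||% character(0))

  inits <- sort(vapply(m$initial_assignments, function(ia) {
    paste0(ia$target, " = ", sig_math(ia$math))
  }, "") %||% character(0))

  constraints <- sort(vapply(m$constraints, function(cn) {
    lo <- if (is.null(cn$lower)) "" else if (is.numeric(cn$lower)) fmt_num(cn$lower) else sig_math(cn$lower)
    hi <- if (is.null(cn$upper)) "" else if (is.numeric(cn$upper)) fmt_num(cn$upper) else sig_math(cn$upper)
    paste0(lo, if (isTRUE(cn$strict_lower)) " < " else " <= ", cn$symbol,
           if (isTRUE(cn$strict_upper)) " < " else " <= ", hi)
  }, "") %||% character(0))

  flux_bounds <- sort(vapply(m$flux_bounds, function(fb) {
    paste0(fmt_num(fb$lower), " <= ", mask_auto(fb$reaction), " <= ", fmt_num(fb$upper))
  }, "") %||% character(0))

  objectives <- vapply(m$objectives, function(ob) {
    paste0(ob$sense, " ", paste(vapply(ob$terms, function(t)
      paste0(fmt_num(t$coef), "*", mask_auto(t$reaction)), ""), collapse = " + "))
  }, "") %||% character(0)  # order matters: first objective is active

  annotations <- sort(vapply(m$annotations, function(a) {
    paste0(mask_auto(a$element), " ", a$qualifier, " ", a$uri)
  }, "") %||% character(0))

  notes <- sort(vapply(m$notes, function(n) {
    paste0(mask_auto(n$element), " notes ", n$text)
  }, "") %||% character(0))

  uncertainty <- sort(vapply(m$uncertainty, function(u) {
    paste0(mask_auto(u$element), ".", u$stat, " = (",
           paste(vapply(u$value, fmt_num, ""), collapse = ","), ")")
  }, "") %||% character(0))

  lay <- m$layout
  layout <- c(
    paste0("enabled=", isTRUE(lay$enabled)),
    paste0("template=", lay$style_template %||% ""),
    paste0("pos ", sig_pair_map(lay$positions)),
    paste0("size ", sig_pair_map(lay$sizes)),
    paste0("curve ", sig_pair_map(lay$curves))
  )

  list(model_id = m$id, symbols = syms, reactions = reactions, events = events,
       rules = rules, initial_assignments = inits, constraints = constraints,
       flux_bounds = flux_bounds, objectives = objectives,
       annotations = annotations, notes = notes, uncertainty = uncertainty,
       layout = layout)
}

#' Compare two models up to statement order and generated ids
#'
#' Two models are semantically equal when every collection (symbols,
#' reactions, rules, events, constraints, flux bounds, objectives,
#' annotations, uncertainty statistics, layout) matches as a multiset,
#' ignoring statement order and auto-generated labels (`_J0`, `_E1`, ...).
#' Whether a symbol was declared explicitly or inferred is not compared.
#' This is the round-trip oracle used by the losslessness checks.
#'
#' @param a,b models ([rxn_model]).
#' @return A list of class `rxn_semantic_diff` with elements `equal`
#'   (logical) and `differences` (character, at most the first 20).
#' @export
rxn_semantic_equal <- function(a, b) {
  sa <- model_signatures(a)
  sb <- model_signatures(b)
  diffs <- character(0)
  if (!identical(sa$model_id, sb$model_id)) {
    diffs <- c(diffs, sprintf("model id: '%s' vs '%s'", sa$model_id, sb$model_id))
  }
  for (coll in setdiff(names(sa), "model_id")) {
    xa <- sa[[coll]]; xb <- sb[[coll]]
    only_a <- setdiff_multiset(xa, xb)
    only_b <- setdiff_multiset(xb, xa)
    for (s in only_a) diffs <- c(diffs, sprintf("%s: only in first: %s", coll, s))
    for (s in only_b) diffs <- c(diffs, sprintf("%s: only in second: %s", coll, s))
  }
  structure(list(equal = length(diffs) == 0, differences = utils::head(diffs, 20)),
            class = "rxn_semantic_diff")
}

setdiff_multiset <- function(x, y) {
  for (v in y) {
    i <- match(v, x)
    if (!is.na(i)) x <- x[-i]
  }
  x
}

#' @export
print.rxn_semantic_diff <- function(x, ...) {
  if (x$equal) {
    cat("models are semantically equal\n")
  } else {
    cat("models differ:\n")
    for (d in x$differences) cat("  - ", d, "\n", sep = "")
  }
  invisible(x)
}
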