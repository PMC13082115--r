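# ---- deterministic text serializer ------------------------------------------

# Symbols are emitted grouped by kind (compartments, species, parameters,
# then named stoichiometries in order of first use); the same sequence
# orders initialization lines. This makes serialize(parse(.)) idempotent
# byte-for-byte: re-parsing the output reconstructs the same emission order.

emission_symbol_sequence <- function(m) {
  kinds <- vapply(m$symbols, function(s) s$kind, "")
  ids <- names(m$symbols)
  comp <- ids[kinds == "compartment"]
  spec <- ids[kinds == "species"]
  par <- ids[kinds == "parameter"]
  stoich <- character(0)
  for (r in m$reactions) {
    for (ref in c(r$reactants, r$products)) {
      if (!is.null(ref$stoich_id) && !(ref$stoich_id %in% stoich)) {
        stoich <- c(stoich, ref$stoich_id)
      }
    }
  }
  c(comp, spec, par, stoich)
}

fmt_brace <- function(v) paste0("{", paste(vapply(v, fmt_num, ""), collapse = ", "), "}")

render_ref <- function(ref) {
  if (!is.null(ref$stoich_id)) return(paste0(ref$stoich_id, " ", ref$species))
  if (ref$stoich == 1) ref$species else paste0(fmt_num(ref$stoich), " ", ref$species)
}

render_reaction_line <- function(r) {
  lhs <- paste(vapply(r$reactants, render_ref, ""), collapse = " + ")
  rhs <- paste(vapply(r$products, render_ref, ""), collapse = " + ")
  line <- paste0(r$id, ": ", lhs, " -> ", rhs)
  if (!is.null(r$kinetic_math)) line <- paste0(line, "; ", math_render(r$kinetic_math))
  line
}

render_event_line <- function(e) {
  line <- paste0(e$id, ": at ", math_render(e$trigger))
  if (!is.null(e$priority)) line <- paste0(line, ", priority = ", math_render(e$priority))
  asg <- vapply(e$assignments, function(a)
    paste0(a$target, " = ", math_render(a$math)), "")
  paste0(line, ": ", paste(asg, collapse = ", "))
}

render_bound <- function(b) if (is.numeric(b)) fmt_num(b) else math_render(b)

#' Serialize a model to canonical text
#'
#' Deterministically renders a model back to the plain-text language with a
#' fixed section order (declarations, substanceOnly, reactions, rules,
#' initializations, events, constraints, flux bounds, objectives,
#' uncertainty, annotations, notes, layout) and canonical whitespace.
#' Re-parsing the output yields a model that is [rxn_semantic_equal()] to
#' the input, and serializing again reproduces the text byte-for-byte.
#' Models with validation errors are refused.
#'
#' @param model an [rxn_model] that validates without errors.
#' @return character scalar: model text, LF line endings, ASCII `->` arrows.
#' @examples
#' res <- rxn_parse("S1 -> S2; k1*S1")
#' cat(rxn_serialize(res$model))
#' @export
rxn_serialize <- function(model) {
  stopifnot(inherits(model, "rxn_model"))
  errs <- diag_errors(rxn_validate(model))
  if (nrow(errs) > 0) {
    stop("model has validation errors:\n",
         paste(sprintf("  line %d: %s", errs$line, errs$message), collapse = "\n"),
         call. = FALSE)
  }
  syms <- model$symbols
  out <- character(0)
  emit <- function(s) out <<- c(out, paste0("  ", s))

  out <- c(out, paste0("model ", model$id))

  decl_line <- function(kind, const) {
    ids <- names(syms)[vapply(syms, function(s)
      s$kind == kind && s$is_const == const, TRUE)]
    if (length(ids) == 0) return(invisible(NULL))
    items <- vapply(ids, function(id) {
      s <- syms[[id]]
      item <- paste0(if (s$is_boundary) "$" else "", id)
      if (!is.null(s$compartment)) item <- paste0(item, " in ", s$compartment)
      item
    }, "")
    emit(paste0(if (const) "const " else "", kind, " ",
                paste(items, collapse = ", ")))
  }
  for (kind in c("compartment", "species", "parameter")) {
    decl_line(kind, FALSE)
    decl_line(kind, TRUE)
  }
  amt <- names(syms)[vapply(syms, function(s) isTRUE(s$substance_only), TRUE)]
  if (length(amt) > 0) emit(paste0("substanceOnly ", paste(amt, collapse = ", ")))

  for (r in model$reactions) emit(render_reaction_line(r))

  for (ru in model$rules) {
    emit(switch(ru$rule_kind,
      algebraic = paste0(if (!is.null(ru$id)) paste0(ru$id, ": ") else "",
                         "0 = ", math_render(ru$math)),
      assignment = paste0(ru$target, " := ", math_render(ru$math)),
      rate = paste0(ru$target, "' = ", math_render(ru$math))
    ))
  }

  for (id in emission_symbol_sequence(model)) {
    s <- syms[[id]]
    if (!is.null(s$initial_value)) emit(paste0(id, " = ", fmt_num(s$initial_value)))
  }
  for (ia in model$initial_assignments) {
    emit(paste0(ia$target, " = ", math_render(ia$math)))
  }

  for (e in model$events) emit(render_event_line(e))

  for (cn in model$constraints) {
    if (!is.null(cn$lower) && !is.null(cn$upper)) {
      emit(paste0(render_bound(cn$lower), if (cn$strict_lower) " < " else " <= ",
                  cn$symbol,
                  if (cn$strict_upper) " < " else " <= ", render_bound(cn$upper)))
    } else if (!is.null(cn$lower)) {
      emit(paste0(render_bound(cn$lower), if (cn$strict_lower) " < " else " <= ",
                  cn$symbol))
    } else {
      emit(paste0(cn$symbol, if (cn$strict_upper) " < " else " <= ",
                  render_bound(cn$upper)))
    }
  }

  # content-based order (by symbol-table position) so models that pass
  # through the SBML bridge, which regroups these records, re-serialize
  # byte-identically
  fbs <- model$flux_bounds
  if (length(fbs) > 0) {
    fbs <- fbs[order(match(vapply(fbs, function(f) f$reaction, ""), names(syms)))]
  }
  for (fb in fbs) {
    emit(paste0(fmt_num(fb$lower), " <= ", fb$reaction, " <= ", fmt_num(fb$upper)))
  }

  for (ob in model$objectives) {
    terms <- character(0)
    for (i in seq_along(ob$terms)) {
      t <- ob$terms[[i]]
      coef <- abs(t$coef)
      body <- if (coef == 1) t$reaction else paste0(fmt_num(coef), " ", t$reaction)
      if (i == 1) {
        terms <- c(terms, paste0(if (t$coef < 0) "- " else "", body))
      } else {
        terms <- c(terms, paste0(if (t$coef < 0) "- " else "+ ", body))
      }
    }
    emit(paste0(ob$sense, " ", paste(terms, collapse = " ")))
  }

  unc <- model$uncertainty
  if (length(unc) > 0) {
    unc <- unc[order(match(vapply(unc, function(u) u$element, ""), names(syms)),
                     match(vapply(unc, function(u) u$stat, ""), UNCERT_STATS))]
  }
  for (u in unc) {
    val <- if (u$stat == "confidenceInterval") fmt_brace(u$value) else fmt_num(u$value)
    emit(paste0(u$element, ".", u$stat, " = ", val))
  }

  ann <- model$annotations
  if (length(ann) > 0) {
    el <- vapply(ann, function(a) a$element, "")
    key1 <- ifelse(el == "model", 0L, match(el, names(syms)))
    key2 <- match(vapply(ann, function(a) a$qualifier, ""), ALL_QUALIFIERS)
    key3 <- vapply(ann, function(a) a$uri, "")
    ann <- ann[order(key1, key2, key3)]
  }
  for (an in ann) {
    emit(paste0(an$element, " ", an$qualifier, " \"", an$uri, "\""))
  }
  nts <- model$notes
  if (length(nts) > 0) {
    el <- vapply(nts, function(n) n$element, "")
    nts <- nts[order(ifelse(el == "model", 0L, match(el, names(syms))))]
  }
  for (nt in nts) {
    emit(paste0(nt$element, " notes \"", nt$text, "\""))
  }

  lay <- model$layout
  if (isTRUE(lay$enabled)) emit("model.layout = on")
  if (!is.null(lay$style_template)) {
    emit(paste0("model.styleTemplate = \"", lay$style_template, "\""))
  }
  by_symbol_order <- function(ids) ids[order(match(ids, names(syms)))]
  for (id in by_symbol_order(names(lay$positions))) {
    prop <- if (identical(symbol_kind(model, id), "reaction")) "centroid" else "position"
    emit(paste0(id, ".", prop, " = ", fmt_brace(lay$positions[[id]])))
  }
  for (id in by_symbol_order(names(lay$sizes))) {
    emit(paste0(id, ".size = ", fmt_brace(lay$sizes[[id]])))
  }
  for (id in by_symbol_order(names(lay$curves))) {
    emit(paste0(id, ".curvePoints = ", fmt_brace(lay$curves[[id]])))
  }

  out <- c(out, "end", "")
  paste(out, collapse = "\n")
}
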