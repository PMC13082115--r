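# ---- SBML Level 3 Version 2 export ------------------------------------------

NS_CORE <- "http://www.sbml.org/sbml/level3/version2/core"
NS_FBC <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
NS_DISTRIB <- "http://www.sbml.org/sbml/level3/version1/distrib/version1"
NS_LAYOUT <- "http://www.sbml.org/sbml/level3/version1/layout/version1"
NS_XSI <- "http://www.w3.org/2001/XMLSchema-instance"
NS_RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_BQBIOL <- "http://biomodels.net/biology-qualifiers/"
NS_BQMODEL <- "http://biomodels.net/model-qualifiers/"
NS_XHTML <- "http://www.w3.org/1999/xhtml"
NS_STYLE_TEMPLATE <- "urn:rxnscript:styleTemplate"

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  s <- gsub('"', "&quot;", s, fixed = TRUE)
  s
}

xattr <- function(name, value) sprintf(' %s="%s"', name, xml_escape(as.character(value)))
xbool <- function(x) if (isTRUE(x)) "true" else "false"

#' Export a model to SBML Level 3 Version 2
#'
#' Maps the internal model to an SBML document. Package namespaces (fbc,
#' distrib, layout) are declared only when the model uses the corresponding
#' features. The mapping contract: species carry
#' `hasOnlySubstanceUnits = substanceOnly` and numeric initial values fill
#' the amount or concentration slot accordingly; species without a
#' compartment are placed in an auto-created `default_compartment` of size 1;
#' named stoichiometries become identified species references initialised
#' via initial assignments; constraints become `constraint` elements whose
#' math conjoins the bound comparisons (strictness preserved as `lt` vs
#' `leq`); flux bounds become constant `<rid>_lb`/`<rid>_ub` parameters
#' referenced by the reaction; objectives fill the fbc objective list, the
#' first one active; uncertainty statistics become distrib `uncertParameter`
#' (or `uncertSpan`) children; CV terms become RDF annotations; notes embed
#' the markdown verbatim in a preformatted XHTML block; layout geometry maps
#' to glyph bounding boxes and curve segments.
#'
#' @param model an [rxn_model] that validates without errors.
#' @return A list of class `rxn_sbml_export`: `document` (XML text),
#'   `packages_used` (subset of fbc/distrib/layout), `warnings`
#'   (diagnostics data frame).
#' @examples
#' res <- rxn_parse("S1 -> S2; k1*S1")
#' doc <- sbml_export(res$model)
#' substr(doc$document, 1, 60)
#' @export
sbml_export <- function(model) {
  stopifnot(inherits(model, "rxn_model"))
  errs <- diag_errors(rxn_validate(model))
  if (nrow(errs) > 0) {
    stop("model has validation errors:\n",
         paste(sprintf("  line %d: %s", errs$line, errs$message), collapse = "\n"),
         call. = FALSE)
  }
  warnings <- diag_df()
  syms <- model$symbols
  kinds <- vapply(syms, function(s) s$kind, "")

  uses_fbc <- length(model$flux_bounds) > 0 || length(model$objectives) > 0
  any_draw <- any(vapply(all_model_math(model), math_has_draw, TRUE))
  uses_distrib <- length(model$uncertainty) > 0 || isTRUE(any_draw)
  uses_layout <- isTRUE(model$layout$enabled) ||
    length(model$layout$positions) > 0 || length(model$layout$curves) > 0
  packages <- c(
    if (uses_fbc) "fbc", if (uses_distrib) "distrib", if (uses_layout) "layout"
  )
  has_curves <- length(model$layout$curves) > 0

  annotated <- unique(c(
    vapply(model$annotations, function(a) a$element, ""),
    vapply(model$notes, function(n) n$element, "")
  ))
  uncert_by_el <- split(model$uncertainty,
                        vapply(model$uncertainty, function(u) u$element, ""))

  out <- character(0)
  push <- function(...) out <<- c(out, paste0(...))

  push('<?xml version="1.0" encoding="UTF-8"?>')
  root <- paste0('<sbml xmlns="', NS_CORE, '" level="3" version="2"')
  if (uses_fbc) root <- paste0(root, ' xmlns:fbc="', NS_FBC, '" fbc:required="false"')
  if (uses_distrib) root <- paste0(root, ' xmlns:distrib="', NS_DISTRIB, '" distrib:required="true"')
  if (uses_layout) root <- paste0(root, ' xmlns:layout="', NS_LAYOUT, '" layout:required="false"')
  if (has_curves) root <- paste0(root, ' xmlns:xsi="', NS_XSI, '"')
  push(root, ">")

  mattr <- paste0(xattr("id", model$id))
  if ("model" %in% annotated) mattr <- paste0(mattr, xattr("metaid", "meta__model"))
  if (uses_fbc) mattr <- paste0(mattr, ' fbc:strict="false"')
  push("  <model", mattr, ">")

  emit_notes_annotations(push, model, "model", "meta__model", indent = "    ")

  # -- compartments -----------------------------------------------------------
  comp_ids <- names(syms)[kinds == "compartment"]
  species_ids <- names(syms)[kinds == "species"]
  needs_default <- any(vapply(species_ids, function(id)
    is.null(syms[[id]]$compartment), TRUE)) && length(species_ids) > 0
  if (length(comp_ids) > 0 || needs_default) {
    push("    <listOfCompartments>")
    for (id in comp_ids) {
      s <- syms[[id]]
      a <- paste0(xattr("id", id), element_meta(id, annotated))
      if (!is.null(s$initial_value)) a <- paste0(a, xattr("size", fmt_num(s$initial_value)))
      a <- paste0(a, xattr("constant", xbool(s$is_const)))
      emit_element(push, model, "compartment", id, a, uncert_by_el, annotated, "      ")
    }
    if (needs_default) {
      push('      <compartment id="default_compartment" size="1" constant="true"/>')
    }
    push("    </listOfCompartments>")
  }

  # -- species ----------------------------------------------------------------
  if (length(species_ids) > 0) {
    push("    <listOfSpecies>")
    for (id in species_ids) {
      s <- syms[[id]]
      a <- paste0(xattr("id", id), element_meta(id, annotated),
                  xattr("compartment", s$compartment %||% "default_compartment"))
      if (!is.null(s$initial_value)) {
        slot <- if (s$substance_only) "initialAmount" else "initialConcentration"
        a <- paste0(a, xattr(slot, fmt_num(s$initial_value)))
      }
      a <- paste0(a,
        xattr("hasOnlySubstanceUnits", xbool(s$substance_only)),
        xattr("boundaryCondition", xbool(s$is_boundary)),
        xattr("constant", xbool(s$is_const)))
      emit_element(push, model, "species", id, a, uncert_by_el, annotated, "      ")
    }
    push("    </listOfSpecies>")
  }

  # -- parameters (model parameters + flux-bound constants) -------------------
  par_ids <- names(syms)[kinds == "parameter"]
  fb_params <- flux_bound_parameters(model)
  if (length(par_ids) > 0 || nrow(fb_params) > 0) {
    push("    <listOfParameters>")
    for (id in par_ids) {
      s <- syms[[id]]
      a <- paste0(xattr("id", id), element_meta(id, annotated))
      if (!is.null(s$initial_value)) a <- paste0(a, xattr("value", fmt_num(s$initial_value)))
      a <- paste0(a, xattr("constant", xbool(s$is_const)))
      emit_element(push, model, "parameter", id, a, uncert_by_el, annotated, "      ")
    }
    for (i in seq_len(nrow(fb_params))) {
      v <- fb_params$value[i]
      vs <- if (!is.finite(v)) { if (v > 0) "INF" else "-INF" } else fmt_num(v)
      push('      <parameter id="', fb_params$id[i], '" value="', vs,
           '" constant="true"/>')
    }
    push("    </listOfParameters>")
  }

  # -- initial assignments ----------------------------------------------------
  stoich_inits <- stoich_init_sequence(model)
  if (length(model$initial_assignments) > 0 || length(stoich_inits) > 0) {
    push("    <listOfInitialAssignments>")
    for (ia in model$initial_assignments) {
      push('      <initialAssignment symbol="', ia$target, '">')
      push("        ", math_to_mathml(ia$math))
      push("      </initialAssignment>")
    }
    for (id in stoich_inits) {
      push('      <initialAssignment symbol="', id, '">')
      push("        ", math_to_mathml(m_num(syms[[id]]$initial_value)))
      push("      </initialAssignment>")
    }
    push("    </listOfInitialAssignments>")
  }

  # -- rules ------------------------------------------------------------------
  if (length(model$rules) > 0) {
    push("    <listOfRules>")
    for (ru in model$rules) {
      el <- switch(ru$rule_kind, assignment = "assignmentRule",
                   rate = "rateRule", algebraic = "algebraicRule")
      a <- ""
      if (!is.null(ru$id)) a <- paste0(a, xattr("id", ru$id))
      if (!is.null(ru$target)) a <- paste0(a, xattr("variable", ru$target))
      push("      <", el, a, ">")
      push("        ", math_to_mathml(ru$math))
      push("      </", el, ">")
    }
    push("    </listOfRules>")
  }

  # -- constraints ------------------------------------------------------------
  if (length(model$constraints) > 0) {
    push("    <listOfConstraints>")
    for (cn in model$constraints) {
      push("      <constraint>")
      push("        ", math_to_mathml(constraint_math(cn)))
      push("      </constraint>")
    }
    push("    </listOfConstraints>")
  }

  # -- reactions --------------------------------------------------------------
  if (length(model$reactions) > 0) {
    fb_by_rxn <- flux_bounds_by_reaction(model)
    push("    <listOfReactions>")
    for (r in model$reactions) {
      a <- paste0(xattr("id", r$id), element_meta(r$id, annotated),
                  xattr("reversible", xbool(r$reversible)))
      fb <- fb_by_rxn[[r$id]]
      if (!is.null(fb)) {
        a <- paste0(a, xattr("fbc:lowerFluxBound", fb["lb_id"]),
                    xattr("fbc:upperFluxBound", fb["ub_id"]))
      }
      push("      <reaction", a, ">")
      emit_notes_annotations(push, model, r$id, paste0("meta_", r$id), indent = "        ")
      emit_uncertainty(push, uncert_by_el[[r$id]], "        ")
      for (side in c("listOfReactants", "listOfProducts")) {
        refs <- if (side == "listOfReactants") r$reactants else r$products
        if (length(refs) == 0) next
        push("        <", side, ">")
        for (ref in refs) {
          if (!is.null(ref$stoich_id)) {
            push('          <speciesReference id="', ref$stoich_id,
                 '" species="', ref$species, '" constant="false"/>')
          } else {
            push('          <speciesReference species="', ref$species,
                 '" stoichiometry="', fmt_num(ref$stoich), '" constant="true"/>')
          }
        }
        push("        </", side, ">")
      }
      if (!is.null(r$kinetic_math)) {
        push("        <kineticLaw>")
        push("          ", math_to_mathml(r$kinetic_math))
        push("        </kineticLaw>")
      }
      push("      </reaction>")
    }
    push("    </listOfReactions>")
  }

  # -- events -----------------------------------------------------------------
  if (length(model$events) > 0) {
    push("    <listOfEvents>")
    for (e in model$events) {
      push('      <event id="', e$id, '" useValuesFromTriggerTime="',
           xbool(e$use_values_from_trigger_time), '">')
      push('        <trigger initialValue="', xbool(e$initial_value_trigger),
           '" persistent="', xbool(e$persistent), '">')
      push("          ", math_to_mathml(e$trigger))
      push("        </trigger>")
      if (!is.null(e$priority)) {
        push("        <priority>")
        push("          ", math_to_mathml(e$priority))
        push("        </priority>")
      }
      push("        <listOfEventAssignments>")
      for (asg in e$assignments) {
        push('          <eventAssignment variable="', asg$target, '">')
        push("            ", math_to_mathml(asg$math))
        push("          </eventAssignment>")
      }
      push("        </listOfEventAssignments>")
      push("      </event>")
    }
    push("    </listOfEvents>")
  }

  # -- fbc objectives ---------------------------------------------------------
  if (length(model$objectives) > 0) {
    push('    <fbc:listOfObjectives fbc:activeObjective="obj1">')
    for (i in seq_along(model$objectives)) {
      ob <- model$objectives[[i]]
      push('      <fbc:objective fbc:id="obj', i, '" fbc:type="', ob$sense, '">')
      push("        <fbc:listOfFluxObjectives>")
      for (t in ob$terms) {
        push('          <fbc:fluxObjective fbc:reaction="', t$reaction,
             '" fbc:coefficient="', fmt_num(t$coef), '"/>')
      }
      push("        </fbc:listOfFluxObjectives>")
      push("      </fbc:objective>")
    }
    push("    </fbc:listOfObjectives>")
  }

  # -- layout -----------------------------------------------------------------
  if (uses_layout) emit_layout(push, model)

  push("  </model>")
  push("</sbml>")

  structure(
    list(document = paste0(paste(out, collapse = "\n"), "\n"),
         packages_used = packages, warnings = warnings),
    class = "rxn_sbml_export"
  )
}

#' @export
print.rxn_sbml_export <- function(x, ...) {
  cat(sprintf("<SBML L3V2 document, %d bytes, packages: %s>\n",
              nchar(x$document),
              if (length(x$packages_used)) paste(x$packages_used, collapse = ", ")
              else "core only"))
  invisible(x)
}

all_model_math <- function(model) {
  out <- list()
  add <- function(x) if (!is.null(x)) out[[length(out) + 1L]] <<- x
  for (r in model$reactions) add(r$kinetic_math)
  for (ru in model$rules) add(ru$math)
  for (ia in model$initial_assignments) add(ia$math)
  for (e in model$events) {
    add(e$trigger); add(e$priority)
    for (a in e$assignments) add(a$math)
  }
  for (cn in model$constraints) {
    if (is.list(cn$lower)) add(cn$lower)
    if (is.list(cn$upper)) add(cn$upper)
  }
  out
}

element_meta <- function(id, annotated) {
  if (id %in% annotated) xattr("metaid", paste0("meta_", id)) else ""
}

# named stoichiometries with a plain numeric initial value, in emission order
stoich_init_sequence <- function(model) {
  seq_ids <- emission_symbol_sequence(model)
  Filter(function(id) {
    s <- model$symbols[[id]]
    s$kind == "stoichiometry" && !is.null(s$initial_value)
  }, seq_ids)
}

flux_bound_parameters <- function(model) {
  used <- names(model$symbols)
  rows <- data.frame(id = character(), value = numeric(), stringsAsFactors = FALSE)
  fbs <- model$flux_bounds
  if (length(fbs) > 0) {
    fbs <- fbs[order(match(vapply(fbs, function(f) f$reaction, ""), used))]
  }
  for (fb in fbs) {
    for (side in c("lb", "ub")) {
      base <- paste0(fb$reaction, "_", side)
      id <- base
      i <- 1L
      while (id %in% c(used, rows$id)) { id <- paste0(base, i); i <- i + 1L }
      rows <- rbind(rows, data.frame(
        id = id, value = if (side == "lb") fb$lower else fb$upper,
        stringsAsFactors = FALSE))
    }
  }
  rows
}

flux_bounds_by_reaction <- function(model) {
  pars <- flux_bound_parameters(model)
  fbs <- model$flux_bounds
  if (length(fbs) > 0) {
    fbs <- fbs[order(match(vapply(fbs, function(f) f$reaction, ""),
                           names(model$symbols)))]
  }
  out <- list()
  for (i in seq_along(fbs)) {
    out[[fbs[[i]]$reaction]] <- c(lb_id = pars$id[2 * i - 1], ub_id = pars$id[2 * i])
  }
  out
}

constraint_math <- function(cn) {
  as_node <- function(x) if (is.numeric(x)) m_num(x) else x
  sym <- m_sym(cn$symbol)
  lower <- if (!is.null(cn$lower)) {
    m_cmp(if (cn$strict_lower) "<" else "<=", as_node(cn$lower), sym)
  }
  upper <- if (!is.null(cn$upper)) {
    m_cmp(if (cn$strict_upper) "<" else "<=", sym, as_node(cn$upper))
  }
  if (!is.null(lower) && !is.null(upper)) m_bool("and", list(lower, upper))
  else lower %||% upper
}

# ---- notes / annotations / uncertainty writers ------------------------------

emit_element <- function(push, model, tag, id, attrs, uncert_by_el, annotated, ind) {
  has_children <- id %in% annotated || !is.null(uncert_by_el[[id]])
  if (!has_children) {
    push(ind, "<", tag, attrs, "/>")
    return(invisible(NULL))
  }
  push(ind, "<", tag, attrs, ">")
  emit_notes_annotations(push, model, id, paste0("meta_", id), paste0(ind, "  "))
  emit_uncertainty(push, uncert_by_el[[id]], paste0(ind, "  "))
  push(ind, "</", tag, ">")
}

emit_notes_annotations <- function(push, model, element, metaid, indent) {
  nts <- Filter(function(n) n$element == element, model$notes)
  if (length(nts) > 0) {
    push(indent, "<notes>")
    push(indent, '  <body xmlns="', NS_XHTML, '">')
    push(indent, "    <pre>", xml_escape(nts[[1]]$text), "</pre>")
    push(indent, "  </body>")
    push(indent, "</notes>")
  }
  ann <- Filter(function(a) a$element == element, model$annotations)
  if (length(ann) == 0) return(invisible(NULL))
  ns <- if (element == "model") "bqmodel" else "bqbiol"
  ns_uri <- if (element == "model") NS_BQMODEL else NS_BQBIOL
  quals <- unique(vapply(ann, function(a) a$qualifier, ""))
  quals <- quals[order(match(quals, ALL_QUALIFIERS))]
  push(indent, "<annotation>")
  push(indent, '  <rdf:RDF xmlns:rdf="', NS_RDF, '" xmlns:', ns, '="', ns_uri, '">')
  push(indent, '    <rdf:Description rdf:about="#', metaid, '">')
  for (q in quals) {
    push(indent, "      <", ns, ":", q, ">")
    push(indent, "        <rdf:Bag>")
    uris <- sort(vapply(Filter(function(a) a$qualifier == q, ann),
                        function(a) a$uri, ""))
    for (u in uris) {
      push(indent, '          <rdf:li rdf:resource="', xml_escape(u), '"/>')
    }
    push(indent, "        </rdf:Bag>")
    push(indent, "      </", ns, ":", q, ">")
  }
  push(indent, "    </rdf:Description>")
  push(indent, "  </rdf:RDF>")
  push(indent, "</annotation>")
}

emit_uncertainty <- function(push, stats, indent) {
  if (is.null(stats) || length(stats) == 0) return(invisible(NULL))
  stats <- stats[order(match(vapply(stats, function(u) u$stat, ""), UNCERT_STATS))]
  push(indent, "<distrib:listOfUncertainties>")
  push(indent, "  <distrib:uncertainty>")
  push(indent, "    <distrib:listOfUncertParameters>")
  for (u in stats) {
    if (u$stat == "confidenceInterval") {
      push(indent, '      <distrib:uncertSpan distrib:type="confidenceInterval"',
           ' distrib:valueLower="', fmt_num(u$value[1]),
           '" distrib:valueUpper="', fmt_num(u$value[2]), '"/>')
    } else {
      push(indent, '      <distrib:uncertParameter distrib:type="', u$stat,
           '" distrib:value="', fmt_num(u$value), '"/>')
    }
  }
  push(indent, "    </distrib:listOfUncertParameters>")
  push(indent, "  </distrib:uncertainty>")
  push(indent, "</distrib:listOfUncertainties>")
}

# ---- layout writer ----------------------------------------------------------

emit_layout <- function(push, model) {
  lay <- model$layout
  syms <- model$symbols
  ids <- names(lay$positions)
  ids <- ids[order(match(ids, names(syms)))]
  kind_of <- function(id) symbol_kind(model, id)

  ext <- c(0, 0)
  for (id in ids) {
    p <- lay$positions[[id]]
    s <- lay$sizes[[id]] %||% LAYOUT_DEFAULT_SIZE
    ext <- pmax(ext, p + s)
  }
  for (id in names(lay$curves)) ext <- pmax(ext, apply(matrix(lay$curves[[id]], ncol = 2, byrow = TRUE), 2, max))

  push("    <layout:listOfLayouts>")
  a <- ' layout:id="layout1"'
  push("      <layout:layout", a, ">")
  if (!is.null(lay$style_template)) {
    push("        <annotation>")
    push('          <styleTemplate xmlns="', NS_STYLE_TEMPLATE, '">',
         xml_escape(lay$style_template), "</styleTemplate>")
    push("        </annotation>")
  }
  push('        <layout:dimensions layout:width="', fmt_num(ext[1]),
       '" layout:height="', fmt_num(ext[2]), '"/>')

  emit_bb <- function(id, ind) {
    p <- lay$positions[[id]]
    s <- lay$sizes[[id]] %||% LAYOUT_DEFAULT_SIZE
    push(ind, "<layout:boundingBox>")
    push(ind, '  <layout:position layout:x="', fmt_num(p[1]),
         '" layout:y="', fmt_num(p[2]), '"/>')
    push(ind, '  <layout:dimensions layout:width="', fmt_num(s[1]),
         '" layout:height="', fmt_num(s[2]), '"/>')
    push(ind, "</layout:boundingBox>")
  }

  comp_ids <- ids[vapply(ids, function(i) identical(kind_of(i), "compartment"), TRUE)]
  if (length(comp_ids) > 0) {
    push("        <layout:listOfCompartmentGlyphs>")
    for (id in comp_ids) {
      push('          <layout:compartmentGlyph layout:id="cg_', id,
           '" layout:compartment="', id, '">')
      emit_bb(id, "            ")
      push("          </layout:compartmentGlyph>")
    }
    push("        </layout:listOfCompartmentGlyphs>")
  }

  sp_ids <- ids[vapply(ids, function(i) identical(kind_of(i), "species"), TRUE)]
  if (length(sp_ids) > 0) {
    push("        <layout:listOfSpeciesGlyphs>")
    for (id in sp_ids) {
      push('          <layout:speciesGlyph layout:id="sg_', id,
           '" layout:species="', id, '">')
      emit_bb(id, "            ")
      push("          </layout:speciesGlyph>")
    }
    push("        </layout:listOfSpeciesGlyphs>")
  }

  rxn_ids <- unique(c(
    ids[vapply(ids, function(i) identical(kind_of(i), "reaction"), TRUE)],
    names(lay$curves)
  ))
  rxn_ids <- rxn_ids[order(match(rxn_ids, names(syms)))]
  if (length(rxn_ids) > 0) {
    push("        <layout:listOfReactionGlyphs>")
    for (id in rxn_ids) {
      push('          <layout:reactionGlyph layout:id="rg_', id,
           '" layout:reaction="', id, '">')
      if (!is.null(lay$positions[[id]])) emit_bb(id, "            ")
      pts <- lay$curves[[id]]
      if (!is.null(pts)) {
        push("            <layout:curve>")
        push("              <layout:listOfCurveSegments>")
        np <- length(pts) / 2
        for (k in seq_len(max(np - 1, 0))) {
          x1 <- pts[2 * k - 1]; y1 <- pts[2 * k]
          x2 <- pts[2 * k + 1]; y2 <- pts[2 * k + 2]
          push('                <layout:curveSegment xsi:type="LineSegment">')
          push('                  <layout:start layout:x="', fmt_num(x1),
               '" layout:y="', fmt_num(y1), '"/>')
          push('                  <layout:end layout:x="', fmt_num(x2),
               '" layout:y="', fmt_num(y2), '"/>')
          push("                </layout:curveSegment>")
        }
        push("              </layout:listOfCurveSegments>")
        push("            </layout:curve>")
      }
      push("          </layout:reactionGlyph>")
    }
    push("        </layout:listOfReactionGlyphs>")
  }

  other_ids <- setdiff(ids, c(comp_ids, sp_ids, rxn_ids))
  if (length(other_ids) > 0) {
    push("        <layout:listOfAdditionalGraphicalObjects>")
    for (id in other_ids) {
      push('          <layout:generalGlyph layout:id="gg_', id,
           '" layout:reference="', id, '">')
      emit_bb(id, "            ")
      push("          </layout:generalGlyph>")
    }
    push("        </layout:listOfAdditionalGraphicalObjects>")
  }
  push("      </layout:layout>")
  push("    </layout:listOfLayouts>")
}
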