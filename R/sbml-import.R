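# ---- SBML Level 3 import ----------------------------------------------------

KNOWN_NS <- c(NS_CORE, NS_FBC, NS_DISTRIB, NS_LAYOUT, NS_XSI, NS_RDF,
              NS_BQBIOL, NS_BQMODEL, NS_XHTML, NS_STYLE_TEMPLATE, MATHML_NS)

sbml_err <- function(msg) {
  structure(class = c("rxn_sbml_error", "error", "condition"),
            list(message = msg, call = NULL))
}

# namespace-agnostic child/attr access (prefixes vary between writers)
lchildren <- function(node, name) {
  xml2::xml_find_all(node, paste0("./*[local-name()='", name, "']"))
}
lchild <- function(node, name) {
  out <- lchildren(node, name)
  if (length(out) == 0) NULL else out[[1]]
}
lattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  nm <- names(at)
  hit <- which(nm == name | endsWith(nm, paste0(":", name)))
  if (length(hit) == 0) NA_character_ else unname(at[hit[1]])
}
lattr_num <- function(node, name) {
  v <- lattr(node, name)
  if (is.na(v)) return(NULL)
  if (v %in% c("INF", "Inf")) return(Inf)
  if (v %in% c("-INF", "-Inf")) return(-Inf)
  as.numeric(v)
}
lattr_bool <- function(node, name, default = FALSE) {
  v <- lattr(node, name)
  if (is.na(v)) default else identical(v, "true")
}

#' Import an SBML Level 3 document
#'
#' Parses an SBML Level 3 document (Core plus fbc, distrib and layout
#' packages) into the internal model. Inverse of [sbml_export()] on the
#' supported construct set. Unsupported constructs (unit definitions,
#' function definitions, event delays, unrecognised package namespaces,
#' unsupported math such as `piecewise`) are never silently lost: each is
#' recorded in the `dropped` table. SBML Levels 1 and 2 are rejected with an
#' error naming the level.
#'
#' @param xml character scalar of XML text, or a path to an `.xml` file.
#' @return A list of class `rxn_sbml_import`: `model` ([rxn_model]) and
#'   `dropped` (data frame with columns `construct`, `reason`).
#' @export
sbml_import <- function(xml) {
  doc <- tryCatch(xml2::read_xml(xml), error = function(e) {
    stop(sbml_err(paste0("not well-formed XML: ", conditionMessage(e))))
  })
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml") {
    stop(sbml_err("not an SBML document (root element is not <sbml>)"))
  }
  level <- lattr(root, "level")
  if (is.na(level) || level != "3") {
    stop(sbml_err(paste0("unsupported SBML level ", level %||% "?",
                         "; only Level 3 is supported")))
  }

  dropped <- data.frame(construct = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop_it <- function(construct, reason) {
    dropped <<- rbind(dropped, data.frame(construct = construct, reason = reason,
                                          stringsAsFactors = FALSE))
  }

  for (uri in unique(unname(xml2::xml_ns(doc)))) {
    if (!(uri %in% KNOWN_NS) && !grepl("level3/version[12]/core", uri)) {
      drop_it(paste0("namespace ", uri), "unrecognized package namespace")
    }
  }

  mnode <- lchild(root, "model")
  if (is.null(mnode)) stop(sbml_err("document has no <model> element"))
  model <- rxn_model(lattr(mnode, "id") %||% "__main")

  try_math <- function(node, what) {
    if (is.null(node)) return(NULL)
    mm <- lchild(node, "math")
    if (is.null(mm)) return(NULL)
    tryCatch(math_from_mathml(mm), rxn_mathml_error = function(e) {
      drop_it(what, conditionMessage(e))
      NULL
    })
  }

  # metaid -> element id map for annotation resolution
  meta_map <- c()
  register_meta <- function(node, id) {
    mid <- lattr(node, "metaid")
    if (!is.na(mid)) meta_map[[mid]] <<- id
  }
  register_meta(mnode, "model")

  read_uncertainty <- function(node, id) {
    lu <- lchild(node, "listOfUncertainties")
    if (is.null(lu)) return(invisible(NULL))
    for (un in lchildren(lu, "uncertainty")) {
      lup <- lchild(un, "listOfUncertParameters")
      if (is.null(lup)) next
      for (up in xml2::xml_children(lup)) {
        type <- lattr(up, "type")
        if (identical(type, "confidenceInterval")) {
          lo <- lattr_num(up, "valueLower")
          hi <- lattr_num(up, "valueUpper")
          model$uncertainty[[length(model$uncertainty) + 1L]] <-
            list(element = id, stat = "confidenceInterval", value = c(lo, hi), line = 1L)
        } else if (type %in% c("mean", "standardDeviation", "variance")) {
          model$uncertainty[[length(model$uncertainty) + 1L]] <-
            list(element = id, stat = type, value = lattr_num(up, "value"), line = 1L)
        } else {
          drop_it(paste0("uncertParameter type ", type %||% "?"),
                  "unsupported uncertainty statistic")
        }
      }
    }
  }

  # -- compartments -----------------------------------------------------------
  lc <- lchild(mnode, "listOfCompartments")
  default_comp_seen <- FALSE
  if (!is.null(lc)) {
    for (cp in lchildren(lc, "compartment")) {
      id <- lattr(cp, "id")
      if (identical(id, "default_compartment")) { default_comp_seen <- TRUE; next }
      rxn_declare(model, id, "compartment", explicit = TRUE)
      if (lattr_bool(cp, "constant")) set_symbol_field(model, id, "is_const", TRUE)
      sz <- lattr_num(cp, "size")
      if (!is.null(sz)) set_symbol_field(model, id, "initial_value", sz)
      register_meta(cp, id)
      read_uncertainty(cp, id)
    }
  }

  # -- species ----------------------------------------------------------------
  ls <- lchild(mnode, "listOfSpecies")
  if (!is.null(ls)) {
    for (sp in lchildren(ls, "species")) {
      id <- lattr(sp, "id")
      rxn_declare(model, id, "species", explicit = TRUE)
      comp <- lattr(sp, "compartment")
      if (!is.na(comp) && comp != "default_compartment") {
        if (is.null(model$symbols[[comp]])) rxn_declare(model, comp, "compartment")
        set_symbol_field(model, id, "compartment", comp)
      }
      amt <- lattr_bool(sp, "hasOnlySubstanceUnits")
      if (amt) set_symbol_field(model, id, "substance_only", TRUE)
      if (lattr_bool(sp, "boundaryCondition")) set_symbol_field(model, id, "is_boundary", TRUE)
      if (lattr_bool(sp, "constant")) set_symbol_field(model, id, "is_const", TRUE)
      iv <- if (amt) lattr_num(sp, "initialAmount") else lattr_num(sp, "initialConcentration")
      if (is.null(iv)) {
        iv <- lattr_num(sp, "initialAmount") %||% lattr_num(sp, "initialConcentration")
        if (is.numeric(iv) && length(iv) == 0) iv <- NULL
      }
      if (!is.null(iv) && length(iv) == 1) set_symbol_field(model, id, "initial_value", iv)
      register_meta(sp, id)
      read_uncertainty(sp, id)
    }
  }

  # -- flux-bound parameter ids (consumed by reaction attributes) -------------
  bound_ids <- character(0)
  lr <- lchild(mnode, "listOfReactions")
  if (!is.null(lr)) {
    for (rx in lchildren(lr, "reaction")) {
      for (at in c("lowerFluxBound", "upperFluxBound")) {
        v <- lattr(rx, at)
        if (!is.na(v)) bound_ids <- c(bound_ids, v)
      }
    }
  }
  par_values <- list()

  lp <- lchild(mnode, "listOfParameters")
  if (!is.null(lp)) {
    for (pr in lchildren(lp, "parameter")) {
      id <- lattr(pr, "id")
      par_values[[id]] <- lattr_num(pr, "value")
      if (id %in% bound_ids) next
      rxn_declare(model, id, "parameter", explicit = TRUE)
      if (lattr_bool(pr, "constant")) set_symbol_field(model, id, "is_const", TRUE)
      v <- lattr_num(pr, "value")
      if (!is.null(v)) set_symbol_field(model, id, "initial_value", v)
      register_meta(pr, id)
      read_uncertainty(pr, id)
    }
  }

  # -- reactions --------------------------------------------------------------
  if (!is.null(lr)) {
    for (rx in lchildren(lr, "reaction")) {
      id <- lattr(rx, "id")
      rxn_declare(model, id, "reaction")
      read_side <- function(list_name) {
        side <- lchild(rx, list_name)
        refs <- list()
        if (is.null(side)) return(refs)
        for (sr in lchildren(side, "speciesReference")) {
          sp <- lattr(sr, "species")
          if (is.null(model$symbols[[sp]])) rxn_declare(model, sp, "species")
          sid <- lattr(sr, "id")
          if (!is.na(sid)) {
            rxn_declare(model, sid, "stoichiometry")
            refs[[length(refs) + 1L]] <- species_ref(sp, stoich_id = sid)
          } else {
            st <- lattr_num(sr, "stoichiometry") %||% 1
            refs[[length(refs) + 1L]] <- species_ref(sp, stoich = st)
          }
        }
        refs
      }
      reactants <- read_side("listOfReactants")
      products <- read_side("listOfProducts")
      if (!is.null(lchild(rx, "listOfModifiers"))) {
        drop_it(paste0("modifiers of reaction ", id), "modifier species are not supported")
      }
      kl <- lchild(rx, "kineticLaw")
      km <- try_math(kl, paste0("kinetic law of ", id))
      if (!is.null(kl) && !is.null(lchild(kl, "listOfLocalParameters"))) {
        drop_it(paste0("local parameters of reaction ", id),
                "local parameters are not supported")
      }
      if (!is.null(km)) declare_math_refs(model, km)
      auto <- grepl(AUTO_ID_RE, id)
      model$reactions[[length(model$reactions) + 1L]] <-
        new_reaction(id, reactants, products, kinetic_math = km,
                     reversible = lattr_bool(rx, "reversible", default = TRUE),
                     auto_id = auto)
      lb_ref <- lattr(rx, "lowerFluxBound")
      ub_ref <- lattr(rx, "upperFluxBound")
      if (!is.na(lb_ref) || !is.na(ub_ref)) {
        lb <- if (!is.na(lb_ref)) par_values[[lb_ref]] else -Inf
        ub <- if (!is.na(ub_ref)) par_values[[ub_ref]] else Inf
        model$flux_bounds[[length(model$flux_bounds) + 1L]] <-
          list(reaction = id, lower = lb %||% -Inf, upper = ub %||% Inf, line = 1L)
      }
      register_meta(rx, id)
      read_uncertainty(rx, id)
    }
  }

  # -- initial assignments ----------------------------------------------------
  lia <- lchild(mnode, "listOfInitialAssignments")
  if (!is.null(lia)) {
    for (ia in lchildren(lia, "initialAssignment")) {
      tgt <- lattr(ia, "symbol")
      mathn <- try_math(ia, paste0("initial assignment of ", tgt))
      if (is.null(mathn)) next
      if (is.null(model$symbols[[tgt]])) rxn_declare(model, tgt, "parameter")
      if (identical(symbol_kind(model, tgt), "stoichiometry") && math_is_number(mathn)) {
        set_symbol_field(model, tgt, "initial_value", math_number_value(mathn))
      } else {
        declare_math_refs(model, mathn)
        model$initial_assignments[[length(model$initial_assignments) + 1L]] <-
          list(target = tgt, math = mathn, line = 1L)
      }
    }
  }

  # -- rules ------------------------------------------------------------------
  lrul <- lchild(mnode, "listOfRules")
  if (!is.null(lrul)) {
    for (ru in xml2::xml_children(lrul)) {
      nm <- xml2::xml_name(ru)
      mathn <- try_math(ru, nm)
      if (is.null(mathn)) next
      declare_math_refs(model, mathn)
      if (nm == "algebraicRule") {
        rid <- lattr(ru, "id")
        if (!is.na(rid)) rxn_declare(model, rid, "rule")
        model$rules[[length(model$rules) + 1L]] <-
          new_rule("algebraic", math = mathn, id = if (is.na(rid)) NULL else rid)
      } else if (nm %in% c("assignmentRule", "rateRule")) {
        tgt <- lattr(ru, "variable")
        if (is.null(model$symbols[[tgt]])) rxn_declare(model, tgt, "parameter")
        model$rules[[length(model$rules) + 1L]] <-
          new_rule(if (nm == "assignmentRule") "assignment" else "rate",
                   target = tgt, math = mathn)
      } else {
        drop_it(nm, "unsupported rule type")
      }
    }
  }

  # -- constraints ------------------------------------------------------------
  lcn <- lchild(mnode, "listOfConstraints")
  if (!is.null(lcn)) {
    for (cn in lchildren(lcn, "constraint")) {
      mathn <- try_math(cn, "constraint")
      if (is.null(mathn)) next
      rec <- decompose_constraint(mathn)
      if (is.null(rec)) {
        drop_it("constraint", "math is not a bound comparison on one symbol")
        next
      }
      if (is.null(model$symbols[[rec$symbol]])) rxn_declare(model, rec$symbol, "parameter")
      declare_math_refs(model, if (is.list(rec$lower)) rec$lower)
      declare_math_refs(model, if (is.list(rec$upper)) rec$upper)
      rec$line <- 1L
      model$constraints[[length(model$constraints) + 1L]] <- rec
    }
  }

  # -- events -----------------------------------------------------------------
  le <- lchild(mnode, "listOfEvents")
  if (!is.null(le)) {
    for (ev in lchildren(le, "event")) {
      id <- lattr(ev, "id")
      if (is.na(id)) id <- next_auto_event_id(model)
      rxn_declare(model, id, "event")
      tr <- lchild(ev, "trigger")
      trig_math <- try_math(tr, paste0("trigger of ", id)) %||% m_num(1)
      if (!is.null(lchild(ev, "delay"))) {
        drop_it(paste0("delay of event ", id), "event delays are not supported")
      }
      prio <- try_math(lchild(ev, "priority"), paste0("priority of ", id))
      assignments <- list()
      lea <- lchild(ev, "listOfEventAssignments")
      if (!is.null(lea)) {
        for (ea in lchildren(lea, "eventAssignment")) {
          tgt <- lattr(ea, "variable")
          am <- try_math(ea, paste0("assignment of ", id))
          if (is.null(am)) next
          if (is.null(model$symbols[[tgt]])) rxn_declare(model, tgt, "parameter")
          declare_math_refs(model, am)
          assignments[[length(assignments) + 1L]] <- list(target = tgt, math = am)
        }
      }
      declare_math_refs(model, trig_math)
      declare_math_refs(model, prio)
      e <- new_event(id, trig_math, assignments, priority = prio,
                     auto_id = grepl(AUTO_ID_RE, id))
      if (!is.null(tr)) {
        e$persistent <- lattr_bool(tr, "persistent", default = TRUE)
        e$initial_value_trigger <- lattr_bool(tr, "initialValue", default = TRUE)
      }
      e$use_values_from_trigger_time <-
        lattr_bool(ev, "useValuesFromTriggerTime", default = TRUE)
      model$events[[length(model$events) + 1L]] <- e
    }
  }

  # -- fbc objectives ---------------------------------------------------------
  lob <- lchild(mnode, "listOfObjectives")
  if (!is.null(lob)) {
    obj_ids <- character(0)
    for (ob in lchildren(lob, "objective")) {
      sense <- lattr(ob, "type")
      obj_ids <- c(obj_ids, lattr(ob, "id"))
      terms <- list()
      lfo <- lchild(ob, "listOfFluxObjectives")
      if (!is.null(lfo)) {
        for (fo in lchildren(lfo, "fluxObjective")) {
          rid <- lattr(fo, "reaction")
          rxn_declare(model, rid, "reaction")
          terms[[length(terms) + 1L]] <-
            list(coef = lattr_num(fo, "coefficient") %||% 1, reaction = rid)
        }
      }
      model$objectives[[length(model$objectives) + 1L]] <-
        list(sense = sense, terms = terms, line = 1L)
    }
    act <- lattr(lob, "activeObjective")
    if (!is.na(act) && length(obj_ids) > 0 && !identical(act, obj_ids[1])) {
      drop_it(paste0("activeObjective ", act),
              "only the first declared objective is treated as active")
    }
  }

  # -- layout -----------------------------------------------------------------
  ll <- lchild(mnode, "listOfLayouts")
  if (!is.null(ll)) {
    model$layout$enabled <- TRUE
    lay_node <- lchild(ll, "layout")
    if (!is.null(lay_node)) import_layout(model, lay_node)
  }

  # -- notes and RDF annotations ----------------------------------------------
  import_notes_annotations(model, mnode, meta_map, drop_it)

  # -- unsupported model children ---------------------------------------------
  known <- c("listOfCompartments", "listOfSpecies", "listOfParameters",
             "listOfInitialAssignments", "listOfRules", "listOfConstraints",
             "listOfReactions", "listOfEvents", "listOfObjectives",
             "listOfLayouts", "notes", "annotation")
  for (ch in xml2::xml_children(mnode)) {
    nm <- xml2::xml_name(ch)
    if (nm %in% known) next
    reason <- switch(nm,
      listOfUnitDefinitions = "unit definitions are not supported",
      listOfFunctionDefinitions = "function definitions are not supported",
      listOfSubmodels = "hierarchical submodels are not supported",
      listOfGeneProducts = "fbc gene products are not supported",
      "unsupported model construct")
    drop_it(nm, reason)
  }

  finalize_model(model)
  structure(list(model = model, dropped = dropped), class = "rxn_sbml_import")
}

#' @export
print.rxn_sbml_import <- function(x, ...) {
  print(x$model)
  if (nrow(x$dropped) > 0) {
    cat("dropped constructs:\n")
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("  - %s: %s\n", x$dropped$construct[i], x$dropped$reason[i]))
    }
  }
  invisible(x)
}

# lower/upper comparisons (possibly conjoined) back to a constraint record
decompose_constraint <- function(node) {
  cmps <- if (node$kind == "bool" && node$op == "and") node$args else list(node)
  rec <- list(symbol = NULL, lower = NULL, upper = NULL,
              strict_lower = FALSE, strict_upper = FALSE)
  for (cmp in cmps) {
    if (cmp$kind != "cmp" || !(cmp$op %in% c("<", "<=", ">", ">="))) return(NULL)
    left <- cmp$left; right <- cmp$right; op <- cmp$op
    if (op %in% c(">", ">=")) {
      tmp <- left; left <- right; right <- tmp
      op <- if (op == ">") "<" else "<="
    }
    # now left (op) right with op in {<, <=}
    if (right$kind == "sym" && left$kind != "sym") {
      sym <- right$id
      if (!is.null(rec$symbol) && rec$symbol != sym) return(NULL)
      rec$symbol <- sym
      rec$lower <- if (left$kind == "num") left$value else left
      rec$strict_lower <- op == "<"
    } else if (left$kind == "sym") {
      sym <- left$id
      if (!is.null(rec$symbol) && rec$symbol != sym) return(NULL)
      rec$symbol <- sym
      rec$upper <- if (right$kind == "num") right$value else right
      rec$strict_upper <- op == "<"
    } else return(NULL)
  }
  if (is.null(rec$symbol)) return(NULL)
  rec
}

import_layout <- function(model, lay_node) {
  read_bb <- function(glyph, id) {
    bb <- lchild(glyph, "boundingBox")
    if (is.null(bb)) return(invisible(NULL))
    pos <- lchild(bb, "position")
    dim <- lchild(bb, "dimensions")
    if (!is.null(pos)) {
      model$layout$positions[[id]] <- c(lattr_num(pos, "x") %||% 0,
                                        lattr_num(pos, "y") %||% 0)
    }
    if (!is.null(dim)) {
      model$layout$sizes[[id]] <- c(lattr_num(dim, "width") %||% 0,
                                    lattr_num(dim, "height") %||% 0)
    }
  }
  for (spec in list(c("listOfCompartmentGlyphs", "compartmentGlyph", "compartment"),
                    c("listOfSpeciesGlyphs", "speciesGlyph", "species"))) {
    lst <- lchild(lay_node, spec[1])
    if (is.null(lst)) next
    for (g in lchildren(lst, spec[2])) {
      id <- lattr(g, spec[3])
      if (is.na(id)) next
      read_bb(g, id)
    }
  }
  lst <- lchild(lay_node, "listOfReactionGlyphs")
  if (!is.null(lst)) {
    for (g in lchildren(lst, "reactionGlyph")) {
      id <- lattr(g, "reaction")
      if (is.na(id)) next
      read_bb(g, id)
      cv <- lchild(g, "curve")
      if (!is.null(cv)) {
        segs <- lchild(cv, "listOfCurveSegments")
        pts <- numeric(0)
        if (!is.null(segs)) {
          for (seg in lchildren(segs, "curveSegment")) {
            st <- lchild(seg, "start"); en <- lchild(seg, "end")
            if (length(pts) == 0 && !is.null(st)) {
              pts <- c(lattr_num(st, "x") %||% 0, lattr_num(st, "y") %||% 0)
            }
            if (!is.null(en)) {
              pts <- c(pts, lattr_num(en, "x") %||% 0, lattr_num(en, "y") %||% 0)
            }
          }
        }
        if (length(pts) > 0) model$layout$curves[[id]] <- pts
      }
    }
  }
  lst <- lchild(lay_node, "listOfAdditionalGraphicalObjects")
  if (!is.null(lst)) {
    for (g in lchildren(lst, "generalGlyph")) {
      id <- lattr(g, "reference")
      if (is.na(id)) next
      read_bb(g, id)
    }
  }
  ann <- lchild(lay_node, "annotation")
  if (!is.null(ann)) {
    st <- lchild(ann, "styleTemplate")
    if (!is.null(st)) model$layout$style_template <- xml2::xml_text(st)
  }
}

import_notes_annotations <- function(model, mnode, meta_map, drop_it) {
  read_notes <- function(node, element) {
    nt <- lchild(node, "notes")
    if (is.null(nt)) return(invisible(NULL))
    pre <- xml2::xml_find_first(nt, ".//*[local-name()='pre']")
    txt <- if (inherits(pre, "xml_node")) xml2::xml_text(pre)
           else trimws(xml2::xml_text(nt))
    model$notes[[length(model$notes) + 1L]] <-
      list(element = element, text = txt, line = 1L)
  }
  read_cv <- function(node, element) {
    ann <- lchild(node, "annotation")
    if (is.null(ann)) return(invisible(NULL))
    rdfs <- xml2::xml_find_all(ann, ".//*[local-name()='RDF']")
    for (rdf in rdfs) {
      for (desc in xml2::xml_find_all(rdf, ".//*[local-name()='Description']")) {
        for (q in xml2::xml_children(desc)) {
          qual <- xml2::xml_name(q)
          uris <- xml2::xml_attr(
            xml2::xml_find_all(q, ".//*[local-name()='li']"), "resource")
          for (u in uris[!is.na(uris)]) {
            if (!(qual %in% ALL_QUALIFIERS)) {
              drop_it(paste0("annotation qualifier ", qual), "unknown qualifier")
              next
            }
            model$annotations[[length(model$annotations) + 1L]] <-
              list(element = element, qualifier = qual, uri = u, line = 1L)
          }
        }
      }
    }
  }
  read_notes(mnode, "model")
  read_cv(mnode, "model")
  for (lst in c("listOfCompartments", "listOfSpecies", "listOfParameters",
                "listOfReactions")) {
    ln <- lchild(mnode, lst)
    if (is.null(ln)) next
    for (el in xml2::xml_children(ln)) {
      id <- lattr(el, "id")
      if (is.na(id) || is.null(model$symbols[[id]])) next
      read_notes(el, id)
      read_cv(el, id)
    }
  }
  invisible(NULL)
}
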