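# ---- structural document check ----------------------------------------------

KNOWN_CSYMBOL_URLS <- c(URL_TIME, URL_RATEOF,
                        paste0(URL_DISTRIB_BASE, names(DRAW_FUNCTIONS)))

#' Structurally check an SBML document
#'
#' A lightweight structural self-check of SBML Level 3 documents: verifies
#' the core namespace and level, package namespace URIs, model presence,
#' id uniqueness across compartments/species/parameters/reactions/events,
#' the required Level 3 attributes (species `compartment`,
#' `boundaryCondition`, `hasOnlySubstanceUnits` and `constant`; parameter
#' and compartment `constant`), that species compartment references resolve,
#' and that every `csymbol` definition URL is one of the supported symbols
#' (time, rateOf, distribution draws). This is not a full SBML validator.
#'
#' @param xml character scalar of XML text, or a path to an `.xml` file.
#' @return A diagnostics data frame (`severity`, `line`, `message`);
#'   zero rows when the document passes.
#' @export
sbml_check <- function(xml) {
  d <- diag_df()
  doc <- tryCatch(xml2::read_xml(xml), error = function(e) NULL)
  if (is.null(doc)) return(diag_add(d, "error", 1L, "not well-formed XML"))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml") {
    return(diag_add(d, "error", 1L, "root element is not <sbml>"))
  }
  ns <- unique(unname(xml2::xml_ns(doc)))
  if (!any(grepl("sbml/level3", ns))) {
    d <- diag_add(d, "error", 1L, "missing SBML Level 3 core namespace")
  }
  if (!identical(lattr(root, "level"), "3")) {
    d <- diag_add(d, "error", 1L, "level attribute is not 3")
  }
  mnode <- lchild(root, "model")
  if (is.null(mnode)) {
    return(diag_add(d, "error", 1L, "document has no <model> element"))
  }

  ids <- character(0)
  collect <- function(list_name, el_name) {
    ln <- lchild(mnode, list_name)
    if (is.null(ln)) return(invisible(NULL))
    for (el in lchildren(ln, el_name)) {
      id <- lattr(el, "id")
      if (!is.na(id)) ids <<- c(ids, id)
    }
  }
  collect("listOfCompartments", "compartment")
  collect("listOfSpecies", "species")
  collect("listOfParameters", "parameter")
  collect("listOfReactions", "reaction")
  collect("listOfEvents", "event")
  dup <- unique(ids[duplicated(ids)])
  for (id in dup) {
    d <- diag_add(d, "error", 1L, sprintf("duplicate id '%s'", id))
  }

  comp_ids <- character(0)
  lc <- lchild(mnode, "listOfCompartments")
  if (!is.null(lc)) {
    for (cp in lchildren(lc, "compartment")) {
      id <- lattr(cp, "id") %||% "?"
      comp_ids <- c(comp_ids, id)
      if (is.na(lattr(cp, "constant"))) {
        d <- diag_add(d, "error", 1L,
                      sprintf("compartment '%s' missing required 'constant'", id))
      }
    }
  }
  ls <- lchild(mnode, "listOfSpecies")
  if (!is.null(ls)) {
    for (sp in lchildren(ls, "species")) {
      id <- lattr(sp, "id") %||% "?"
      comp <- lattr(sp, "compartment")
      if (is.na(comp)) {
        d <- diag_add(d, "error", 1L,
                      sprintf("species '%s' missing required 'compartment'", id))
      } else if (!(comp %in% comp_ids)) {
        d <- diag_add(d, "error", 1L, sprintf(
          "species '%s' references unknown compartment '%s'", id, comp))
      }
      for (at in c("hasOnlySubstanceUnits", "boundaryCondition", "constant")) {
        if (is.na(lattr(sp, at))) {
          d <- diag_add(d, "error", 1L,
                        sprintf("species '%s' missing required '%s'", id, at))
        }
      }
    }
  }
  lp <- lchild(mnode, "listOfParameters")
  if (!is.null(lp)) {
    for (pr in lchildren(lp, "parameter")) {
      if (is.na(lattr(pr, "constant"))) {
        d <- diag_add(d, "error", 1L, sprintf(
          "parameter '%s' missing required 'constant'", lattr(pr, "id") %||% "?"))
      }
    }
  }

  for (cs in xml2::xml_find_all(doc, "//*[local-name()='csymbol']")) {
    url <- xml2::xml_attr(cs, "definitionURL")
    if (is.na(url) || !(url %in% KNOWN_CSYMBOL_URLS)) {
      d <- diag_add(d, "error", 1L,
                    sprintf("unknown csymbol definitionURL '%s'", url %||% "?"))
    }
  }
  d
}
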