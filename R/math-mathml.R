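# ---- content MathML conversion ----------------------------------------------

MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
URL_TIME <- "http://www.sbml.org/sbml/symbols/time"
URL_RATEOF <- "http://www.sbml.org/sbml/symbols/rateOf"
URL_DISTRIB_BASE <- "http://www.sbml.org/sbml/symbols/distrib/"

# text-level MathML writer: deterministic byte output, no pretty printing
# beyond the fixed single-space token layout inside cn/ci/csymbol.

mathml_fn_element <- c(
  abs = "abs", exp = "exp", ln = "ln", log10 = "log", sqrt = "root",
  sin = "sin", cos = "cos", tan = "tan",
  asin = "arcsin", acos = "arccos", atan = "arctan",
  sinh = "sinh", cosh = "cosh", tanh = "tanh",
  floor = "floor", ceiling = "ceiling"
)
mathml_op_element <- c(
  "+" = "plus", "-" = "minus", "*" = "times", "/" = "divide", "^" = "power",
  "<" = "lt", "<=" = "leq", ">" = "gt", ">=" = "geq", "==" = "eq", "!=" = "neq"
)

#' Convert a math node to content MathML
#'
#' Emits SBML-flavoured content MathML: simulation time and `rateOf` become
#' `csymbol` elements with their SBML Level 3 definition URLs, and
#' distribution-draw functions become `csymbol` elements with the
#' Distributions-package definition URLs.
#'
#' @param node a math node.
#' @param wrap include the `<math>` wrapper element (default `TRUE`).
#' @return character scalar of XML text.
#' @examples
#' math_to_mathml(math_parse("rateOf(G)"))
#' @export
#' @seealso [math_from_mathml()]
math_to_mathml <- function(node, wrap = TRUE) {
  body <- ml_emit(node)
  if (wrap) paste0('<math xmlns="', MATHML_NS, '">', body, "</math>") else body
}

ml_cn <- function(value) {
  if (!is.finite(value)) {
    if (value > 0) return("<infinity/>")
    return("<apply><minus/><infinity/></apply>")
  }
  s <- fmt_num(value)
  if (grepl("[eE]", s)) {
    parts <- strsplit(s, "[eE]", fixed = FALSE)[[1]]
    ex <- sub("^\\+", "", parts[2])
    return(paste0('<cn type="e-notation">', parts[1], "<sep/>", ex, "</cn>"))
  }
  if (grepl("^-?[0-9]+$", s)) {
    return(paste0('<cn type="integer">', s, "</cn>"))
  }
  paste0("<cn>", s, "</cn>")
}

ml_emit <- function(n) {
  switch(n$kind,
    num = ml_cn(n$value),
    sym = paste0("<ci>", n$id, "</ci>"),
    time = paste0('<csymbol encoding="text" definitionURL="', URL_TIME, '">time</csymbol>'),
    neg = paste0("<apply><minus/>", ml_emit(n$x), "</apply>"),
    binop = paste0("<apply><", mathml_op_element[[n$op]], "/>",
                   ml_emit(n$left), ml_emit(n$right), "</apply>"),
    cmp = paste0("<apply><", mathml_op_element[[n$op]], "/>",
                 ml_emit(n$left), ml_emit(n$right), "</apply>"),
    bool = paste0("<apply><", n$op, "/>",
                  paste(vapply(n$args, ml_emit, ""), collapse = ""), "</apply>"),
    call = ml_emit_call(n),
    stop("unsupported node kind '", n$kind, "'", call. = FALSE)
  )
}

ml_emit_call <- function(n) {
  args <- paste(vapply(n$args, ml_emit, ""), collapse = "")
  if (n$fn == "rateOf") {
    return(paste0('<apply><csymbol encoding="text" definitionURL="', URL_RATEOF,
                  '">rateOf</csymbol>', args, "</apply>"))
  }
  if (n$fn %in% names(DRAW_FUNCTIONS)) {
    return(paste0('<apply><csymbol encoding="text" definitionURL="',
                  URL_DISTRIB_BASE, n$fn, '">', n$fn, "</csymbol>", args, "</apply>"))
  }
  el <- mathml_fn_element[[n$fn]]
  paste0("<apply><", el, "/>", args, "</apply>")
}

# ---- MathML reader ----------------------------------------------------------

mathml_err <- function(msg) {
  structure(
    class = c("rxn_mathml_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

#' Convert content MathML to a math node
#'
#' Inverse of [math_to_mathml()] on the supported construct set. Unsupported
#' MathML elements (e.g. `piecewise`, `lambda`, the `delay` csymbol) raise an
#' error naming the element.
#'
#' @param xml character scalar of XML text, or an `xml2` node.
#' @return A math node.
#' @export
math_from_mathml <- function(xml) {
  node <- if (inherits(xml, "xml_node")) xml else xml2::read_xml(xml)
  if (xml2::xml_name(node) == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1) stop(mathml_err("math element must have exactly one child"))
    node <- kids[[1]]
  }
  ml_read(node)
}

ml_read <- function(el) {
  name <- xml2::xml_name(el)
  switch(name,
    infinity = m_num(Inf),
    cn = ml_read_cn(el),
    ci = m_sym(trimws(xml2::xml_text(el))),
    csymbol = {
      url <- xml2::xml_attr(el, "definitionURL")
      if (identical(url, URL_TIME)) return(m_time())
      stop(mathml_err(paste0("bare csymbol with definitionURL '", url, "' is not supported")))
    },
    apply = ml_read_apply(el),
    stop(mathml_err(paste0("unsupported MathML element '", name, "'")))
  )
}

ml_read_cn <- function(el) {
  type <- xml2::xml_attr(el, "type")
  if (!is.na(type) && type == "e-notation") {
    kids <- xml2::xml_contents(el)
    txt <- vapply(kids, function(k) trimws(xml2::xml_text(k)), "")
    txt <- txt[nzchar(txt)]
    if (length(txt) != 2) stop(mathml_err("malformed e-notation cn"))
    return(m_num(as.numeric(paste0(txt[1], "e", txt[2]))))
  }
  if (!is.na(type) && !(type %in% c("integer", "real"))) {
    stop(mathml_err(paste0("unsupported cn type '", type, "'")))
  }
  v <- suppressWarnings(as.numeric(trimws(xml2::xml_text(el))))
  if (is.na(v)) stop(mathml_err("malformed cn value"))
  m_num(v)
}

ml_read_apply <- function(el) {
  kids <- xml2::xml_children(el)
  if (length(kids) < 1) stop(mathml_err("empty apply"))
  head <- kids[[1]]
  args <- lapply(kids[-1], ml_read)
  hname <- xml2::xml_name(head)

  if (hname == "csymbol") {
    url <- xml2::xml_attr(head, "definitionURL")
    if (identical(url, URL_RATEOF)) {
      if (length(args) != 1 || args[[1]]$kind != "sym") {
        stop(mathml_err("rateOf requires a single ci argument"))
      }
      return(m_call("rateOf", args))
    }
    if (startsWith(url %||% "", URL_DISTRIB_BASE)) {
      fn <- substring(url, nchar(URL_DISTRIB_BASE) + 1L)
      if (!(fn %in% names(DRAW_FUNCTIONS))) {
        stop(mathml_err(paste0("unsupported distribution csymbol '", fn, "'")))
      }
      if (length(args) != DRAW_FUNCTIONS[[fn]]) {
        stop(mathml_err(paste0(fn, " has wrong arity")))
      }
      return(m_call(fn, args))
    }
    stop(mathml_err(paste0("unsupported csymbol definitionURL '", url, "'")))
  }

  op <- names(mathml_op_element)[match(hname, mathml_op_element)]
  if (!is.na(op)) {
    if (op == "-" && length(args) == 1) return(m_neg(args[[1]]))
    if (op %in% c("+", "*") && length(args) > 2) {
      node <- args[[1]]
      for (a in args[-1]) node <- m_binop(op, node, a)
      return(node)
    }
    if (length(args) != 2) stop(mathml_err(paste0("'", hname, "' needs two operands")))
    if (op %in% c("+", "-", "*", "/", "^")) return(m_binop(op, args[[1]], args[[2]]))
    return(m_cmp(op, args[[1]], args[[2]]))
  }

  if (hname %in% c("and", "or")) {
    if (length(args) < 2) stop(mathml_err(paste0("'", hname, "' needs >= 2 operands")))
    return(m_bool(hname, args))
  }
  if (hname == "not") {
    if (length(args) != 1) stop(mathml_err("'not' needs one operand"))
    return(m_bool("not", args))
  }

  fn <- names(mathml_fn_element)[match(hname, mathml_fn_element)]
  if (!is.na(fn)) {
    if (length(args) != 1) stop(mathml_err(paste0("'", hname, "' needs one operand")))
    return(m_call(fn, args))
  }
  stop(mathml_err(paste0("unsupported MathML element '", hname, "'")))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
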