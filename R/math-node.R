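# ---- expression tree constructors -------------------------------------------
# A math node is a plain list with a `kind` field:
#   num  : value (double)
#   sym  : id (character)
#   time : (simulation time csymbol)
#   binop: op %in% c("+","-","*","/","^"), left, right
#   neg  : x
#   cmp  : op %in% c("<","<=",">",">=","==","!="), left, right
#   bool : op %in% c("and","or","not"), args (list; `not` has exactly one)
#   call : fn (character), args (list)

#' Construct math expression nodes
#'
#' Low-level constructors for the expression tree used in rate laws, rules,
#' event triggers/priorities and initial assignments. Most users should build
#' trees with [math_parse()] instead.
#'
#' @param value numeric scalar.
#' @param id symbol identifier.
#' @param op operator name.
#' @param left,right,x child nodes.
#' @param args list of child nodes.
#' @param fn function name (a standard math function, a distribution draw
#'   such as `uniform`, or `rateOf`).
#' @return A math node (plain list with a `kind` field).
#' @name math_node
NULL

#' @rdname math_node
#' @export
m_num <- function(value) list(kind = "num", value = as.numeric(value))

#' @rdname math_node
#' @export
m_sym <- function(id) list(kind = "sym", id = as.character(id))

#' @rdname math_node
#' @export
m_time <- function() list(kind = "time")

#' @rdname math_node
#' @export
m_binop <- function(op, left, right) {
  stopifnot(op %in% c("+", "-", "*", "/", "^"))
  list(kind = "binop", op = op, left = left, right = right)
}

#' @rdname math_node
#' @export
m_neg <- function(x) list(kind = "neg", x = x)

#' @rdname math_node
#' @export
m_cmp <- function(op, left, right) {
  stopifnot(op %in% c("<", "<=", ">", ">=", "==", "!="))
  list(kind = "cmp", op = op, left = left, right = right)
}

#' @rdname math_node
#' @export
m_bool <- function(op, args) {
  stopifnot(op %in% c("and", "or", "not"))
  if (op == "not") stopifnot(length(args) == 1L)
  list(kind = "bool", op = op, args = args)
}

#' @rdname math_node
#' @export
m_call <- function(fn, args) list(kind = "call", fn = fn, args = args)

# Distribution draw functions and their arity (two-parameter call forms;
# normal takes a standard deviation, lognormal log-scale mu/sigma).
DRAW_FUNCTIONS <- c(
  normal = 2L, uniform = 2L, lognormal = 2L, exponential = 1L,
  gamma = 2L, poisson = 1L, binomial = 2L
)

# Standard (non-draw) math functions supported in expressions and MathML.
MATH_FUNCTIONS <- c(
  "abs", "exp", "ln", "log10", "sqrt",
  "sin", "cos", "tan", "asin", "acos", "atan",
  "sinh", "cosh", "tanh", "floor", "ceiling"
)

is_draw_call <- function(node) {
  node$kind == "call" && node$fn %in% names(DRAW_FUNCTIONS)
}

#' Does an expression contain a distribution draw?
#' @param node a math node.
#' @return logical scalar.
#' @export
math_has_draw <- function(node) {
  if (is.null(node)) return(FALSE)
  switch(node$kind,
    num = , sym = , time = FALSE,
    binop = , cmp = math_has_draw(node$left) || math_has_draw(node$right),
    neg = math_has_draw(node$x),
    bool = any(vapply(node$args, math_has_draw, logical(1))),
    call = is_draw_call(node) ||
      any(vapply(node$args, math_has_draw, logical(1))),
    FALSE
  )
}

# All symbol ids referenced in a tree (excluding rateOf's `time`; `time` is
# a csymbol, not a symbol reference).
math_symbols <- function(node) {
  if (is.null(node)) return(character(0))
  switch(node$kind,
    num = , time = character(0),
    sym = node$id,
    binop = , cmp = c(math_symbols(node$left), math_symbols(node$right)),
    neg = math_symbols(node$x),
    bool = , call = unlist(lapply(node$args, math_symbols), use.names = FALSE),
    character(0)
  )
}

# A tree is "constant" if it is a bare numeric literal (possibly negated):
# such initialisations set initial values; anything else is an initial
# assignment.
math_is_number <- function(node) {
  if (is.null(node)) return(FALSE)
  if (node$kind == "num") return(TRUE)
  if (node$kind == "neg") return(math_is_number(node$x))
  FALSE
}

math_number_value <- function(node) {
  if (node$kind == "num") return(node$value)
  if (node$kind == "neg") return(-math_number_value(node$x))
  stop("not a numeric literal")
}

# ---- number formatting ------------------------------------------------------

# Shortest decimal representation that round-trips to the same double.
# Integers print without a decimal point.
fmt_num <- function(x) {
  if (length(x) != 1 || is.na(x)) stop("fmt_num needs one number")
  if (!is.finite(x)) return(if (x > 0) "Inf" else "-Inf")
  if (x == floor(x) && abs(x) < 1e15) {
    return(format(x, scientific = FALSE))
  }
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g")
    if (as.numeric(s) == x) return(s)
  }
  formatC(x, digits = 17, format = "g")
}

# ---- rendering --------------------------------------------------------------

.prec <- function(node) {
  switch(node$kind,
    num = 100, sym = 100, time = 100, call = 100,
    neg = 7,
    binop = switch(node$op, "^" = 8, "*" = 6, "/" = 6, "+" = 5, "-" = 5),
    cmp = 4,
    bool = switch(node$op, not = 3, and = 2, or = 1)
  )
}

#' Render a math node as canonical text
#'
#' Produces text with minimal parentheses; [math_parse()] applied to the
#' output yields a structurally identical tree. Boolean connectives are
#' rendered with the `and`/`or`/`not` spellings.
#'
#' @param node a math node.
#' @return character scalar.
#' @examples
#' math_render(math_parse("k1 * S1"))
#' @export
math_render <- function(node) {
  stopifnot(is.list(node), !is.null(node$kind))
  rnd <- function(n) {
    switch(n$kind,
      num = fmt_num(n$value),
      sym = n$id,
      time = "time",
      call = paste0(n$fn, "(", paste(vapply(n$args, rnd, ""), collapse = ", "), ")"),
      neg = {
        inner <- rnd(n$x)
        if (.prec(n$x) < 7) inner <- paste0("(", inner, ")")
        paste0("-", inner)
      },
      binop = {
        p <- .prec(n)
        right_assoc <- n$op == "^"
        l <- rnd(n$left)
        r <- rnd(n$right)
        pl <- .prec(n$left)
        pr <- .prec(n$right)
        if (pl < p || (pl == p && right_assoc)) l <- paste0("(", l, ")")
        if (pr < p || (pr == p && !right_assoc)) r <- paste0("(", r, ")")
        paste0(l, " ", n$op, " ", r)
      },
      cmp = {
        l <- rnd(n$left); r <- rnd(n$right)
        if (.prec(n$left) < 5) l <- paste0("(", l, ")")
        if (.prec(n$right) < 5) r <- paste0("(", r, ")")
        paste0(l, " ", n$op, " ", r)
      },
      bool = {
        p <- .prec(n)
        if (n$op == "not") {
          inner <- rnd(n$args[[1]])
          if (.prec(n$args[[1]]) <= p) inner <- paste0("(", inner, ")")
          paste0("not ", inner)
        } else {
          parts <- vapply(n$args, function(a) {
            s <- rnd(a)
            if (.prec(a) < p) s <- paste0("(", s, ")")
            s
          }, "")
          paste(parts, collapse = paste0(" ", n$op, " "))
        }
      },
      stop("unsupported node kind: ", n$kind)
    )
  }
  rnd(node)
}

# Structural equality of two trees (numbers compared exactly).
math_identical <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  if (a$kind != b$kind) return(FALSE)
  switch(a$kind,
    num = identical(a$value, b$value),
    sym = identical(a$id, b$id),
    time = TRUE,
    neg = math_identical(a$x, b$x),
    binop = , cmp = a$op == b$op &&
      math_identical(a$left, b$left) && math_identical(a$right, b$right),
    bool = a$op == b$op && length(a$args) == length(b$args) &&
      all(mapply(math_identical, a$args, b$args)),
    call = a$fn == b$fn && length(a$args) == length(b$args) &&
      (length(a$args) == 0 || all(mapply(math_identical, a$args, b$args))),
    FALSE
  )
}
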