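# ---- tokenizer --------------------------------------------------------------

# Token: list(type, text, pos). Types: NUM, ID, OP, LPAR, RPAR, COMMA, END.
TOKEN_RE <- list(
  ws   = "^[ \t]+",
  num  = "^(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?",
  id   = "^[A-Za-z_][A-Za-z0-9_]*",
  op2  = "^(?:<=|>=|==|!=|&&|\\|\\|)",
  op1  = "^[-+*/^<>!,()=]"
)

tokenize_expr <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexpr(TOKEN_RE$ws, rest, perl = TRUE))
    if (length(m) == 1) { i <- i + nchar(m); next }
    matched <- FALSE
    for (ty in c("num", "id", "op2", "op1")) {
      m <- regmatches(rest, regexpr(TOKEN_RE[[ty]], rest, perl = TRUE))
      if (length(m) == 1) {
        type <- switch(m,
          "(" = "LPAR", ")" = "RPAR", "," = "COMMA",
          switch(ty, num = "NUM", id = "ID", "OP")
        )
        toks[[length(toks) + 1L]] <- list(type = type, text = m, pos = i)
        i <- i + nchar(m)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(math_err(sprintf("unexpected character '%s'", substr(text, i, i)), i))
    }
  }
  toks[[length(toks) + 1L]] <- list(type = "END", text = "", pos = n + 1L)
  toks
}

math_err <- function(msg, col) {
  structure(
    class = c("rxn_math_error", "error", "condition"),
    list(message = sprintf("column %d: %s", col, msg), call = NULL, col = col)
  )
}

# ---- recursive-descent parser ----------------------------------------------
# Precedence (loosest first): or < and < not < comparison < +- < */ <
# unary minus < ^ (right-assoc).

#' Parse a mathematical expression
#'
#' Parses rate-law style expressions into a tree. Conventional precedence is
#' used; `^` is right-associative and binds tighter than unary minus.
#' Both `&&`/`||`/`!` and `and`/`or`/`not` boolean spellings are accepted;
#' `time` is a reserved word denoting simulation time. `rateOf(<id>)`
#' requires a bare identifier argument; distribution draws
#' (`uniform`, `normal`, `lognormal`, `exponential`, `gamma`, `poisson`,
#' `binomial`) are checked for arity.
#'
#' @param text character scalar, non-empty.
#' @return A math node; see [math_node].
#' @examples
#' math_parse("k1*S1")
#' math_parse("time > 2 and x < 1")
#' @export
math_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) stop(math_err("empty expression", 1L))
  toks <- tokenize_expr(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  node <- p_or(st)
  tk <- peek(st)
  if (tk$type != "END") {
    stop(math_err(sprintf("unexpected '%s'", tk$text), tk$pos))
  }
  node
}

peek <- function(st) st$toks[[st$i]]
advance <- function(st) { tk <- st$toks[[st$i]]; st$i <- st$i + 1L; tk }
expect <- function(st, type, what) {
  tk <- advance(st)
  if (tk$type != type) stop(math_err(sprintf("expected %s, found '%s'", what, tk$text), tk$pos))
  tk
}

p_or <- function(st) {
  args <- list(p_and(st))
  while (peek(st)$type == "OP" && peek(st)$text %in% c("||") ||
         (peek(st)$type == "ID" && peek(st)$text == "or")) {
    advance(st)
    args[[length(args) + 1L]] <- p_and(st)
  }
  if (length(args) == 1) args[[1]] else m_bool("or", args)
}

p_and <- function(st) {
  args <- list(p_not(st))
  while ((peek(st)$type == "OP" && peek(st)$text == "&&") ||
         (peek(st)$type == "ID" && peek(st)$text == "and")) {
    advance(st)
    args[[length(args) + 1L]] <- p_not(st)
  }
  if (length(args) == 1) args[[1]] else m_bool("and", args)
}

p_not <- function(st) {
  tk <- peek(st)
  if ((tk$type == "OP" && tk$text == "!") ||
      (tk$type == "ID" && tk$text == "not")) {
    advance(st)
    return(m_bool("not", list(p_not(st))))
  }
  p_cmp(st)
}

p_cmp <- function(st) {
  left <- p_add(st)
  tk <- peek(st)
  if (tk$type == "OP" && tk$text %in% c("<", "<=", ">", ">=", "==", "!=")) {
    advance(st)
    right <- p_add(st)
    return(m_cmp(tk$text, left, right))
  }
  left
}

p_add <- function(st) {
  node <- p_mul(st)
  repeat {
    tk <- peek(st)
    if (tk$type == "OP" && tk$text %in% c("+", "-")) {
      advance(st)
      node <- m_binop(tk$text, node, p_mul(st))
    } else return(node)
  }
}

p_mul <- function(st) {
  node <- p_unary(st)
  repeat {
    tk <- peek(st)
    if (tk$type == "OP" && tk$text %in% c("*", "/")) {
      advance(st)
      node <- m_binop(tk$text, node, p_unary(st))
    } else return(node)
  }
}

p_unary <- function(st) {
  tk <- peek(st)
  if (tk$type == "OP" && tk$text == "-") {
    advance(st)
    return(m_neg(p_unary(st)))
  }
  if (tk$type == "OP" && tk$text == "+") {
    advance(st)
    return(p_unary(st))
  }
  p_pow(st)
}

p_pow <- function(st) {
  base <- p_atom(st)
  tk <- peek(st)
  if (tk$type == "OP" && tk$text == "^") {
    advance(st)
    # right-associative; unary minus allowed in the exponent
    return(m_binop("^", base, p_unary(st)))
  }
  base
}

p_atom <- function(st) {
  tk <- advance(st)
  if (tk$type == "NUM") return(m_num(as.numeric(tk$text)))
  if (tk$type == "LPAR") {
    node <- p_or(st)
    expect(st, "RPAR", "')'")
    return(node)
  }
  if (tk$type == "ID") {
    name <- tk$text
    if (peek(st)$type == "LPAR") {
      advance(st)
      args <- list()
      if (peek(st)$type != "RPAR") {
        repeat {
          args[[length(args) + 1L]] <- p_or(st)
          if (peek(st)$type == "COMMA") { advance(st); next }
          break
        }
      }
      expect(st, "RPAR", "')'")
      return(check_call(name, args, tk$pos))
    }
    if (name == "time") return(m_time())
    if (name %in% c("Inf", "INF")) return(m_num(Inf))
    if (name %in% c("and", "or", "not")) {
      stop(math_err(sprintf("'%s' used as a value", name), tk$pos))
    }
    return(m_sym(name))
  }
  stop(math_err(sprintf("unexpected '%s'", if (tk$type == "END") "end of expression" else tk$text), tk$pos))
}

check_call <- function(name, args, pos) {
  if (name == "rateOf") {
    if (length(args) != 1 || args[[1]]$kind != "sym") {
      stop(math_err("rateOf takes exactly one identifier argument", pos))
    }
  } else if (name %in% names(DRAW_FUNCTIONS)) {
    want <- DRAW_FUNCTIONS[[name]]
    if (length(args) != want) {
      stop(math_err(sprintf("%s expects %d argument(s), got %d", name, want, length(args)), pos))
    }
  } else if (!(name %in% MATH_FUNCTIONS)) {
    stop(math_err(sprintf("unknown function '%s'", name), pos))
  } else if (length(args) != 1) {
    stop(math_err(sprintf("%s expects 1 argument, got %d", name, length(args)), pos))
  }
  m_call(name, args)
}
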