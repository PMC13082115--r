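# ---- line-oriented model text parser ----------------------------------------

ID_RE <- "[A-Za-z_][A-Za-z0-9_]*"
NUM_RE <- "(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?"

parse_err <- function(msg) {
  structure(class = c("rxn_parse_error", "error", "condition"),
            list(message = msg, call = NULL))
}

# Scan positions of `chars` at top level (outside (), {} and "strings").
top_positions <- function(s, chars) {
  cs <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  inq <- FALSE
  out <- integer(0)
  for (i in seq_along(cs)) {
    c <- cs[i]
    if (inq) { if (c == '"') inq <- FALSE; next }
    if (c == '"') { inq <- TRUE; next }
    if (c %in% c("(", "{")) depth <- depth + 1L
    else if (c %in% c(")", "}")) depth <- depth - 1L
    else if (depth == 0L && c %in% chars) out <- c(out, i)
  }
  out
}

split_top <- function(s, char) {
  pos <- top_positions(s, char)
  if (length(pos) == 0) return(s)
  starts <- c(1L, pos + 1L)
  ends <- c(pos - 1L, nchar(s))
  vapply(seq_along(starts), function(i) substr(s, starts[i], ends[i]), "")
}

# Replace quoted spans with placeholders of equal length (for safe matching).
blank_quotes <- function(s) {
  cs <- strsplit(s, "", fixed = TRUE)[[1]]
  inq <- FALSE
  for (i in seq_along(cs)) {
    if (cs[i] == '"') { inq <- !inq; next }
    if (inq) cs[i] <- "\u1"
  }
  paste(cs, collapse = "")
}

# Strip comments while preserving line structure.
strip_comments <- function(text) {
  cs <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(cs)
  out <- character(n)
  i <- 1L
  inq <- FALSE
  while (i <= n) {
    c <- cs[i]
    if (inq) {
      out[i] <- c
      if (c == '"') inq <- FALSE
      i <- i + 1L
      next
    }
    if (c == '"') { out[i] <- c; inq <- TRUE; i <- i + 1L; next }
    if (c == "/" && i < n && cs[i + 1L] == "/") {
      while (i <= n && cs[i] != "\n") { out[i] <- " "; i <- i + 1L }
      next
    }
    if (c == "/" && i < n && cs[i + 1L] == "*") {
      out[i] <- " "; out[i + 1L] <- " "; i <- i + 2L
      while (i <= n && !(cs[i] == "*" && i < n && cs[i + 1L] == "/")) {
        out[i] <- if (cs[i] == "\n") "\n" else " "
        i <- i + 1L
      }
      if (i <= n) { out[i] <- " "; if (i < n) out[i + 1L] <- " "; i <- i + 2L }
      next
    }
    out[i] <- c
    i <- i + 1L
  }
  paste(out[seq_len(min(i - 1L, n))], collapse = "")
}

# ---- top-level entry --------------------------------------------------------

#' Parse model text
#'
#' Reads a plain-text model description line by line, building the internal
#' model with implicit symbol declaration and collecting diagnostics instead
#' of aborting: after a malformed statement the parser recovers and
#' continues. Statements end at a newline or `;`, except the `;` that
#' separates a reaction from its rate law. `//` and `/* ... */` comments are
#' dropped. Both the ASCII `->` arrow and the typographic minus arrow are
#' accepted. Defaults are applied (species placed in an automatic
#' compartment at export, reactions reversible, event attributes set to the
#' SBML Level 3 defaults). An optional `model <id> ... end` wrapper names
#' the model; bare statements form a model with id `__main`.
#'
#' @param text character: model source (a single string or a vector of lines).
#' @return A list of class `rxn_parse_result`: `model` ([rxn_model]) and
#'   `diagnostics` (data frame with `severity`, `line`, `message`; includes
#'   semantic validation results).
#' @examples
#' res <- rxn_parse("S1 -> S2; k1*S1")
#' res$model
#' @export
rxn_parse <- function(text) {
  stopifnot(is.character(text))
  text <- paste(text, collapse = "\n")
  if (!all(validUTF8(text))) text <- iconv(text, "UTF-8", "UTF-8", sub = "byte")
  text <- gsub("\r\n", "\n", text, fixed = TRUE)
  text <- gsub("−>", "->", text)   # typographic minus arrow
  text <- strip_comments(text)

  model <- rxn_model()
  d <- diag_df()
  header_seen <- FALSE
  in_model <- FALSE

  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    stmts <- split_statements(line)
    for (stmt in stmts) {
      stmt <- trimws(stmt)
      if (!nzchar(stmt)) next
      res <- tryCatch(
        {
          out <- dispatch_statement(model, stmt, ln,
                                    header_seen = header_seen,
                                    in_model = in_model)
          if (identical(out, "model_header")) { header_seen <- TRUE; in_model <- TRUE }
          if (identical(out, "model_end")) in_model <- FALSE
          NULL
        },
        rxn_parse_error = function(e) conditionMessage(e),
        rxn_conflict_error = function(e) conditionMessage(e),
        rxn_math_error = function(e) conditionMessage(e),
        error = function(e) conditionMessage(e)
      )
      if (!is.null(res)) d <- diag_add(d, "error", ln, res)
      w <- model$pending_warnings
      if (!is.null(w)) {
        for (msg in w) d <- diag_add(d, "warning", ln, msg)
        model$pending_warnings <- NULL
      }
    }
  }

  reclassify_reaction_constraints(model)
  finalize_model(model)
  d <- rbind(d, rxn_validate(model))
  structure(list(model = model, diagnostics = d), class = "rxn_parse_result")
}

#' @export
print.rxn_parse_result <- function(x, ...) {
  print(x$model)
  ne <- sum(x$diagnostics$severity == "error")
  nw <- sum(x$diagnostics$severity == "warning")
  cat(sprintf("  diagnostics: %d error(s), %d warning(s)\n", ne, nw))
  invisible(x)
}

#' Parse a model file
#' @param path path to a `.rxn` text file (UTF-8).
#' @return See [rxn_parse()].
#' @export
rxn_parse_file <- function(path) {
  rxn_parse(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

warn_later <- function(model, msg) {
  model$pending_warnings <- c(model$pending_warnings, msg)
}

# `;` ends a statement unless the clause to its left contains an arrow, in
# which case it separates the reaction from its rate law.
split_statements <- function(line) {
  parts <- split_top(line, ";")
  if (length(parts) == 1) return(parts)
  out <- character(0)
  i <- 1L
  while (i <= length(parts)) {
    p <- parts[i]
    if (grepl("->", blank_quotes(p), fixed = TRUE) && i < length(parts)) {
      out <- c(out, paste0(p, ";", parts[i + 1L]))
      i <- i + 2L
    } else {
      out <- c(out, p)
      i <- i + 1L
    }
  }
  out
}

# ---- statement dispatch -----------------------------------------------------

dispatch_statement <- function(model, stmt, line, header_seen, in_model) {
  bq <- blank_quotes(stmt)

  if (grepl(paste0("^model\\s+", ID_RE, "\\s*$"), bq)) {
    id <- sub("^model\\s+", "", trimws(stmt))
    if (header_seen) stop(parse_err("only one model block is supported"))
    model$id <- id
    return("model_header")
  }
  if (grepl("^end\\s*$", bq)) {
    if (!in_model) stop(parse_err("'end' without a model header"))
    return("model_end")
  }
  if (grepl("^substanceOnly\\b", bq)) {
    return(parse_substance_only(model, stmt, line))
  }
  if (grepl("^(maximize|minimize)\\b", bq)) {
    return(parse_objective_clause(model, stmt, line))
  }
  if (grepl("^(const\\s+|var\\s+)?(species|compartment|parameter)\\b", bq) ||
      grepl(paste0("^const\\s+\\$?", ID_RE), bq)) {
    return(parse_declaration(model, stmt, line))
  }
  if (grepl("->", bq, fixed = TRUE)) {
    return(parse_reaction_clause(model, stmt, line))
  }
  if (grepl(paste0("^(", ID_RE, "\\s*:\\s*)?at\\b"), bq)) {
    return(parse_event_clause(model, stmt, line))
  }
  if (grepl(paste0("^(model|", ID_RE, ")\\s+", ID_RE, '\\s+"'), stmt)) {
    return(parse_annotation_clause(model, stmt, line))
  }
  if (grepl(paste0("^(model|", ID_RE, ")\\.", ID_RE, "\\s*="), bq)) {
    return(parse_dot_clause(model, stmt, line))
  }
  # comparisons at top level (after removing two-char ops there is no bare =)
  ops_blanked <- gsub("<=|>=|==|!=", "\u2", bq)
  has_cmp <- length(top_positions(bq, c("<", ">"))) > 0 ||
    grepl("\u2", ops_blanked, fixed = TRUE)
  has_assign <- length(top_positions(ops_blanked, "=")) > 0
  if (has_cmp && !has_assign) {
    return(parse_inequality_clause(model, stmt, line))
  }
  if (grepl(paste0("^(", ID_RE, "\\s*:\\s*)?0\\s*="), bq) ||
      grepl(":=", bq, fixed = TRUE) ||
      grepl(paste0("^", ID_RE, "'\\s*="), bq) ||
      grepl(paste0("^\\$?", ID_RE, "\\s*="), bq)) {
    return(parse_rule_or_init_clause(model, stmt, line))
  }
  stop(parse_err(sprintf("unrecognized statement: '%s'", stmt)))
}

# ---- clause parsers ---------------------------------------------------------

parse_substance_only <- function(model, stmt, line) {
  rest <- trimws(sub("^substanceOnly\\b", "", stmt))
  ids <- trimws(split_top(rest, ","))
  if (length(ids) == 0 || any(!nzchar(ids))) {
    stop(parse_err("substanceOnly needs a comma-separated id list"))
  }
  for (id in ids) {
    if (!grepl(paste0("^", ID_RE, "$"), id)) {
      stop(parse_err(sprintf("invalid identifier '%s' in substanceOnly", id)))
    }
    rxn_declare(model, id, "species")  # amounts only make sense for species
    set_symbol_field(model, id, "substance_only", TRUE)
  }
  invisible(NULL)
}

parse_declaration <- function(model, stmt, line) {
  s <- trimws(stmt)
  is_const <- FALSE
  if (grepl("^const\\b", s)) { is_const <- TRUE; s <- trimws(sub("^const\\b", "", s)) }
  if (grepl("^var\\b", s)) s <- trimws(sub("^var\\b", "", s))
  kind <- "parameter"
  if (grepl("^(species|compartment|parameter)\\b", s)) {
    kind <- sub("^(species|compartment|parameter)\\b.*$", "\\1", s)
    s <- trimws(sub("^(species|compartment|parameter)\\b", "", s))
  }
  if (!nzchar(s)) stop(parse_err("empty declaration"))
  items <- trimws(split_top(s, ","))
  for (item in items) {
    m <- regmatches(item, regexec(
      paste0("^(\\$?)(", ID_RE, ")(?:\\s+in\\s+(", ID_RE, "))?$"), item))[[1]]
    if (length(m) == 0) {
      stop(parse_err(sprintf("malformed declaration item '%s'", item)))
    }
    boundary <- m[2] == "$"
    id <- m[3]
    comp <- if (nzchar(m[4])) m[4] else NULL
    this_kind <- if (boundary || !is.null(comp)) "species" else kind
    rxn_declare(model, id, this_kind, explicit = TRUE)
    if (boundary) set_symbol_field(model, id, "is_boundary", TRUE)
    if (is_const) set_symbol_field(model, id, "is_const", TRUE)
    if (!is.null(comp)) {
      rxn_declare(model, comp, "compartment")
      set_symbol_field(model, id, "compartment", comp)
    }
  }
  invisible(NULL)
}

#' @noRd
parse_reaction_clause <- function(model, stmt, line) {
  s <- trimws(stmt)
  rate <- NULL
  semi <- top_positions(s, ";")
  if (length(semi) > 0) {
    rate_txt <- trimws(substr(s, semi[1] + 1L, nchar(s)))
    s <- trimws(substr(s, 1L, semi[1] - 1L))
    if (nzchar(rate_txt)) rate <- math_parse(rate_txt)
  }
  label <- NULL
  m <- regmatches(s, regexec(paste0("^(", ID_RE, ")\\s*:\\s*(.*)$"), s))[[1]]
  if (length(m) > 0) { label <- m[2]; s <- m[3] }
  arrow <- regexpr("->", s, fixed = TRUE)
  if (arrow < 0) stop(parse_err("reaction clause without arrow"))
  lhs <- trimws(substr(s, 1L, arrow - 1L))
  rhs <- trimws(substr(s, arrow + 2L, nchar(s)))
  reactants <- parse_reaction_side(model, lhs)
  products <- parse_reaction_side(model, rhs)
  if (length(reactants) == 0 && length(products) == 0) {
    stop(parse_err("reaction with empty reactant and product sides"))
  }
  auto <- is.null(label)
  id <- if (auto) next_auto_reaction_id(model) else label
  rxn_declare(model, id, "reaction")
  declare_math_refs(model, rate)
  model$reactions[[length(model$reactions) + 1L]] <-
    new_reaction(id, reactants, products, kinetic_math = rate,
                 reversible = TRUE, auto_id = auto, line = line)
  invisible(NULL)
}

parse_reaction_side <- function(model, side) {
  if (!nzchar(side)) return(list())
  terms <- trimws(split_top(side, "+"))
  refs <- list()
  for (term in terms) {
    if (!nzchar(term)) stop(parse_err("empty term on reaction side"))
    m <- regmatches(term, regexec(
      paste0("^(?:(", NUM_RE, "|", ID_RE, ")\\s+)?(\\$?)(", ID_RE, ")$"),
      term, perl = TRUE))[[1]]
    if (length(m) == 0) {
      stop(parse_err(sprintf("malformed reaction term '%s'", term)))
    }
    coef <- m[2]
    boundary <- m[3] == "$"
    sp <- m[4]
    rxn_declare(model, sp, "species")
    if (boundary) set_symbol_field(model, sp, "is_boundary", TRUE)
    if (!nzchar(coef)) {
      refs[[length(refs) + 1L]] <- species_ref(sp, stoich = 1)
    } else if (grepl(paste0("^", NUM_RE, "$"), coef, perl = TRUE)) {
      v <- as.numeric(coef)
      if (v <= 0) stop(parse_err("stoichiometry must be > 0"))
      refs[[length(refs) + 1L]] <- species_ref(sp, stoich = v)
    } else {
      rxn_declare(model, coef, "stoichiometry")
      refs[[length(refs) + 1L]] <- species_ref(sp, stoich_id = coef)
    }
  }
  refs
}

#' @noRd
parse_event_clause <- function(model, stmt, line) {
  s <- trimws(stmt)
  label <- NULL
  m <- regmatches(s, regexec(paste0("^(", ID_RE, ")\\s*:\\s*(at\\b.*)$"), s))[[1]]
  if (length(m) > 0) { label <- m[2]; s <- m[3] }
  if (!grepl("^at\\b", s)) stop(parse_err("event clause must start with 'at'"))
  s <- trimws(sub("^at\\b", "", s))
  colon <- top_positions(s, ":")
  if (length(colon) == 0) stop(parse_err("event missing ':' after trigger"))
  head_txt <- substr(s, 1L, colon[1] - 1L)
  body_txt <- substr(s, colon[1] + 1L, nchar(s))

  head_parts <- trimws(split_top(head_txt, ","))
  trigger_txt <- head_parts[1]
  if (!nzchar(trigger_txt)) stop(parse_err("event with empty trigger"))
  trigger <- math_parse(trigger_txt)
  priority <- NULL
  for (opt in head_parts[-1]) {
    om <- regmatches(opt, regexec("^priority\\s*=\\s*(.+)$", opt))[[1]]
    if (length(om) == 0) {
      stop(parse_err(sprintf("unknown event option '%s'", opt)))
    }
    priority <- math_parse(om[2])
  }

  asg_parts <- trimws(split_top(body_txt, ","))
  asg_parts <- asg_parts[nzchar(asg_parts)]
  if (length(asg_parts) == 0) stop(parse_err("event with empty assignment list"))
  assignments <- list()
  for (ap in asg_parts) {
    am <- regmatches(ap, regexec(paste0("^(", ID_RE, ")\\s*=\\s*(.+)$"), ap))[[1]]
    if (length(am) == 0) {
      stop(parse_err(sprintf("malformed event assignment '%s'", ap)))
    }
    tgt <- am[2]
    mathn <- math_parse(am[3])
    if (is.null(model$symbols[[tgt]])) rxn_declare(model, tgt, "parameter")
    declare_math_refs(model, mathn)
    assignments[[length(assignments) + 1L]] <- list(target = tgt, math = mathn)
  }
  declare_math_refs(model, trigger)
  declare_math_refs(model, priority)
  auto <- is.null(label)
  id <- if (auto) next_auto_event_id(model) else label
  rxn_declare(model, id, "event")
  model$events[[length(model$events) + 1L]] <-
    new_event(id, trigger, assignments, priority = priority,
              auto_id = auto, line = line)
  invisible(NULL)
}

#' @noRd
parse_rule_or_init_clause <- function(model, stmt, line) {
  s <- trimws(stmt)

  m <- regmatches(s, regexec(paste0("^(?:(", ID_RE, ")\\s*:\\s*)?0\\s*=\\s*(.+)$"), s))[[1]]
  if (length(m) > 0) {
    id <- if (nzchar(m[2])) m[2] else NULL
    mathn <- math_parse(m[3])
    if (!is.null(id)) rxn_declare(model, id, "rule")
    declare_math_refs(model, mathn)
    model$rules[[length(model$rules) + 1L]] <-
      new_rule("algebraic", math = mathn, id = id, line = line)
    return(invisible(NULL))
  }

  if (grepl(":=", blank_quotes(s), fixed = TRUE)) {
    m <- regmatches(s, regexec(paste0("^(", ID_RE, ")\\s*:=\\s*(.+)$"), s))[[1]]
    if (length(m) == 0) stop(parse_err("malformed assignment rule (target must be an identifier)"))
    tgt <- m[2]
    mathn <- math_parse(m[3])
    if (is.null(model$symbols[[tgt]])) rxn_declare(model, tgt, "parameter")
    declare_math_refs(model, mathn)
    model$rules[[length(model$rules) + 1L]] <-
      new_rule("assignment", target = tgt, math = mathn, line = line)
    return(invisible(NULL))
  }

  m <- regmatches(s, regexec(paste0("^(", ID_RE, ")'\\s*=\\s*(.+)$"), s))[[1]]
  if (length(m) > 0) {
    tgt <- m[2]
    mathn <- math_parse(m[3])
    if (is.null(model$symbols[[tgt]])) rxn_declare(model, tgt, "parameter")
    if (isTRUE(model$symbols[[tgt]]$is_const)) {
      stop(parse_err(sprintf("rate rule targets constant symbol '%s'", tgt)))
    }
    declare_math_refs(model, mathn)
    model$rules[[length(model$rules) + 1L]] <-
      new_rule("rate", target = tgt, math = mathn, line = line)
    return(invisible(NULL))
  }

  m <- regmatches(s, regexec(paste0("^(\\$?)(", ID_RE, ")\\s*=\\s*(.+)$"), s))[[1]]
  if (length(m) == 0) stop(parse_err(sprintf("malformed statement '%s'", s)))
  boundary <- m[2] == "$"
  tgt <- m[3]
  mathn <- math_parse(m[4])
  if (is.null(model$symbols[[tgt]])) {
    rxn_declare(model, tgt, if (boundary) "species" else "parameter")
  }
  if (boundary) set_symbol_field(model, tgt, "is_boundary", TRUE)
  if (math_is_number(mathn)) {
    set_symbol_field(model, tgt, "initial_value", math_number_value(mathn))
  } else {
    declare_math_refs(model, mathn)
    model$initial_assignments[[length(model$initial_assignments) + 1L]] <-
      list(target = tgt, math = mathn, line = line)
  }
  invisible(NULL)
}

#' @noRd
parse_inequality_clause <- function(model, stmt, line) {
  s <- trimws(stmt)
  toks <- regmatches(s, gregexpr("<=|>=|<|>", s))[[1]]
  parts <- trimws(strsplit(s, "<=|>=|<|>")[[1]])
  if (length(toks) == 1) {
    parts <- c(parts, "")[1:2]
    lhs <- parts[1]; rhs <- parts[2]
    reversed <- toks[1] %in% c(">", ">=")
    strict <- toks[1] %in% c("<", ">")
    lhs_is_id <- grepl(paste0("^", ID_RE, "$"), lhs)
    rhs_is_id <- grepl(paste0("^", ID_RE, "$"), rhs)
    if (lhs_is_id == rhs_is_id) {
      stop(parse_err("inequality must relate one identifier and one bound"))
    }
    id <- if (lhs_is_id) lhs else rhs
    bound <- math_parse(if (lhs_is_id) rhs else lhs)
    # id on the left of `<` means an upper bound (and vice versa for `>`)
    is_upper <- xor(lhs_is_id, reversed)
    add_constraint(model, id, line,
                   lower = if (is_upper) NULL else bound,
                   upper = if (is_upper) bound else NULL,
                   strict_lower = !is_upper && strict,
                   strict_upper = is_upper && strict)
    return(invisible(NULL))
  }
  if (length(toks) != 2 || length(parts) != 3) {
    stop(parse_err("malformed chained inequality"))
  }
  dir1 <- toks[1] %in% c("<", "<=")
  dir2 <- toks[2] %in% c("<", "<=")
  if (dir1 != dir2) stop(parse_err("mixed inequality directions"))
  if (!dir1) { parts <- rev(parts); toks <- rev(chartr("<>", "><", toks)) }
  lo_txt <- parts[1]; id <- parts[2]; hi_txt <- parts[3]
  if (!grepl(paste0("^", ID_RE, "$"), id)) {
    stop(parse_err("middle term of a chained inequality must be an identifier"))
  }
  lower <- math_parse(lo_txt)
  upper <- math_parse(hi_txt)
  add_constraint(model, id, line, lower = lower, upper = upper,
                 strict_lower = toks[1] == "<", strict_upper = toks[2] == "<")
  invisible(NULL)
}

add_constraint <- function(model, id, line, lower, upper,
                           strict_lower, strict_upper) {
  if (identical(symbol_kind(model, id), "reaction")) {
    if (is.null(lower) || is.null(upper)) {
      stop(parse_err(sprintf("flux bounds on '%s' need both lower and upper bounds", id)))
    }
    if (!math_is_number(lower) || !math_is_number(upper)) {
      stop(parse_err(sprintf("flux bounds on '%s' must be numeric", id)))
    }
    if (strict_lower || strict_upper) {
      warn_later(model, sprintf(
        "strict inequality on flux bound for '%s' treated as non-strict", id))
    }
    model$flux_bounds[[length(model$flux_bounds) + 1L]] <-
      list(reaction = id, lower = math_number_value(lower),
           upper = math_number_value(upper), line = line)
    return(invisible(NULL))
  }
  if (is.null(model$symbols[[id]])) rxn_declare(model, id, "parameter")
  num_or_math <- function(x) {
    if (is.null(x)) NULL else if (math_is_number(x)) math_number_value(x) else x
  }
  declare_math_refs(model, lower)
  declare_math_refs(model, upper)
  model$constraints[[length(model$constraints) + 1L]] <-
    list(symbol = id, lower = num_or_math(lower), upper = num_or_math(upper),
         strict_lower = strict_lower, strict_upper = strict_upper, line = line)
  invisible(NULL)
}

# A constraint whose subject turned out to be a reaction (declared later in
# the file) is really a flux bound; reclassify after the full pass.
reclassify_reaction_constraints <- function(model) {
  keep <- list()
  for (cn in model$constraints) {
    if (identical(symbol_kind(model, cn$symbol), "reaction") &&
        is.numeric(cn$lower) && is.numeric(cn$upper)) {
      model$flux_bounds[[length(model$flux_bounds) + 1L]] <-
        list(reaction = cn$symbol, lower = cn$lower, upper = cn$upper,
             line = cn$line)
    } else {
      keep[[length(keep) + 1L]] <- cn
    }
  }
  model$constraints <- keep
  invisible(model)
}

#' @noRd
parse_objective_clause <- function(model, stmt, line) {
  s <- trimws(stmt)
  sense <- sub("^(maximize|minimize)\\b.*$", "\\1", s)
  rest <- trimws(sub("^(maximize|minimize)\\b", "", s))
  if (!nzchar(rest)) stop(parse_err("objective with no terms"))
  # split into +/- separated linear terms
  pos <- top_positions(rest, c("+", "-"))
  bounds <- c(0L, pos, nchar(rest) + 1L)
  terms <- list()
  sign <- 1
  start <- 1L
  pieces <- list()
  idx <- c(pos, nchar(rest) + 1L)
  prev <- 1L
  signs <- 1
  for (p in idx) {
    piece <- trimws(substr(rest, prev, p - 1L))
    pieces[[length(pieces) + 1L]] <- list(sign = signs, text = piece)
    if (p <= nchar(rest)) {
      signs <- if (substr(rest, p, p) == "-") -1 else 1
    }
    prev <- p + 1L
  }
  for (pc in pieces) {
    if (!nzchar(pc$text)) stop(parse_err("empty objective term"))
    m <- regmatches(pc$text, regexec(
      paste0("^(?:(", NUM_RE, ")\\s*\\*?\\s+)?(", ID_RE, ")$"), pc$text, perl = TRUE))[[1]]
    if (length(m) == 0) {
      stop(parse_err(sprintf(
        "objective term '%s' is not a linear [coefficient] reaction-id term", pc$text)))
    }
    coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
    rid <- m[3]
    rxn_declare(model, rid, "reaction")
    terms[[length(terms) + 1L]] <- list(coef = pc$sign * coef, reaction = rid)
  }
  model$objectives[[length(model$objectives) + 1L]] <-
    list(sense = sense, terms = terms, line = line)
  invisible(NULL)
}

#' @noRd
parse_dot_clause <- function(model, stmt, line) {
  s <- trimws(stmt)
  m <- regmatches(s, regexec(
    paste0("^(model|", ID_RE, ")\\.(", ID_RE, ")\\s*=\\s*(.+)$"), s))[[1]]
  if (length(m) == 0) stop(parse_err("malformed dot-property statement"))
  el <- m[2]; prop <- m[3]; val <- trimws(m[4])

  parse_brace_list <- function(v) {
    bm <- regmatches(v, regexec("^\\{(.*)\\}$", v))[[1]]
    if (length(bm) == 0) stop(parse_err(sprintf("expected {a, b, ...}, found '%s'", v)))
    nums <- trimws(split_top(bm[2], ","))
    out <- suppressWarnings(as.numeric(nums))
    if (any(is.na(out))) stop(parse_err("non-numeric value in {...} list"))
    out
  }

  if (el == "model") {
    if (prop == "layout") {
      if (!(val %in% c("on", "off"))) stop(parse_err("model.layout must be on or off"))
      model$layout$enabled <- val == "on"
      return(invisible(NULL))
    }
    if (prop == "styleTemplate") {
      sm <- regmatches(val, regexec('^"([^"]*)"$', val))[[1]]
      if (length(sm) == 0) stop(parse_err("styleTemplate needs a quoted name"))
      model$layout$style_template <- sm[2]
      return(invisible(NULL))
    }
    stop(parse_err(sprintf("unknown model property '%s'", prop)))
  }

  if (prop %in% UNCERT_STATS) {
    if (is.null(model$symbols[[el]])) rxn_declare(model, el, "parameter")
    if (prop == "confidenceInterval") {
      v <- parse_brace_list(val)
      if (length(v) != 2) stop(parse_err("confidenceInterval needs {lo, hi}"))
    } else {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v)) stop(parse_err(sprintf("%s needs a numeric value", prop)))
    }
    model$uncertainty[[length(model$uncertainty) + 1L]] <-
      list(element = el, stat = prop, value = v, line = line)
    return(invisible(NULL))
  }

  if (prop %in% c("position", "size", "centroid", "curvePoints")) {
    if (is.null(model$symbols[[el]])) rxn_declare(model, el, "parameter")
    v <- parse_brace_list(val)
    if (prop %in% c("position", "size", "centroid") && length(v) != 2) {
      stop(parse_err(sprintf("%s needs exactly 2 numbers", prop)))
    }
    if (prop == "curvePoints" && (length(v) < 2 || length(v) %% 2 != 0)) {
      stop(parse_err("curvePoints needs an even number of coordinates"))
    }
    if (prop == "size") model$layout$sizes[[el]] <- v
    else if (prop == "curvePoints") model$layout$curves[[el]] <- v
    else model$layout$positions[[el]] <- v   # position and reaction centroid
    return(invisible(NULL))
  }
  stop(parse_err(sprintf("unknown property name '%s'", prop)))
}

#' @noRd
parse_annotation_clause <- function(model, stmt, line) {
  s <- trimws(stmt)
  m <- regmatches(s, regexec(
    paste0('^(model|', ID_RE, ')\\s+(', ID_RE, ')\\s+"([^"]*)"\\s*$'), s))[[1]]
  if (length(m) == 0) stop(parse_err("malformed annotation (missing quotes?)"))
  el <- m[2]; qual <- m[3]; body <- m[4]
  if (qual == "notes") {
    if (el != "model" && is.null(model$symbols[[el]])) rxn_declare(model, el, "parameter")
    existing <- vapply(model$notes, function(n) n$element, "")
    if (el %in% existing) {
      warn_later(model, sprintf("duplicate notes for '%s'; the later entry wins", el))
      model$notes <- model$notes[existing != el]
    }
    model$notes[[length(model$notes) + 1L]] <-
      list(element = el, text = body, line = line)
    return(invisible(NULL))
  }
  valid <- if (el == "model") MODEL_QUALIFIERS else BIOL_QUALIFIERS
  if (!(qual %in% valid)) {
    stop(parse_err(sprintf("unknown %s qualifier '%s'",
                           if (el == "model") "model" else "element", qual)))
  }
  if (el != "model" && is.null(model$symbols[[el]])) rxn_declare(model, el, "parameter")
  model$annotations[[length(model$annotations) + 1L]] <-
    list(element = el, qualifier = qual, uri = body, line = line)
  invisible(NULL)
}
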