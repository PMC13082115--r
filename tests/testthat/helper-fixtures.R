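# shared fixture builders for the test suite (everything is generated in code)

# random expression tree over a small symbol pool; `boolean` controls whether
# the root may be a comparison/connective
gen_tree <- function(depth, boolean = FALSE) {
  syms <- c("a", "b", "c", "k1", "S1")
  leaf <- function() {
    if (runif(1) < 0.5) m_sym(sample(syms, 1))
    else if (runif(1) < 0.1) m_time()
    else m_num(round(runif(1, 0, 99.99), 2))
  }
  arith <- function(d) {
    if (d <= 0 || runif(1) < 0.3) return(leaf())
    pick <- runif(1)
    if (pick < 0.55) {
      m_binop(sample(c("+", "-", "*", "/", "^"), 1), arith(d - 1), arith(d - 1))
    } else if (pick < 0.7) {
      m_neg(arith(d - 1))
    } else if (pick < 0.85) {
      m_call(sample(c("sin", "exp", "ln", "abs", "sqrt", "tanh"), 1),
             list(arith(d - 1)))
    } else if (pick < 0.95) {
      fn <- sample(names(rxnscript:::DRAW_FUNCTIONS), 1)
      arity <- rxnscript:::DRAW_FUNCTIONS[[fn]]
      m_call(fn, replicate(arity, arith(max(d - 1, 0)), simplify = FALSE))
    } else {
      m_call("rateOf", list(m_sym(sample(syms, 1))))
    }
  }
  if (!boolean) return(arith(depth))
  cmp <- function(d) m_cmp(sample(c("<", "<=", ">", ">=", "==", "!="), 1),
                           arith(d - 1), arith(d - 1))
  if (runif(1) < 0.5) return(cmp(depth))
  op <- sample(c("and", "or", "not"), 1)
  if (op == "not") m_bool("not", list(cmp(depth - 1)))
  else m_bool(op, replicate(sample(2:3, 1), cmp(depth - 1), simplify = FALSE))
}

# a full-feature worked model used across serializer/SBML tests
full_feature_text <- function() {
  paste(c(
    "model demo",
    "compartment central",
    "const species S1 in central",
    "species S2 in central, $S3",
    "substanceOnly S2",
    "J0: S1 -> S2; k1*S1",
    "R1: 2 S2 -> S3",
    "n S1 -> S2",
    "n = 3",
    "S2 = 10",
    "ka = lognormal(0.1, 0.25)",
    "E0: at time > 3: k4 = 10",
    "E1: at time > 2 and x < 1, priority = uniform(0,2): x = 5",
    "A1: 0 = S2 + x",
    "z := k1 * 2",
    "w' = k4",
    "10 < J2 < 50",
    "0 <= R1 <= 1000",
    "maximize R1 + 2 J0",
    "x.mean = 10",
    "P1.confidenceInterval = {1, 2}",
    'S2 is "http://identifiers.org/CHEBI:17234"',
    'model notes "generated demo model"',
    "model.layout = on",
    "S2.position = {50, 40}",
    "R1.centroid = {10, 20}",
    "R1.curvePoints = {0, 0, 10, 20, 30, 40}",
    'model.styleTemplate = "Escher"',
    "end"), collapse = "\n")
}

# random generator config across the feature-flag lattice
random_config <- function(seed) {
  flags <- c("events", "rules", "constraints", "fbc", "distrib", "layout",
             "annotations", "named_stoich", "substance_only")
  set.seed(seed * 7L + 13L)
  on <- sample(flags, sample(0:length(flags), 1))
  args <- as.list(stats::setNames(rep(TRUE, length(on)), on))
  do.call(rxn_generator_config,
          c(list(seed = seed, n_species = sample(2:6, 1),
                 n_reactions = sample(1:4, 1),
                 max_math_depth = sample(2:4, 1)), args))
}

# byte-level mutations for the crash-freedom property
mutate_text <- function(text, n_mut = 3L) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  junk <- c(LETTERS, letters, 0:9, "<", ">", "=", ";", ":", "(", ")", "{",
            "}", ",", ".", "$", "'", "\"", "->", "&&", "é", "\\", "#",
            "@", "~", " ")
  for (i in seq_len(n_mut)) {
    op <- sample(c("del", "ins", "dup", "trunc", "swap"), 1)
    if (length(chars) < 2) break
    pos <- sample(seq_along(chars), 1)
    if (op == "del") chars <- chars[-pos]
    else if (op == "ins") chars <- append(chars, sample(junk, 1), after = pos)
    else if (op == "dup") chars <- append(chars, chars[pos], after = pos)
    else if (op == "trunc") chars <- chars[seq_len(pos)]
    else {
      pos2 <- sample(seq_along(chars), 1)
      tmp <- chars[pos]; chars[pos] <- chars[pos2]; chars[pos2] <- tmp
    }
  }
  paste(chars, collapse = "")
}

expect_clean_parse <- function(text) {
  res <- rxn_parse(text)
  errs <- res$diagnostics[res$diagnostics$severity == "error", ]
  expect_equal(nrow(errs), 0,
               info = paste(errs$message, collapse = "; "))
  res
}
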