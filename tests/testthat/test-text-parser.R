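test_that("a reaction line implicitly declares its species and rate parameters", {
  res <- expect_clean_parse("S1 -> S2; k1*S1")
  m <- res$model
  expect_equal(m$symbols$S1$kind, "species")
  expect_equal(m$symbols$S2$kind, "species")
  expect_equal(m$symbols$k1$kind, "parameter")
  expect_length(m$reactions, 1)
  r <- m$reactions[[1]]
  expect_true(r$auto_id)
  expect_equal(r$reactants[[1]]$species, "S1")
  expect_equal(r$reactants[[1]]$stoich, 1)
  expect_equal(math_render(r$kinetic_math), "k1 * S1")
  expect_true(r$reversible)

  # typographic minus arrow is accepted
  res2 <- expect_clean_parse("S1 −> S2; k1*S1")
  expect_true(rxn_semantic_equal(m, res2$model)$equal)
})

test_that("empty input yields an empty valid model", {
  res <- rxn_parse("")
  expect_equal(nrow(res$diagnostics), 0)
  expect_length(res$model$reactions, 0)
  expect_length(res$model$symbols, 0)
  expect_equal(res$model$id, "__main")
})

test_that("reaction sides support numeric and named stoichiometries", {
  m <- expect_clean_parse("2 A + B -> 3 C")$model
  r <- m$reactions[[1]]
  expect_equal(vapply(r$reactants, function(x) x$stoich, 1), c(2, 1))
  expect_equal(r$products[[1]]$stoich, 3)

  m <- expect_clean_parse(c("J0: n L -> RL; k*L^n", "n = 3"))$model
  expect_equal(m$symbols$n$kind, "stoichiometry")
  expect_equal(m$reactions[[1]]$reactants[[1]]$stoich_id, "n")
  expect_equal(m$symbols$n$initial_value, 3)

  bad <- rxn_parse("2 3 A -> B")
  expect_true(any(bad$diagnostics$severity == "error"))
  bad2 <- rxn_parse(" -> ")
  expect_true(any(bad2$diagnostics$severity == "error"))
})

test_that("event clauses parse triggers, priorities and assignment lists", {
  m <- expect_clean_parse("E0: at time > 3: k4 = 10")$model
  e <- m$events[[1]]
  expect_equal(e$id, "E0")
  expect_equal(e$trigger, m_cmp(">", m_time(), m_num(3)))
  expect_equal(e$assignments[[1]]$target, "k4")
  expect_equal(e$assignments[[1]]$math, m_num(10))
  expect_true(e$persistent && e$initial_value_trigger && e$use_values_from_trigger_time)

  m <- expect_clean_parse("E1: at time > 2 and x < 1, priority = uniform(0,2): x = 5")$model
  e <- m$events[[1]]
  expect_equal(e$priority, m_call("uniform", list(m_num(0), m_num(2))))
  expect_equal(e$assignments[[1]]$math, m_num(5))

  m <- expect_clean_parse("at x > 0: y = 1")$model
  expect_true(m$events[[1]]$auto_id)
  expect_match(m$events[[1]]$id, "^_E[0-9]+$")

  bad <- rxn_parse("E2: at x > 0")
  expect_true(any(grepl("':'", bad$diagnostics$message)))
  bad2 <- rxn_parse("E2: at x > 0: ")
  expect_true(any(grepl("assignment", bad2$diagnostics$message)))
})

test_that("rules and initializations are distinguished by their left-hand side", {
  m <- expect_clean_parse(c("A1: 0 = S1 + S2", "S1 -> S2"))$model
  ru <- m$rules[[1]]
  expect_equal(ru$rule_kind, "algebraic")
  expect_equal(ru$id, "A1")
  expect_null(ru$target)

  m <- expect_clean_parse("S1 = 10")$model
  expect_equal(m$symbols$S1$initial_value, 10)

  m <- expect_clean_parse("ka = lognormal(0.1, 0.25)")$model
  expect_null(m$symbols$ka$initial_value)
  expect_length(m$initial_assignments, 1)
  expect_equal(m$initial_assignments[[1]]$math,
               m_call("lognormal", list(m_num(0.1), m_num(0.25))))

  m <- expect_clean_parse(c("x := y + 1", "z' = x"))$model
  expect_equal(m$rules[[1]]$rule_kind, "assignment")
  expect_equal(m$rules[[2]]$rule_kind, "rate")

  bad <- rxn_parse("0 := x")
  expect_true(any(bad$diagnostics$severity == "error"))
})

test_that("chained inequalities become constraints or flux bounds by subject kind", {
  m <- expect_clean_parse("10 < J2 < 50")$model
  expect_equal(m$symbols$J2$kind, "parameter")
  cn <- m$constraints[[1]]
  expect_equal(cn$lower, 10)
  expect_equal(cn$upper, 50)
  expect_true(cn$strict_lower && cn$strict_upper)

  m <- expect_clean_parse(c("R1: A -> B", "0 <= R1 <= 1000"))$model
  expect_length(m$constraints, 0)
  fb <- m$flux_bounds[[1]]
  expect_equal(fb$reaction, "R1")
  expect_equal(c(fb$lower, fb$upper), c(0, 1000))

  # bound stated before the reaction is declared is reclassified afterwards
  m <- expect_clean_parse(c("0 <= R1 <= 1000", "R1: A -> B"))$model
  expect_length(m$constraints, 0)
  expect_equal(m$flux_bounds[[1]]$reaction, "R1")

  m <- expect_clean_parse("5 < X")$model
  cn <- m$constraints[[1]]
  expect_equal(cn$lower, 5)
  expect_null(cn$upper)

  strict <- rxn_parse(c("R1: A -> B", "0 < R1 < 10"))
  expect_true(any(strict$diagnostics$severity == "warning"))
  expect_equal(strict$model$flux_bounds[[1]]$lower, 0)

  bad <- rxn_parse("1 < 2 < 3")
  expect_true(any(bad$diagnostics$severity == "error"))
})

test_that("objectives parse linear combinations of reaction ids", {
  m <- expect_clean_parse(c("R1: A -> B", "R2: B -> C", "maximize R1 + R2"))$model
  ob <- m$objectives[[1]]
  expect_equal(ob$sense, "maximize")
  expect_equal(vapply(ob$terms, function(t) t$coef, 1), c(1, 1))
  expect_equal(vapply(ob$terms, function(t) t$reaction, ""), c("R1", "R2"))

  m <- expect_clean_parse(c("J: A -> B", "minimize J"))$model
  expect_equal(m$objectives[[1]]$sense, "minimize")
  expect_length(m$objectives[[1]]$terms, 1)

  m <- expect_clean_parse(c("R1: A -> B", "R2: B -> C",
                            "maximize 2 R1 - 0.5 R2"))$model
  expect_equal(vapply(m$objectives[[1]]$terms, function(t) t$coef, 1), c(2, -0.5))

  bad <- rxn_parse(c("R1: A -> B", "maximize R1 * R1"))
  expect_true(any(bad$diagnostics$severity == "error"))
})

test_that("dot properties set uncertainty statistics and layout geometry", {
  m <- expect_clean_parse("x.mean = 10")$model
  u <- m$uncertainty[[1]]
  expect_equal(u$element, "x")
  expect_equal(u$stat, "mean")
  expect_equal(u$value, 10)

  m <- expect_clean_parse("x.position = {50, 40}")$model
  expect_equal(m$layout$positions$x, c(50, 40))
  expect_true(m$layout$enabled)

  m <- expect_clean_parse("model.layout = on")$model
  expect_true(m$layout$enabled)

  m <- expect_clean_parse("p.confidenceInterval = {1, 2}")$model
  expect_equal(m$uncertainty[[1]]$value, c(1, 2))

  bad <- rxn_parse("x.frobnicate = 1")
  expect_true(any(grepl("unknown property", bad$diagnostics$message)))
  bad2 <- rxn_parse("x.position = {1, 2, 3}")
  expect_true(any(bad2$diagnostics$severity == "error"))
})

test_that("annotation statements attach CV terms and notes", {
  m <- expect_clean_parse('S1 is "http://identifiers.org/CHEBI:17234"')$model
  a <- m$annotations[[1]]
  expect_equal(a$element, "S1")
  expect_equal(a$qualifier, "is")
  expect_equal(a$uri, "http://identifiers.org/CHEBI:17234")

  m <- expect_clean_parse('model notes "Markdown **context**"')$model
  expect_equal(m$notes[[1]]$element, "model")
  expect_equal(m$notes[[1]]$text, "Markdown **context**")

  bad <- rxn_parse('S1 frobnicates "x"')
  expect_true(any(grepl("qualifier", bad$diagnostics$message)))

  dup <- rxn_parse(c('S1 notes "one"', 'S1 notes "two"'))
  expect_true(any(dup$diagnostics$severity == "warning"))
  expect_length(dup$model$notes, 1)
  expect_equal(dup$model$notes[[1]]$text, "two")
})

test_that("substanceOnly marks species as amounts wherever it appears", {
  m <- expect_clean_parse(c("substanceOnly S1", "S1 -> S2", "S1 = 10"))$model
  expect_true(m$symbols$S1$substance_only)
  expect_false(m$symbols$S2$substance_only)
  m2 <- expect_clean_parse(c("S1 -> S2", "substanceOnly S1", "S1 = 10"))$model
  expect_true(rxn_semantic_equal(m, m2)$equal)
})

test_that("parsing is deterministic and permutation of independent statements is benign", {
  txt <- full_feature_text()
  m1 <- expect_clean_parse(txt)$model
  m2 <- expect_clean_parse(txt)$model
  expect_identical(rxn_serialize(m1), rxn_serialize(m2))

  body <- c("R1: A -> B; k*A", "k = 2", "A = 1", "10 < p < 50",
            "0 <= R1 <= 100", 'A is "http://identifiers.org/CHEBI:1"',
            "E0: at time > 1: k = 3")
  base <- expect_clean_parse(body)$model
  set.seed(33)
  for (i in 1:8) {
    perm <- expect_clean_parse(sample(body))$model
    expect_true(rxn_semantic_equal(base, perm)$equal)
  }
})

test_that("the parser survives arbitrary mutated input without crashing", {
  set.seed(404)
  seeds <- 1:15
  for (s in seeds) {
    txt <- rxn_generate(random_config(s))
    for (j in 1:10) {
      mut <- mutate_text(txt, n_mut = sample(1:8, 1))
      expect_no_error(rxn_parse(mut))
    }
  }
  # pathological fragments
  for (frag in c(";;;;", "->", "((((", "model", "end", "\"", "a b c d",
                 "S1 -> ; k1", "at :", "{}", "x.position = {", "0 = ")) {
    expect_no_error(rxn_parse(frag))
  }
})
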