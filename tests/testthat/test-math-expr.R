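test_that("expression parsing builds conventional-precedence trees", {
  n <- math_parse("k1*S1")
  expect_equal(n$kind, "binop")
  expect_equal(n$op, "*")
  expect_equal(n$left, m_sym("k1"))
  expect_equal(n$right, m_sym("S1"))

  n <- math_parse("time > 2 and x < 1")
  expect_equal(n$kind, "bool")
  expect_equal(n$op, "and")
  expect_equal(n$args[[1]], m_cmp(">", m_time(), m_num(2)))
  expect_equal(n$args[[2]], m_cmp("<", m_sym("x"), m_num(1)))

  # unary minus binds looser than ^, + looser than *
  expect_equal(math_parse("-a^b"), m_neg(m_binop("^", m_sym("a"), m_sym("b"))))
  expect_equal(math_parse("a + b*c"),
               m_binop("+", m_sym("a"), m_binop("*", m_sym("b"), m_sym("c"))))
  # ^ is right-associative
  expect_equal(math_parse("a^b^c"),
               m_binop("^", m_sym("a"), m_binop("^", m_sym("b"), m_sym("c"))))
  # ASCII boolean spellings accepted
  expect_true(rxnscript:::math_identical(math_parse("a && b || !c"),
                                         math_parse("a and b or not c")))
})

test_that("malformed expressions are rejected with positioned errors", {
  expect_error(math_parse("rateOf(3+4)"), class = "rxn_math_error")
  expect_error(math_parse("(a + b"), class = "rxn_math_error")
  expect_error(math_parse("a +* b"), class = "rxn_math_error")
  expect_error(math_parse(""), class = "rxn_math_error")
  expect_error(math_parse("uniform(1)"), class = "rxn_math_error")
  expect_error(math_parse("frobnicate(1)"), class = "rxn_math_error")
})

test_that("text rendering round-trips generated trees structurally", {
  set.seed(101)
  for (i in 1:300) {
    tree <- gen_tree(sample(1:6, 1), boolean = runif(1) < 0.3)
    txt <- math_render(tree)
    back <- math_parse(txt)
    expect_true(rxnscript:::math_identical(tree, back), info = txt)
  }
  expect_equal(math_render(m_binop("*", m_sym("k1"), m_sym("S1"))), "k1 * S1")
  expect_equal(math_render(m_num(0)), "0")
})

test_that("MathML conversion is exact and inverse on generated trees", {
  x <- math_to_mathml(m_call("rateOf", list(m_sym("G"))))
  expect_match(x, 'definitionURL="http://www.sbml.org/sbml/symbols/rateOf"')
  x <- math_to_mathml(m_call("uniform", list(m_num(0), m_num(1))))
  expect_match(x, 'definitionURL="http://www.sbml.org/sbml/symbols/distrib/uniform"')
  expect_match(x, "<cn type=\"integer\">0</cn><cn type=\"integer\">1</cn>")
  expect_match(math_to_mathml(m_num(10)), '<cn type="integer">10</cn>')
  expect_match(math_to_mathml(m_time()),
               'definitionURL="http://www.sbml.org/sbml/symbols/time"')

  set.seed(202)
  for (i in 1:300) {
    tree <- gen_tree(sample(1:6, 1), boolean = runif(1) < 0.3)
    back <- math_from_mathml(math_to_mathml(tree))
    expect_true(rxnscript:::math_identical(tree, back),
                info = math_render(tree))
  }
})

test_that("unsupported MathML elements raise named errors", {
  bad <- '<math xmlns="http://www.w3.org/1998/Math/MathML"><piecewise/></math>'
  expect_error(math_from_mathml(bad), "piecewise", class = "rxn_mathml_error")
  lam <- '<math xmlns="http://www.w3.org/1998/Math/MathML"><lambda/></math>'
  expect_error(math_from_mathml(lam), "lambda", class = "rxn_mathml_error")
  # n-ary plus from external writers folds to nested binary nodes
  nary <- paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">',
                 "<apply><plus/><ci>a</ci><ci>b</ci><ci>c</ci></apply></math>")
  expect_true(rxnscript:::math_identical(math_from_mathml(nary),
                                         math_parse("a + b + c")))
})

test_that("numeric evaluation follows arithmetic and boolean semantics", {
  expect_equal(math_eval(math_parse("2^3 - 1")), 7)
  expect_equal(math_eval(math_parse("2 < 3")), 1)
  expect_equal(math_eval(math_parse("2 > 3 or 1 <= 1")), 1)
  expect_equal(math_eval(math_parse("not (1 == 1)")), 0)
  expect_equal(math_eval(math_parse("k*S"), list(k = 2, S = 3.5)), 7)
  expect_equal(math_eval(math_parse("ln(exp(2))")), 2)
  expect_error(math_eval(math_parse("k*S"), list(k = 2)), "unbound")
  expect_error(math_eval(math_parse("rateOf(G)"), list(G = 1)), "rateOf")
  expect_error(math_eval(math_parse("time + 1")), "time")
})

test_that("distribution draws are seeded, pure, and domain-checked", {
  e <- math_parse("uniform(0, 2)")
  set.seed(7); a <- replicate(50, math_eval(e))
  set.seed(7); b <- replicate(50, math_eval(e))
  expect_identical(a, b)
  set.seed(1)
  m <- mean(replicate(5000, math_eval(e)))
  expect_lt(abs(m - 1), 0.05)
  expect_error(math_eval(math_parse("uniform(2, 2)")), "lower bound")
  expect_error(math_eval(math_parse("normal(0, 0)")), "standard deviation")
  expect_error(math_eval(math_parse("binomial(3, 2)")), "p must be")
})
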