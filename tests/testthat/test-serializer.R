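test_that("serialization produces the canonical surface forms", {
  m <- expect_clean_parse("S1 -> S2; k1*S1")$model
  txt <- rxn_serialize(m)
  expect_match(txt, "S1 -> S2; k1 \\* S1")
  expect_match(txt, "^model __main\n")
  expect_match(txt, "\nend\n$")

  empty <- rxn_serialize(rxn_model("m1"))
  expect_equal(empty, "model m1\nend\n")

  # unit stoichiometries are elided, larger ones kept
  m <- expect_clean_parse("2 A + B -> 3 C")$model
  expect_match(rxn_serialize(m), "2 A \\+ B -> 3 C")
})

test_that("serializer refuses models with validation errors", {
  m <- rxn_model()
  rxn_declare(m, "S1", "species")
  m$reactions[[1]] <- rxnscript:::new_reaction(
    "J1", list(rxnscript:::species_ref("S1")), list(),
    kinetic_math = math_parse("missing_k * S1"))
  rxn_declare(m, "J1", "reaction")
  expect_error(rxn_serialize(m), "validation errors")
})

test_that("parse-serialize is lossless and byte-idempotent on generated corpora", {
  for (s in 1:60) {
    txt <- rxn_generate(random_config(s))
    p1 <- rxn_parse(txt)
    expect_equal(sum(p1$diagnostics$severity == "error"), 0, info = txt)
    t1 <- rxn_serialize(p1$model)
    p2 <- rxn_parse(t1)
    eq <- rxn_semantic_equal(p1$model, p2$model)
    expect_true(eq$equal, info = paste(c(txt, eq$differences), collapse = "\n"))
    expect_identical(rxn_serialize(p2$model), t1, info = txt)
  }
})

test_that("worked full-feature model is stable through two parse-serialize cycles", {
  t1 <- rxn_serialize(expect_clean_parse(full_feature_text())$model)
  t2 <- rxn_serialize(expect_clean_parse(t1)$model)
  expect_identical(t1, t2)
})
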