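test_that("implicit declaration and kind promotion follow the ladder", {
  m <- rxn_model()
  rxn_declare(m, "S1", "species")          # structural role: reaction side
  rxn_declare(m, "S1", "parameter")        # later math reference
  expect_equal(m$symbols$S1$kind, "species")

  rxn_declare(m, "k1", "parameter")        # first seen in a rate law
  expect_equal(m$symbols$k1$kind, "parameter")
  rxn_declare(m, "k1", "stoichiometry")    # coefficient position promotes
  expect_equal(m$symbols$k1$kind, "stoichiometry")

  rxn_declare(m, "X", "parameter", explicit = TRUE)
  expect_error(rxn_declare(m, "X", "compartment", explicit = TRUE),
               class = "rxn_conflict_error")
  # implicit structural kinds cannot cross to another structural kind
  rxn_declare(m, "C", "compartment")
  expect_error(rxn_declare(m, "C", "species"), class = "rxn_conflict_error")
  expect_error(rxn_declare(m, "time", "parameter"), class = "rxn_conflict_error")
})

test_that("final kind depends only on the set of structural roles", {
  roles <- list(
    species = c("parameter", "species", "parameter"),
    stoichiometry = c("parameter", "parameter", "stoichiometry"),
    compartment = c("compartment", "parameter"),
    parameter = c("parameter", "parameter")
  )
  set.seed(11)
  for (want in names(roles)) {
    seq0 <- roles[[want]]
    for (p in 1:6) {
      m <- rxn_model()
      for (k in sample(seq0)) rxn_declare(m, "id1", k)
      expect_equal(m$symbols$id1$kind, want)
    }
  }
})

test_that("validation finds invariant violations and is idempotent", {
  m <- rxn_model("empty1")
  expect_equal(nrow(rxn_validate(m)), 0)

  res <- expect_clean_parse(c("R1: S1 -> S2; k*S1", "0 <= R1 <= 1000"))
  expect_equal(nrow(rxn_validate(res$model)), 0)

  # assignment rule targeting a const symbol
  bad <- rxn_parse(c("const kx", "kx := 2"))
  d <- bad$diagnostics
  expect_true(any(d$severity == "error" & grepl("constant", d$message)))

  # undeclared reference (hand-built model skips the parser's auto-declare)
  m <- rxn_model()
  rxn_declare(m, "S1", "species")
  m$reactions[[1]] <- rxnscript:::new_reaction(
    "J1", list(rxnscript:::species_ref("S1")), list(),
    kinetic_math = math_parse("k_missing * S1"))
  rxn_declare(m, "J1", "reaction")
  d1 <- rxn_validate(m)
  expect_true(any(grepl("k_missing", d1$message)))
  expect_identical(d1, rxn_validate(m))
})

test_that("semantic equality ignores order and generated ids, and is an equivalence", {
  a <- expect_clean_parse(c("J1: A -> B; k*A", "J2: B -> C"))$model
  b <- expect_clean_parse(c("J2: B -> C", "J1: A -> B; k*A"))$model
  expect_true(rxn_semantic_equal(a, a)$equal)
  expect_true(rxn_semantic_equal(a, b)$equal)
  expect_true(rxn_semantic_equal(b, a)$equal)

  # unlabeled reactions get auto ids that are not compared
  c1 <- expect_clean_parse(c("A -> B; k*A", "B -> C"))$model
  c2 <- expect_clean_parse(c("B -> C", "A -> B; k*A"))$model
  expect_true(rxn_semantic_equal(c1, c2)$equal)

  d1 <- expect_clean_parse(c("R1: A -> B", "0 <= R1 <= 1000"))$model
  d2 <- expect_clean_parse(c("R1: A -> B", "0 <= R1 <= 999"))$model
  res <- rxn_semantic_equal(d1, d2)
  expect_false(res$equal)
  expect_length(res$differences, 2)  # one per direction of the changed bound

  # transitivity across a three-model chain
  e1 <- expect_clean_parse(full_feature_text())$model
  e2 <- rxn_parse(rxn_serialize(e1))$model
  e3 <- rxn_parse(rxn_serialize(e2))$model
  expect_true(rxn_semantic_equal(e1, e2)$equal)
  expect_true(rxn_semantic_equal(e2, e3)$equal)
  expect_true(rxn_semantic_equal(e1, e3)$equal)
})
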