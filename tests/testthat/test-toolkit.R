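test_that("the generator is deterministic and produces parseable fixtures", {
  cfg0 <- rxn_generator_config(seed = 1, n_species = 0, n_reactions = 0)
  txt0 <- rxn_generate(cfg0)
  m0 <- expect_clean_parse(txt0)$model
  expect_length(m0$symbols, 0)
  expect_length(m0$reactions, 0)

  cfg <- rxn_generator_config(seed = 7, n_species = 5, n_reactions = 4, fbc = TRUE)
  txt <- rxn_generate(cfg)
  expect_identical(txt, rxn_generate(cfg))
  expect_match(txt, "maximize")
  expect_match(txt, "[0-9] <= R[0-9]+ <= [0-9]")
  expect_clean_parse(txt)

  # generated output never triggers parser errors across the seeded lattice
  for (s in 61:140) {
    res <- rxn_parse(rxn_generate(random_config(s)))
    expect_equal(sum(res$diagnostics$severity == "error"), 0)
  }
})

test_that("generation does not disturb the caller's random stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(rxn_generate(rxn_generator_config(seed = 3)))
  expect_identical(runif(1), before)
})

test_that("round-trip checking passes on worked examples and reports failures", {
  expect_true(rxn_roundtrip("S1 -> S2; k1*S1")$pass)

  # statements reconstructed from the worked examples of each feature family
  corpus <- c(
    'S1 is "http://identifiers.org/CHEBI:17234"',
    paste("R1: A -> B", "0 <= R1 <= 1000", "maximize R1", sep = "\n"),
    "E0: at time > 3: k4 = 10",
    paste("E0: at time > 2 and x < 1, priority = uniform(0,1): x = 3",
          "E1: at time > 2 and x < 1, priority = uniform(0,2): x = 5", sep = "\n"),
    "ka = lognormal(0.1, 0.25)",
    "A1: 0 = S1 + S2\nS1 -> S2",
    "10 < J2 < 50",
    "x.mean = 10\nx.standardDeviation = 2",
    "substanceOnly S1\nS1 = 10\nS1 -> S2",
    "J0: n L -> RL; k*L^n\nn = 3",
    "G' = -1\nH := rateOf(G)\nn_increase: -> N; H*N",
    "model.layout = on\nS1 -> S2\nS1.position = {50, 40}"
  )
  for (txt in corpus) {
    rt <- rxn_roundtrip(txt)
    expect_true(rt$pass, info = paste(c(txt, "----", rt$differences), collapse = "\n"))
  }

  rt_bad <- rxn_roundtrip("this is not ( a model")
  expect_false(rt_bad$pass)
  expect_match(rt_bad$differences[1], "parse error")
})

test_that("priority race converges to the analytic 3/4", {
  expect_true(priority_race(1, seed = 2) %in% c(0, 1))
  # analytic oracle: P(u1 > u0) = 1 - P(u1 < u0) = 1 - 1/2 * 1/2 = 3/4
  f <- priority_race(4000, seed = 11)
  expect_lt(abs(f - 0.75), 0.03)
  # identical seed, identical result
  expect_identical(priority_race(500, seed = 5), priority_race(500, seed = 5))
  # shrinking error with growing n under one seed family
  err1 <- abs(priority_race(500, seed = 1) - 0.75)
  err2 <- abs(priority_race(20000, seed = 1) - 0.75)
  expect_lt(err2, max(err1, 0.02))
})

test_that("the command-line converter performs both translations", {
  skip_on_os("windows")
  cli <- system.file("cli", "rxnscript", package = "rxnscript")
  skip_if(cli == "", "CLI script not installed")
  tmp <- withr::local_tempdir()
  ant <- file.path(tmp, "m.rxn")
  xml <- file.path(tmp, "m.xml")
  back <- file.path(tmp, "back.rxn")
  writeLines("S1 -> S2; k1*S1", ant)
  rs <- function(...) system2("Rscript", c(cli, ...), stdout = TRUE, stderr = TRUE)
  rs("a2s", ant, "-o", xml)
  expect_true(file.exists(xml))
  expect_equal(nrow(sbml_check(paste(readLines(xml), collapse = "\n"))), 0)
  rs("s2a", xml, "-o", back)
  m1 <- rxn_parse(readLines(ant))$model
  m2 <- rxn_parse(readLines(back))$model
  expect_true(rxn_semantic_equal(m1, m2)$equal)
  # converting the converted text again is idempotent
  xml2_path <- file.path(tmp, "m2.xml")
  rs("a2s", back, "-o", xml2_path)
  expect_identical(readLines(xml2_path), readLines(xml))
})
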