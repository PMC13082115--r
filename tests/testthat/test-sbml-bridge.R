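read_doc <- function(txt) xml2::read_xml(txt)
# attribute lookup tolerant of namespace-prefix stripping
attr1 <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | endsWith(names(at), paste0(":", name)))
  if (length(hit) == 0) NA_character_ else unname(at[hit[1]])
}
find1 <- function(doc, name) {
  xml2::xml_find_first(doc, paste0("//*[local-name()='", name, "']"))
}
findall <- function(doc, name) {
  xml2::xml_find_all(doc, paste0("//*[local-name()='", name, "']"))
}

test_that("flux bounds export as constant parameters referenced by the reaction", {
  m <- expect_clean_parse(c("R1: A -> B", "0 <= R1 <= 1000"))$model
  ex <- sbml_export(m)
  expect_true("fbc" %in% ex$packages_used)
  expect_match(ex$document, 'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"')
  doc <- read_doc(ex$document)
  rx <- find1(doc, "reaction")
  lb <- attr1(rx, "lowerFluxBound")
  ub <- attr1(rx, "upperFluxBound")
  pars <- findall(doc, "parameter")
  vals <- stats::setNames(xml2::xml_attr(pars, "value"), xml2::xml_attr(pars, "id"))
  expect_equal(as.numeric(vals[[lb]]), 0)
  expect_equal(as.numeric(vals[[ub]]), 1000)
  expect_equal(xml2::xml_attr(pars, "constant"), rep("true", length(pars)))
})

test_that("an empty model exports as a minimal core-only L3V2 document", {
  ex <- sbml_export(rxn_model("m0"))
  expect_length(ex$packages_used, 0)
  doc <- read_doc(ex$document)
  root <- xml2::xml_root(doc)
  expect_equal(xml2::xml_name(root), "sbml")
  expect_equal(xml2::xml_attr(root, "level"), "3")
  expect_equal(xml2::xml_attr(root, "version"), "2")
  expect_false(grepl("fbc|distrib|layout", ex$document))
  expect_equal(nrow(sbml_check(ex$document)), 0)
})

test_that("uncertainty statistics export as distrib uncertainty parameters", {
  m <- expect_clean_parse("x.mean = 10")$model
  ex <- sbml_export(m)
  expect_true("distrib" %in% ex$packages_used)
  doc <- read_doc(ex$document)
  up <- find1(doc, "uncertParameter")
  expect_equal(attr1(up, "type"), "mean")
  expect_equal(as.numeric(attr1(up, "value")), 10)

  m2 <- expect_clean_parse("p.confidenceInterval = {1, 2}")$model
  doc2 <- read_doc(sbml_export(m2)$document)
  sp <- find1(doc2, "uncertSpan")
  expect_equal(attr1(sp, "type"), "confidenceInterval")
  expect_equal(as.numeric(c(attr1(sp, "valueLower"), attr1(sp, "valueUpper"))),
               c(1, 2))
})

test_that("species mapping honours substanceOnly, boundary and compartments", {
  m <- expect_clean_parse(c("compartment c1", "species A in c1, $B",
                            "substanceOnly A", "A = 10", "B = 2",
                            "A -> B"))$model
  doc <- read_doc(sbml_export(m)$document)
  sps <- findall(doc, "species")
  ids <- xml2::xml_attr(sps, "id")
  a <- sps[[which(ids == "A")]]
  b <- sps[[which(ids == "B")]]
  expect_equal(xml2::xml_attr(a, "hasOnlySubstanceUnits"), "true")
  expect_equal(xml2::xml_attr(a, "initialAmount"), "10")
  expect_true(is.na(xml2::xml_attr(a, "initialConcentration")))
  expect_equal(xml2::xml_attr(a, "compartment"), "c1")
  expect_equal(xml2::xml_attr(b, "hasOnlySubstanceUnits"), "false")
  expect_equal(xml2::xml_attr(b, "initialConcentration"), "2")
  expect_equal(xml2::xml_attr(b, "boundaryCondition"), "true")

  # species without a compartment get the auto-created default
  doc2 <- read_doc(sbml_export(expect_clean_parse("X -> Y")$model)$document)
  cps <- findall(doc2, "compartment")
  expect_equal(xml2::xml_attr(cps, "id"), "default_compartment")
  expect_equal(xml2::xml_attr(cps, "size"), "1")
})

test_that("constraints export as conjoined comparisons preserving strictness", {
  m <- expect_clean_parse("10 < J2 <= 50")$model
  doc <- read_doc(sbml_export(m)$document)
  cn <- find1(doc, "constraint")
  math <- xml2::xml_find_first(cn, ".//*[local-name()='math']")
  node <- math_from_mathml(math)
  expect_equal(node$kind, "bool")
  expect_equal(node$op, "and")
  expect_equal(node$args[[1]], m_cmp("<", m_num(10), m_sym("J2")))
  expect_equal(node$args[[2]], m_cmp("<=", m_sym("J2"), m_num(50)))
})

test_that("import inverts export on the full-feature model with nothing dropped", {
  m <- expect_clean_parse(full_feature_text())$model
  ex <- sbml_export(m)
  expect_setequal(ex$packages_used, c("fbc", "distrib", "layout"))
  expect_equal(nrow(sbml_check(ex$document)), 0)
  im <- sbml_import(ex$document)
  expect_equal(nrow(im$dropped), 0)
  eq <- rxn_semantic_equal(m, im$model)
  expect_true(eq$equal, info = paste(eq$differences, collapse = "\n"))
  expect_equal(nrow(rxn_validate(im$model)), 0)
  # event priority distribution survives the round trip as a draw call
  e1 <- Filter(function(e) e$id == "E1", im$model$events)[[1]]
  expect_equal(e1$priority, m_call("uniform", list(m_num(0), m_num(2))))
  # named stoichiometry value survives via its initial assignment
  expect_equal(im$model$symbols$n$initial_value, 3)
})

test_that("unsupported constructs are dropped loudly, never silently", {
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2"',
    ' xmlns:comp="http://www.sbml.org/sbml/level3/version1/comp/version1">',
    '<model id="m">',
    "<listOfUnitDefinitions><unitDefinition id=\"u\"/></listOfUnitDefinitions>",
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    "</model></sbml>")
  im <- sbml_import(doc)
  expect_gte(nrow(im$dropped), 2)
  expect_true(any(grepl("comp", im$dropped$construct)))
  expect_true(any(im$dropped$construct == "listOfUnitDefinitions"))
  expect_equal(im$model$symbols$c$kind, "compartment")
})

test_that("pre-Level-3 documents are rejected naming the level", {
  l2 <- paste0('<sbml xmlns="http://www.sbml.org/sbml/level2/version4" ',
               'level="2" version="4"><model id="m"/></sbml>')
  expect_error(sbml_import(l2), "level 2", class = "rxn_sbml_error")
  expect_error(sbml_import("<notsbml/>"), "not an SBML", class = "rxn_sbml_error")
})

test_that("document checking flags structural defects", {
  ok <- sbml_export(expect_clean_parse("S1 -> S2; k*S1")$model)$document
  expect_equal(nrow(sbml_check(ok)), 0)

  miss <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '<model id="m"><listOfSpecies><species id="S1" hasOnlySubstanceUnits="false"',
    ' boundaryCondition="false" constant="false"/></listOfSpecies></model></sbml>')
  d <- sbml_check(miss)
  expect_true(any(grepl("compartment", d$message)))

  dup <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    '<model id="m"><listOfParameters>',
    '<parameter id="p" constant="true"/><parameter id="p" constant="true"/>',
    "</listOfParameters></model></sbml>")
  d2 <- sbml_check(dup)
  expect_true(any(grepl("duplicate id 'p'", d2$message)))
})

test_that("namespace declarations are minimal per feature partition", {
  partitions <- list(
    core = rxn_generator_config(seed = 5),
    fbc = rxn_generator_config(seed = 6, fbc = TRUE),
    distrib = rxn_generator_config(seed = 7, distrib = TRUE),
    layout = rxn_generator_config(seed = 8, layout = TRUE)
  )
  for (nm in names(partitions)) {
    m <- expect_clean_parse(rxn_generate(partitions[[nm]]))$model
    ex <- sbml_export(m)
    if (nm == "core") {
      expect_length(ex$packages_used, 0)
      expect_false(grepl("fbc|distrib|layout", ex$document))
    } else {
      expect_true(nm %in% ex$packages_used)
      expect_setequal(ex$packages_used, nm)
    }
    # declared namespaces exactly match reported packages
    for (pkg in c("fbc", "distrib", "layout")) {
      expect_equal(grepl(paste0("xmlns:", pkg), ex$document),
                   pkg %in% ex$packages_used)
    }
  }
})

test_that("export is deterministic byte-for-byte", {
  m <- expect_clean_parse(full_feature_text())$model
  expect_identical(sbml_export(m)$document, sbml_export(m)$document)
  m2 <- expect_clean_parse(full_feature_text())$model
  expect_identical(sbml_export(m)$document, sbml_export(m2)$document)
})
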