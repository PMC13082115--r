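# ---- round-trip checker and Monte-Carlo utilities ---------------------------

#' Check lossless round-tripping of a model text
#'
#' Runs text -> model -> SBML -> model -> text and verifies that (i)
#' re-parsing the canonical text reproduces the model, (ii) the SBML
#' round-trip reproduces the model with an empty dropped list, and (iii) the
#' second-generation canonical text is byte-identical to the first. This is
#' the package's losslessness claim in executable form.
#'
#' @param text character: model source text.
#' @return A list of class `rxn_roundtrip`: `pass` plus the per-stage flags
#'   `text_equal`, `sbml_equal`, `text_identical`, the `dropped` table, the
#'   difference reports and the diagnostics of the initial parse.
#' @examples
#' rxn_roundtrip("S1 -> S2; k1*S1")$pass
#' @export
rxn_roundtrip <- function(text) {
  p1 <- rxn_parse(text)
  errs <- diag_errors(p1$diagnostics)
  if (nrow(errs) > 0) {
    return(structure(list(pass = FALSE, text_equal = FALSE, sbml_equal = FALSE,
                          text_identical = FALSE,
                          dropped = data.frame(construct = character(),
                                               reason = character()),
                          differences = sprintf("parse error: %s", errs$message),
                          diagnostics = p1$diagnostics),
                     class = "rxn_roundtrip"))
  }
  t1 <- rxn_serialize(p1$model)
  p2 <- rxn_parse(t1)
  eq_text <- rxn_semantic_equal(p1$model, p2$model)
  ex <- sbml_export(p1$model)
  im <- sbml_import(ex$document)
  eq_sbml <- rxn_semantic_equal(p1$model, im$model)
  t2 <- rxn_serialize(im$model)
  pass <- eq_text$equal && eq_sbml$equal && identical(t1, t2) &&
    nrow(im$dropped) == 0
  structure(
    list(pass = pass, text_equal = eq_text$equal, sbml_equal = eq_sbml$equal,
         text_identical = identical(t1, t2), dropped = im$dropped,
         differences = c(eq_text$differences, eq_sbml$differences),
         diagnostics = p1$diagnostics),
    class = "rxn_roundtrip"
  )
}

#' @export
print.rxn_roundtrip <- function(x, ...) {
  cat(sprintf("round-trip: %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  text re-parse equal:  %s\n", x$text_equal))
  cat(sprintf("  SBML round-trip equal: %s\n", x$sbml_equal))
  cat(sprintf("  canonical text stable: %s\n", x$text_identical))
  if (nrow(x$dropped) > 0) {
    cat(sprintf("  dropped: %s\n",
                paste(x$dropped$construct, collapse = ", ")))
  }
  for (d in utils::head(x$differences, 10)) cat("  - ", d, "\n", sep = "")
  invisible(x)
}

#' Monte-Carlo event-priority race
#'
#' Draws `n` independent pairs, `u0` from `uniform(0, 1)` and `u1` from
#' `uniform(0, 2)`, through the expression evaluator, and returns the
#' fraction of pairs with `u1 > u0`. This reproduces the ordering
#' probability of two simultaneous events whose priorities are sampled from
#' those distributions: the wider-distribution event wins with probability
#' 3/4 (integrating, `P(u1 < u0)` requires `u1 < 1`, which has probability
#' 1/2 times 1/2).
#'
#' @param n number of trials (>= 1).
#' @param seed integer seed.
#' @return Fraction in `[0, 1]` of trials where the `uniform(0, 2)` draw is
#'   larger.
#' @examples
#' priority_race(1000, seed = 1)
#' @export
priority_race <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  e0 <- math_parse("uniform(0, 1)")
  e1 <- math_parse("uniform(0, 2)")
  wins <- 0L
  for (i in seq_len(n)) {
    u0 <- math_eval(e0)
    u1 <- math_eval(e1)
    if (u1 > u0) wins <- wins + 1L
  }
  wins / n
}
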