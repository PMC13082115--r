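# ---- seeded random model generator ------------------------------------------

#' Generator configuration
#'
#' Configuration for the seeded random fixture generator used by the
#' round-trip property suites. Feature flags switch language features on;
#' every enabled feature appears in the output at least once when the
#' species/reaction budget allows.
#'
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param n_species,n_reactions non-negative counts.
#' @param events,rules,constraints,fbc,distrib,layout,annotations,named_stoich,substance_only
#'   feature flags.
#' @param max_math_depth maximum expression-tree depth (<= 8).
#' @return A list of class `rxn_generator_config`.
#' @export
rxn_generator_config <- function(seed = 1L, n_species = 5L, n_reactions = 4L,
                                 events = FALSE, rules = FALSE,
                                 constraints = FALSE, fbc = FALSE,
                                 distrib = FALSE, layout = FALSE,
                                 annotations = FALSE, named_stoich = FALSE,
                                 substance_only = FALSE, max_math_depth = 3L) {
  stopifnot(n_species >= 0, n_reactions >= 0, max_math_depth <= 8)
  structure(
    list(seed = as.integer(seed), n_species = as.integer(n_species),
         n_reactions = as.integer(n_reactions), events = events, rules = rules,
         constraints = constraints, fbc = fbc, distrib = distrib,
         layout = layout, annotations = annotations,
         named_stoich = named_stoich, substance_only = substance_only,
         max_math_depth = as.integer(max_math_depth)),
    class = "rxn_generator_config"
  )
}

gen_num <- function() {
  v <- round(stats::runif(1, 0.1, 9.9), 2)
  if (stats::runif(1) < 0.3) v <- round(v)
  if (v <= 0) v <- 1
  v
}

gen_expr_text <- function(vars, depth) {
  if (depth <= 0 || length(vars) == 0 || stats::runif(1) < 0.35) {
    if (length(vars) > 0 && stats::runif(1) < 0.6) {
      return(sample(vars, 1))
    }
    return(fmt_num(gen_num()))
  }
  op <- sample(c("+", "-", "*", "/", "^"), 1, prob = c(.3, .2, .3, .15, .05))
  lhs <- gen_expr_text(vars, depth - 1L)
  rhs <- if (op == "^") fmt_num(sample(2:3, 1)) else gen_expr_text(vars, depth - 1L)
  paste0("(", lhs, " ", op, " ", rhs, ")")
}

#' Generate a random model as text
#'
#' Produces a deterministic (seed-driven) plain-text model exercising the
#' requested language features. The output always parses with zero error
#' diagnostics, which makes it suitable as a round-trip fixture corpus.
#'
#' @param config an [rxn_generator_config()].
#' @return character scalar: model text.
#' @examples
#' cat(rxn_generate(rxn_generator_config(seed = 7, fbc = TRUE)))
#' @export
rxn_generate <- function(config = rxn_generator_config()) {
  stopifnot(inherits(config, "rxn_generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(config$seed)

  ns <- config$n_species
  nr <- config$n_reactions
  species <- if (ns > 0) paste0("S", seq_len(ns)) else character(0)
  out <- character(0)
  emit <- function(...) out <<- c(out, paste0(...))

  emit("model fixture", config$seed)

  use_comp <- ns > 0 && stats::runif(1) < 0.5
  if (use_comp) {
    emit("compartment c1")
    emit("species ", paste(paste0(species, " in c1"), collapse = ", "))
  } else if (ns > 0) {
    emit("species ", paste(species, collapse = ", "))
  }
  if (config$substance_only && ns > 0) {
    emit("substanceOnly ", species[1])
  }

  params <- character(0)
  rxn_ids <- character(0)
  stoich_used <- FALSE
  for (i in seq_len(nr)) {
    if (ns == 0) break
    rid <- paste0("R", i)
    rxn_ids <- c(rxn_ids, rid)
    nreac <- sample(1:min(2, ns), 1)
    nprod <- sample(1:min(2, ns), 1)
    reac <- sample(species, nreac)
    prod <- sample(species, nprod)
    term <- function(sp) {
      if (stats::runif(1) < 0.2) paste0(sample(2:3, 1), " ", sp) else sp
    }
    lhs_terms <- vapply(reac, term, "")
    if (config$named_stoich && !stoich_used) {
      lhs_terms[1] <- paste0("n1 ", reac[1])
      stoich_used <- TRUE
    }
    k <- paste0("k", i)
    params <- c(params, k)
    rate_vars <- c(k, reac)
    if (stoich_used && grepl("^n1 ", lhs_terms[1])) rate_vars <- c(rate_vars, "n1")
    rate <- paste0(k, " * ", gen_expr_text(rate_vars, config$max_math_depth - 1L))
    emit(rid, ": ", paste(lhs_terms, collapse = " + "), " -> ",
         paste(vapply(prod, term, ""), collapse = " + "), "; ", rate)
  }
  if (stoich_used) emit("n1 = ", fmt_num(sample(2:4, 1)))

  for (k in params) {
    if (stats::runif(1) < 0.7) emit(k, " = ", fmt_num(gen_num()))
  }
  for (sp in utils::head(species, 2)) {
    emit(sp, " = ", fmt_num(gen_num()))
  }
  if (config$distrib) {
    emit("kd1 = lognormal(0.1, 0.25)")
    emit("kd2 = uniform(0, ", fmt_num(gen_num()), ")")
    if (length(species) > 0) emit(species[1], ".mean = ", fmt_num(gen_num()))
    emit("kd1.confidenceInterval = {1, 2}")
  }

  if (config$rules) {
    vars <- c(params, species)
    emit("za := ", gen_expr_text(vars, 2L))
    emit("wa' = ", gen_expr_text(c(vars, "za"), 2L))
    if (length(species) > 0) {
      emit("alg1: 0 = ", species[1], " - ", gen_expr_text(vars, 1L))
    }
  }

  if (config$events) {
    tgt <- if (length(params) > 0) params[1] else "pE"
    emit("E1: at time > ", fmt_num(gen_num()), ": ", tgt, " = ", fmt_num(gen_num()))
    if (config$distrib) {
      emit("E2: at time > 2 and ", tgt, " < 1, priority = uniform(0, 2): ",
           tgt, " = 5")
    }
  }

  if (config$constraints) {
    emit("10 < pc1 < 50")
    emit("pc2 <= 4")
  }

  if (config$fbc && length(rxn_ids) > 0) {
    for (rid in utils::head(rxn_ids, 2)) {
      emit("0 <= ", rid, " <= ", fmt_num(round(stats::runif(1, 100, 1000))))
    }
    emit("maximize ", paste(utils::head(rxn_ids, 2), collapse = " + "))
  }

  if (config$annotations) {
    if (length(species) > 0) {
      emit(species[1], " is \"http://identifiers.org/CHEBI:", sample(10000:99999, 1), "\"")
    }
    emit("model is \"http://identifiers.org/biomodels.db/BIOMD", sample(1000:9999, 1), "\"")
    emit("model notes \"generated fixture model\"")
  }

  if (config$layout) {
    emit("model.layout = on")
    if (length(species) > 0 && stats::runif(1) < 0.7) {
      for (i in seq_len(min(2, ns))) {
        emit(species[i], ".position = {", fmt_num(round(stats::runif(1, 0, 500))),
             ", ", fmt_num(round(stats::runif(1, 0, 500))), "}")
      }
      if (length(rxn_ids) > 0) {
        emit(rxn_ids[1], ".curvePoints = {0, 0, ",
             fmt_num(round(stats::runif(1, 10, 100))), ", 40}")
      }
    }
  }

  emit("end")
  paste0(paste(out, collapse = "\n"), "\n")
}
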