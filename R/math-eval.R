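# ---- numeric evaluation -----------------------------------------------------

#' Evaluate a math expression numerically
#'
#' Evaluates a tree under a set of symbol bindings. Comparisons and boolean
#' connectives return 1/0. Distribution draws consume values from R's random
#' number stream, so results are reproducible given `set.seed()`; parameter
#' domains are checked at evaluation time (`sd > 0`, `lo < hi`, ...).
#' `rateOf` and the `time` csymbol have no value outside a simulation and
#' are rejected.
#'
#' @param node a math node.
#' @param bindings named list or numeric vector mapping symbol ids to values.
#' @return numeric scalar.
#' @examples
#' math_eval(math_parse("2^3 - 1"))
#' set.seed(1)
#' math_eval(math_parse("uniform(0, 2)"))
#' @export
math_eval <- function(node, bindings = list()) {
  b <- unlist(bindings)
  ev <- function(n) {
    switch(n$kind,
      num = n$value,
      sym = {
        if (is.null(b) || is.na(match(n$id, names(b)))) {
          stop("unbound symbol '", n$id, "'", call. = FALSE)
        }
        unname(b[[n$id]])
      },
      time = stop("'time' cannot be evaluated outside a simulation", call. = FALSE),
      neg = -ev(n$x),
      binop = {
        l <- ev(n$left); r <- ev(n$right)
        switch(n$op, "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r, "^" = l^r)
      },
      cmp = {
        l <- ev(n$left); r <- ev(n$right)
        as.numeric(switch(n$op,
          "<" = l < r, "<=" = l <= r, ">" = l > r, ">=" = l >= r,
          "==" = l == r, "!=" = l != r
        ))
      },
      bool = {
        vals <- vapply(n$args, ev, numeric(1)) != 0
        as.numeric(switch(n$op,
          and = all(vals), or = any(vals), not = !vals[[1]]
        ))
      },
      call = eval_call(n, ev),
      stop("cannot evaluate node kind '", n$kind, "'", call. = FALSE)
    )
  }
  ev(node)
}

eval_call <- function(n, ev) {
  if (n$fn == "rateOf") {
    stop("rateOf cannot be evaluated outside a simulation", call. = FALSE)
  }
  a <- vapply(n$args, ev, numeric(1))
  if (n$fn %in% names(DRAW_FUNCTIONS)) return(draw_sample(n$fn, a))
  switch(n$fn,
    abs = abs(a), exp = exp(a), ln = log(a), log10 = log10(a), sqrt = sqrt(a),
    sin = sin(a), cos = cos(a), tan = tan(a),
    asin = asin(a), acos = acos(a), atan = atan(a),
    sinh = sinh(a), cosh = cosh(a), tanh = tanh(a),
    floor = floor(a), ceiling = ceiling(a),
    stop("unknown function '", n$fn, "'", call. = FALSE)
  )
}

draw_sample <- function(fn, a) {
  bad <- function(msg) stop(fn, ": ", msg, call. = FALSE)
  switch(fn,
    normal = {
      if (a[2] <= 0) bad("standard deviation must be > 0")
      stats::rnorm(1, mean = a[1], sd = a[2])
    },
    uniform = {
      if (a[1] >= a[2]) bad("lower bound must be < upper bound")
      stats::runif(1, min = a[1], max = a[2])
    },
    lognormal = {
      if (a[2] <= 0) bad("sigma must be > 0")
      stats::rlnorm(1, meanlog = a[1], sdlog = a[2])
    },
    exponential = {
      if (a[1] <= 0) bad("rate must be > 0")
      stats::rexp(1, rate = a[1])
    },
    gamma = {
      if (a[1] <= 0 || a[2] <= 0) bad("shape and scale must be > 0")
      stats::rgamma(1, shape = a[1], scale = a[2])
    },
    poisson = {
      if (a[1] < 0) bad("rate must be >= 0")
      stats::rpois(1, lambda = a[1])
    },
    binomial = {
      if (a[1] < 0 || a[1] != floor(a[1])) bad("n must be a non-negative integer")
      if (a[2] < 0 || a[2] > 1) bad("p must be in [0, 1]")
      stats::rbinom(1, size = a[1], prob = a[2])
    }
  )
}
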