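#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG to a reproducible state for the duration of `code` and
#' restores the caller's RNG state afterwards, so seeded operations never
#' disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive child seeds from a master seed
#'
#' @param seed Master seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @keywords internal
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

## scalar validation helpers ------------------------------------------------

assertScalarNumeric <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("'%s' must be > %g", name, lower))
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("'%s' must be >= %g", name, lower))
  }
  if (x > upper) stop(sprintf("'%s' must be <= %g", name, upper))
  invisible(x)
}

assertCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != round(x)) {
    stop(sprintf("'%s' must be a single non-negative integer", name))
  }
  invisible(as.integer(x))
}

## chromophore labels used throughout
CHROMOPHORES <- c("OHb", "DHb", "THb")
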