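# internal helpers: argument checks and counter-based seeding

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort(sprintf("`%s` must be supplied", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %g", name, lower))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%g, %g]", name, lower, upper))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single whole number", name))
  }
  if (x < lower) abort(sprintf("`%s` must be >= %d", name, lower))
  invisible(as.integer(x))
}

#' Derive a child seed from a master seed and a draw index
#'
#' Counter-based seed derivation: each ensemble draw gets a seed that is a
#' deterministic function of `(master_seed, index)`, so ensembles are
#' reproducible without any shared global random state. Values stay below
#' 2^31 - 1.
#'
#' @param master_seed Integer master seed.
#' @param index Integer draw index (vectorised).
#' @return Integer vector of seeds, one per index.
#' @export
#' @examples
#' child_seed(42, 1:3)
child_seed <- function(master_seed, index) {
  m <- as.double(master_seed) %% 2147483647
  s <- (m * 48271 + as.double(index) * 110351524 + 12345) %% 2147483647
  as.integer(ifelse(s == 0, 1, s))
}

# run code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
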