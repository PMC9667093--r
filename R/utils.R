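#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's
#' `.Random.seed` afterwards, so seeded helpers never perturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  force(code)
}

# derive a child seed < 2^31 from a master seed and stream offsets
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (k in seq_along(offs)) {
    s <- (s * 69069 + 104729 * as.double(offs[k]) + 7919) %% 2147483629
  }
  as.integer(s) + 1L
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)
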