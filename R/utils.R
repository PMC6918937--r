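#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
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
  expr
}

#' Derive a per-cell child seed from a master seed
#'
#' Deterministic counter scheme: each (subject, time point, condition) cell of
#' the experiment gets its own reproducible seed, independent of generation
#' order. The linear combination keeps distinct cells on distinct seeds for
#' any design of realistic size, and the modulus keeps the result a valid
#' 32-bit R seed.
#'
#' @param master master integer seed.
#' @param subject subject index (1-based).
#' @param time_index time-point index (1-based).
#' @param condition_index condition index (1-based).
#' @return An integer seed.
#' @export
child_seed <- function(master, subject, time_index, condition_index) {
  s <- (as.double(master) * 100003 +
          as.double(subject) * 1009 +
          as.double(time_index) * 101 +
          as.double(condition_index) * 13) %% 2147483629
  as.integer(s)
}

# stop() unless all conditions named in ... are TRUE; names are the messages
check_that <- function(...) {
  conds <- list(...)
  for (nm in names(conds)) {
    if (!isTRUE(conds[[nm]])) stop(nm, call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
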