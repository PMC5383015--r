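#' Run code with a temporary RNG seed
#'
#' Evaluates an expression under `set.seed(seed)` and restores the caller's
#' RNG state afterwards, so seeded helpers are side-effect-free with respect
#' to the global random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Encode a sign pattern as a character key
#'
#' Patterns of +1/-1 traits are keyed as strings of `+` and `-` characters,
#' e.g. `"+-++"`. Keys index the count tables of
#' [estimate_distribution()] output.
#'
#' @param s integer or numeric vector with entries in `{-1, +1}`.
#' @return a single character string.
#' @seealso [key_to_pattern()]
#' @export
#' @examples
#' pattern_key(c(1, -1, 1))
pattern_key <- function(s) {
  stopifnot(all(s %in% c(-1L, 1L)))
  paste(ifelse(s > 0, "+", "-"), collapse = "")
}

#' Decode a pattern key back to a sign vector
#'
#' @param key a string of `+`/`-` characters as produced by [pattern_key()].
#' @return integer vector of `-1`/`+1`.
#' @export
key_to_pattern <- function(key) {
  ch <- strsplit(key, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("+", "-"))) stop("key must contain only '+' and '-'")
  ifelse(ch == "+", 1L, -1L)
}

# integer code (bit i set iff trait i == +1) <-> key helpers used when
# tabulating C++ sign codes
code_to_key <- function(code, N) {
  vapply(seq_along(code), function(k) {
    paste(ifelse(bitwAnd(bitwShiftR(code[k], 0:(N - 1)), 1L) == 1L, "+", "-"),
          collapse = "")
  }, character(1))
}

stop_dim <- function(...) stop(sprintf(...), call. = FALSE)

assert_sign_vector <- function(x, what = "pattern") {
  if (!all(x %in% c(-1, 1))) {
    stop(sprintf("%s must contain only -1 and +1", what), call. = FALSE)
  }
  invisible(TRUE)
}
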