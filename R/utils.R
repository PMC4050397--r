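# internal helpers shared across the package

#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 2) {
  # base round() is round-half-even; printed percentages use half-up
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# run expr with a locally-seeded RNG, restoring the caller's RNG state
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# split "a;b;c" cells into a list of character vectors (empty cell -> character(0))
#' @keywords internal
#' @noRd
split_codes <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    out <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    out[nzchar(out)]
  })
}

#' @keywords internal
#' @noRd
join_codes <- function(x) {
  vapply(x, function(s) paste(s, collapse = ";"), character(1))
}
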