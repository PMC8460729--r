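# small internal helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded simulator calls do
#' not perturb user code. A `NULL`/`NA` seed evaluates the expression with
#' the current RNG stream.
#' @param seed integer seed or `NULL`
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# flags are stored as a comma-joined string in one column
has_flag <- function(flags, flag) {
  if (!length(flags)) return(logical(0))
  vapply(strsplit(ifelse(is.na(flags), "", flags), ",", fixed = TRUE),
         function(x) flag %in% x, logical(1))
}

add_flag <- function(flags, flag) {
  if (!length(flags)) return(character(0))
  flags <- ifelse(is.na(flags), "", flags)
  want <- !has_flag(flags, flag)
  flags[want] <- ifelse(nzchar(flags[want]), paste0(flags[want], ",", flag), flag)
  flags
}

# display convention for duplication rates and summary percentages
format_rate1 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
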