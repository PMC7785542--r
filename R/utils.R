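# internal helpers shared across modules

#' @noRd
round_half_up <- function(x, digits = 0) {
  # base round() is banker's rounding; report columns need half-up
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar NA of matching type for optional fields; keeps JSON round-trips exact
#' @noRd
na_chr <- NA_character_

#' @noRd
stop_brscore <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "brscore_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @noRd
is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' @noRd
is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

#' @noRd
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

# run code with a locally seeded RNG, restoring global state afterwards
#' @noRd
with_seed <- function(seed, code) {
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
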