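#' Round half away from zero
#'
#' Decimal rounding that resolves ties upward (5 always rounds away from
#' zero), the convention used when reporting percentages and physical
#' descriptors in annotation tables. Base R's \code{round()} rounds to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)        # 1
#' round_half_up(81.0126, 1) # 81.0
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # epsilon guards against representation error just below a .5 boundary
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so generators are deterministic without clobbering the
#' session stream.
#'
#' @param seed integer seed or NULL (no seeding).
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# stop() with a condition class so callers can distinguish error families
pk_stop <- function(class, msg, call. = FALSE) {
  cond <- structure(
    class = c(class, "phagekit_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}
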