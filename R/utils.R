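#' @importFrom data.table data.table setDT setorder := .N .SD fwrite fread
#' @importFrom stats rbeta rbinom runif median sd quantile setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a locally seeded RNG stream
#'
#' Saves and restores `.Random.seed` so that package functions that need
#' reproducible draws do not perturb the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# fixed-format numeric rendering for deterministic text output
fmt_num <- function(x, digits = 4L) {
  formatC(x, format = "f", digits = digits, drop0trailing = FALSE)
}

stop2 <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop2(...)
  invisible(TRUE)
}
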