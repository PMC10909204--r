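#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package internals never disturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) {
  stop(structure(class = c("proj2proj_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_config <- function(...) {
  stop(structure(class = c("proj2proj_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_finite_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_invalid(what, " must be a numeric matrix")
  if (!all(is.finite(x)))
    stop_invalid(what, " contains non-finite values")
  invisible(x)
}

# derive a reproducible child seed (kept well below 2^31)
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(k) %% 1009L
}
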