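#' @keywords internal
ft_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "fundtess_error", "error", "condition")))
}

ft_assert <- function(ok, class, msg) {
  if (!isTRUE(ok)) ft_stop(class, msg)
  invisible(TRUE)
}

# run expr with a private RNG stream, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
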