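# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Integer apportionment by the largest-remainder method: returns integer counts
# summing to `total`, proportional to `weights`.
largest_remainder <- function(weights, total) {
  stopifnot(total >= 0, all(weights >= 0))
  if (sum(weights) == 0) return(rep(0L, length(weights)))
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  short <- total - sum(base)
  if (short > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

assert_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(sprintf("`%s` must be finite and non-negative", name), call. = FALSE)
  invisible(x)
}
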