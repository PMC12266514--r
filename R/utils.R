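# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`,
#' and restores the previous state so generators behave as pure
#' functions of their seed argument.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
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

# dense descending rank: largest value gets rank 1, ties share a rank
dense_rank_desc <- function(x) {
  match(x, sort(unique(x), decreasing = TRUE))
}

# derive a deterministic stream of sub-seeds below 2^31
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if_not <- function(cond, ...) {
  if (!cond) stop(..., call. = FALSE)
}

# canonical unordered edge key "a|b" with a < b lexicographically
edge_key <- function(a, b) {
  swap <- a > b
  ifelse(swap, paste(b, a, sep = "|"), paste(a, b, sep = "|"))
}
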