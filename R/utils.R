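# Internal helpers: argument checking and reproducible seeding.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_invalid("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) stop_invalid("`%s` must be a single number in %s%g, %g%s", name,
                        if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]")
  as.numeric(x)
}

#' Derive a reproducible integer seed from arbitrary components
#'
#' Folds its arguments (integers and strings) into a single seed in
#' `[1, 2^31 - 2]` with an FNV-style multiplicative hash.  Used to give every
#' scenario and every replicate its own substream so that any unit of the
#' study is reproducible in isolation and independent of execution order.
#'
#' @param ... integers and/or character strings identifying the stream.
#' @return A single integer suitable for [set.seed()].
#' @export
mix_seed <- function(...) {
  parts <- list(...)
  h <- 2166136261
  m <- 2147483647  # 2^31 - 1, prime; double arithmetic stays exact below 2^53
  for (p in parts) {
    bytes <- if (is.character(p)) as.integer(charToRaw(paste(p, collapse = "|")))
             else as.integer(p)
    for (b in bytes) {
      h <- (h * 16777619) %% m
      h <- (h + (b %% m) + m) %% m
    }
  }
  as.integer(h %% (m - 1L) + 1L)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
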