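## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG state
#'
#' Saves and restores `.Random.seed` so seeded package code never perturbs
#' the caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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

## Deterministic small-integer hash of a character key, used to derive
## per-variant sub-seeds so per-variant computations are order-independent.
key_seed <- function(seed, key) {
  bytes <- utf8ToInt(paste(key, collapse = "|"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1998244353
  as.integer((as.numeric(seed) + h) %% .Machine$integer.max)
}

## Variant identity key used throughout: chrom:pos:ref:alt
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

other_bases <- function(base) BASES[BASES != base]

stop_arg <- function(...) stop(..., call. = FALSE)

## simple per-stage counter log (records in/out/filtered with reasons)
new_log <- function() new.env(parent = emptyenv())

log_count <- function(log, what, n = 1L) {
  if (is.null(log)) return(invisible(NULL))
  cur <- get0(what, envir = log, ifnotfound = 0L)
  assign(what, cur + n, envir = log)
  invisible(NULL)
}

log_as_list <- function(log) {
  if (is.null(log)) return(list())
  as.list(log)
}
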