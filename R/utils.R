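`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under set.seed(seed) without disturbing the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
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

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-session child seeds
#' (a linear-congruential mix, kept below 2^31). Indexed children mean a
#' change in cohort size never reshuffles earlier sessions.
#'
#' @param master Master integer seed.
#' @param index Child index (1, 2, ...).
#' @return An integer seed.
#' @export
child_seed <- function(master, index) {
  m <- 2147483647  # 2^31 - 1
  as.integer((((as.numeric(master) %% m) * 48271) %% m + 7919 * index) %% m)
}

# Fold an unbounded coordinate into [0, L] by reflection (triangle wave).
reflect_into <- function(z, L) {
  z <- z %% (2 * L)
  ifelse(z > L, 2 * L - z, z)
}
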