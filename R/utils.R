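#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer `seed` is required", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# round half away from zero, used for whole-percent reporting
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
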