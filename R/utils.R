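#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded simulators do not perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Fan one master seed out to per-stage seeds
#'
#' Fixed offsets keep a single user-facing seed reproducing every stage
#' while decorrelating their streams. Results stay below 2^31 - 1.
#'
#' @keywords internal
#' @noRd
fan_seed <- function(seed, stage) {
  offsets <- c(
    genome = 11L, library = 23L, selection = 37L, reads = 51L,
    dose = 67L, combination = 83L
  )
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single probability in [0, 1]")
  }
  invisible(x)
}
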