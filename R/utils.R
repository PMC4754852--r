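#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random stream set from `seed`, then restores
#' the previous stream so library calls never perturb a caller's RNG state.
#' All stochastic functions in the package route their randomness through
#' this helper, which is what makes identical seeds give byte-identical
#' outputs.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a stage seed from a master seed
#'
#' Deterministic per-stage seeds: hashing the stage name into the offset
#' means adding a stage to the pipeline never shifts another stage's random
#' stream. Result stays inside the 32-bit integer range R requires.
#'
#' @param master_seed single integer.
#' @param stage character scalar naming the stage.
#' @return a single integer seed.
#' @keywords internal
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) %% 1e6) * 2039 + h) %% 2147483587L + 1L
}

# format a numeric for delimited output at 6 significant digits
fmt_num <- function(x, na = "NA") {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- na
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
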