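# Internal helpers: seeded evaluation and argument checking.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded package functions do
#' not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage RNG substream from a master seed
#'
#' Hashes the (seed, stage-name) pair so that adding a stage never perturbs
#' the streams of earlier stages. The result stays below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return integer substream seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

# Stop with a consistent error class so callers can distinguish argument
# errors from computation failures.
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("mycogrowth_invalid", "error")))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_invalid(...)
}

# Deterministic split of n items into count ~ frac * n using floor, with the
# remainder never allocated (floor rule); items are taken lowest-index first.
floor_count <- function(frac, n) {
  as.integer(floor(frac * n + 1e-9))
}
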