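#' @importFrom stats median pt phyper p.adjust rnorm runif density var lm coef setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators do not
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # initialize so we have a state to restore
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive an independent child seed for a named generator stage
#'
#' One user-facing seed drives the whole pipeline; each stage draws from its
#' own derived stream so that adding or removing a stage does not shift the
#' random numbers of the others. The derivation is a small multiplicative
#' hash of the stage name, kept below 2^31 - 1.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) * 7919 + h * 131 + 17) %% 2147483647)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
}
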