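#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

## Classed errors so callers can distinguish contract violations.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "litcohesion_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the previous global RNG
#' state so library calls never disturb a caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' Every randomized stage of the workflow draws from its own deterministic
#' sub-seed so that stages are reproducible independently of evaluation
#' order. Result is always in `[1, 2^31 - 2]`.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483629) + 1L
}

round_half_up <- function(x) floor(x + 0.5)

## Minimal structured logger: stage-tagged lines on stderr via message().
log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}
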