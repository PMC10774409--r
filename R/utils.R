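#' @keywords internal
"_PACKAGE"

# Classed condition helpers so callers/tests can distinguish validation
# failures from configuration errors without string-matching messages.

ws_stop <- function(msg, class = "warmsoil_validation_error") {
  stop(errorCondition(msg, class = c(class, "warmsoil_error")))
}

ws_config_stop <- function(msg) ws_stop(msg, class = "warmsoil_config_error")

ws_io_stop <- function(msg) ws_stop(msg, class = "warmsoil_io_error")

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded helpers do not perturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Derive a distinct child seed from a base seed and a label, staying well
# below .Machine$integer.max. Deterministic and platform-independent.
child_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label))) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x)
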