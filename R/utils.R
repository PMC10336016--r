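#' @keywords internal
"_PACKAGE"

# Numerically stable row-wise softmax.
softmax_rows <- function(x) {
  x <- as.matrix(x)
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# SELU with the standard published constants.
SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu <- function(x) {
  SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
}

selu_grad <- function(x) {
  SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# One seed governs every stochastic stage of a run.  Sub-streams are derived
# deterministically from the run seed and a stage name so that, e.g., fold
# assignment does not perturb the dropout stream.  Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# Evaluate an expression under a local RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}
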