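# internal helpers shared across modules

#' @importFrom rlang abort warn hash .data
#' @importFrom stats rnorm runif rlnorm sd median setNames approx lm coef cor
#'   pt qt complete.cases
#' @importFrom utils head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never disturbs the
# user's RNG stream.
with_seed_ <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministically derive sub-seeds from a master seed, kept within the
# 32-bit signed integer range R requires of set.seed().
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L)
  as.integer((as.double(master) * 48271 + stream * 1009) %% 2147483647)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "biohackr_error")
}
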