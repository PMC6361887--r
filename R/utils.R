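#' @keywords internal
"_PACKAGE"

# Run `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL means "use the current global stream" (and advance it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Derive a named child seed from a master seed
#'
#' Deterministically maps a master seed and a stage name to a child seed so
#' that each pipeline stage draws from its own stream: adding a stage never
#' perturbs the randomness of existing stages. The map is a Lehmer step of
#' the master combined with an FNV-1a hash of the stream name, reduced
#' modulo 2^31 - 1.
#'
#' @param master integer master seed.
#' @param name character stream name, e.g. `"cohort"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @examples
#' seed_stream(1, "cohort")
#' seed_stream(1, "staircase")
#' @export
seed_stream <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.character(name), length(name) == 1L, nzchar(name))
  m <- 2147483647 # 2^31 - 1
  h <- 2166136261
  for (code in utf8ToInt(name)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% m
  }
  s <- ((abs(master) %% m) * 48271 + h) %% m
  as.integer(if (s == 0) 1 else s)
}

# FNV-1a hash of a character string, as 8 hex digits (config fingerprints).
# h is carried as a double < 2^32; the xor only ever touches the low byte.
fnv1a_hex <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (code in utf8ToInt(x)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(code %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Half-up rounding (R's round() is banker's); spec'd for signal-dot counts.
round_half_up <- function(x) floor(x + 0.5)

stop_domain <- function(...) stop(..., call. = FALSE)
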