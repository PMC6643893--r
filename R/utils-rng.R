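#' Derive a reproducible child seed from a root seed
#'
#' Breeding campaigns draw random numbers in many places (founder subsampling,
#' meiosis per cross, Monte-Carlo look-ahead evaluation). To keep results
#' invariant to the order and number of draws elsewhere, each stochastic unit
#' gets its own stream, seeded deterministically from a root seed and a set of
#' integer indices (e.g. generation and cross number). Uses a Lehmer-style
#' multiplicative hash modulo 2^31 - 1.
#'
#' @param seed Integer root seed (or `NULL`, returning `NULL`).
#' @param ... Integer indices identifying the stream.
#' @return An integer seed in `[1, 2^31 - 2]`, or `NULL` if `seed` is `NULL`.
#' @export
#' @examples
#' child_seed(42, 1, 3)
child_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  h <- as.double(seed) %% 2147483647
  for (k in as.double(c(...))) {
    h <- (h * 48271 + k + 1) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is untouched. seed = NULL evaluates with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
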