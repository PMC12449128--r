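# Shared internal helpers: seeding, rank transforms, input checks.

#' Derive a reproducible child seed from a master seed
#'
#' Named sub-streams ("task", "agents", "bold", "perm", "boot", ...) are
#' derived deterministically from one master seed so that every random stage
#' of the pipeline is replayable in isolation. The result always stays below
#' 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stream Character stream label.
#' @param index Optional integer offset within a stream (e.g. subject number).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # small string hash (djb2), folded into [0, 2^31 - 2]
  h <- 5381
  for (ch in utf8ToInt(stream)) h <- (h * 33 + ch) %% 2147483647
  as.integer((seed + h + 97561 * index) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; if `seed`
# is NULL the current RNG is used and advanced (standard R behaviour).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Column-wise rank transform (average ranks for ties). Used before the
# rank-based PLS and regression analyses so relationships are interpreted as
# monotone rather than strictly linear.
rank_columns <- function(x) {
  if (is.null(dim(x))) return(rank(x, ties.method = "average"))
  apply(x, 2L, rank, ties.method = "average")
}

check_proportion <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
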