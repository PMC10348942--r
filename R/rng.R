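#' Derive a stable per-trace seed
#'
#' Per-trace seeds are derived from the root seed by hashing the
#' (participant, condition, trial) coordinates with a Fowler-Noll-Vo style
#' mix, so generation is independent of the order in which traces are
#' requested and two traces of one study never share a stream.
#'
#' @param root integer root seed.
#' @param ... integers or strings identifying the stream (participant id,
#'   condition label, trial index, channel tag, ...).
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(root, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(p) else as.integer(p)
  }))
  h <- (as.double(root) %% 2147483647) + 1
  for (p in c(parts, 101L)) {
    h <- (h * 16807 + as.double(p) + 1) %% 2147483647
    h <- (h * 48271 + 11) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
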