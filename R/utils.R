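# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. Seeds must stay below 2^31 (R integers are 32-bit).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a stream of per-run seeds from a master seed via a splittable
# counter; all results stay within 32-bit integer range.
derive_seeds <- function(master_seed, n, stream = 0L) {
  base <- (as.numeric(master_seed) * 7919 + as.numeric(stream) * 104729) %%
    2147483647
  as.integer((base + seq_len(n) * 611953) %% 2147483647)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
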