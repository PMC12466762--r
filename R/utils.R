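# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never disturb
# user-level random streams.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Shift a matrix by (dr, dc) with zero padding; entry [i, j] of the result
# is m[i - dr, j - dc] where that index exists, else 0.
shift_matrix <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ri <- max(1, 1 + dr):min(h, h + dr)
  ci <- max(1, 1 + dc):min(w, w + dc)
  if (length(ri) && length(ci)) out[ri, ci] <- m[ri - dr, ci - dc, drop = FALSE]
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bovi <- function(..., class) {
  stop(structure(class = c(class, "bovimetry_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
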