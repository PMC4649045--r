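# Internal helpers: validation, seeded sub-streams, RNG hygiene.

abort_field <- function(field, msg) {
  rlang::abort(sprintf("invalid `%s`: %s", field, msg), class = "raypar_validation_error")
}

check_number <- function(x, field, min = -Inf, max = Inf, strict_min = FALSE,
                         strict_max = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    abort_field(field, sprintf(
      "must lie in %s%s, %s%s but is %g",
      if (strict_min) "(" else "[", format(min),
      format(max), if (strict_max) ")" else "]", x
    ))
  }
  if (integer && x != round(x)) abort_field(field, "must be a whole number")
  invisible(x)
}

#' Derive a named random sub-stream seed
#'
#' All randomness in a pipeline run flows from one global seed; each stage
#' draws from its own sub-stream so that stages can be re-run independently
#' and in any order without perturbing each other.
#'
#' @param seed Integer global seed.
#' @param name Character stream name (e.g. `"generate"`, `"windows"`).
#' @param index Optional integer for families of streams (e.g. one per core).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, name, index = 0L) {
  check_number(seed, "seed", integer = TRUE)
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% m
  s <- (abs(seed) %% m) * 48271 %% m
  s <- (s + h * 69621 + (index %% m) * 16807) %% m
  as.integer(s %% (m - 1) + 1)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
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
  force(expr)
}

um_to_mm <- function(x) x / 1000

# findInterval-based ring lookup: radial position (mm) -> ring index 1..K.
ring_of <- function(r, borders) {
  k <- findInterval(r, borders, rightmost.closed = TRUE)
  pmin(pmax(k, 1L), length(borders) - 1L)
}

# TRUE when a radial position falls in the latewood zone of its ring.
in_latewood <- function(r, borders, onsets) {
  r >= onsets[ring_of(r, borders)]
}

# Chunked scans over large integer matrices: avoid materializing a
# full-size logical temporary (label maps run to tens of megapixels).
CHUNK_COLS <- 256L

count_nonzero <- function(m) {
  nx <- ncol(m)
  total <- 0L
  j <- 1L
  while (j <= nx) {
    jh <- min(j + CHUNK_COLS - 1L, nx)
    total <- total + sum(m[, j:jh] != 0L)
    j <- jh + 1L
  }
  total
}

nonzero_indices <- function(m) {
  ny <- nrow(m)
  nx <- ncol(m)
  parts <- list()
  j <- 1L
  while (j <= nx) {
    jh <- min(j + CHUNK_COLS - 1L, nx)
    w <- which(m[, j:jh, drop = FALSE] != 0L)
    if (length(w)) parts[[length(parts) + 1L]] <- w + (j - 1L) * ny
    j <- jh + 1L
  }
  if (!length(parts)) integer(0) else unlist(parts, use.names = FALSE)
}
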