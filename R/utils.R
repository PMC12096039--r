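#' @keywords internal
"_PACKAGE"

# argument checks ------------------------------------------------------------

stop_invalid <- function(...) {
  stop(structure(
    class = c("dyadtrf_invalid_argument", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_invalid("`", name, "` must be a single positive number")
  invisible(x)
}

check_fraction <- function(x, name, upper_open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
    (if (upper_open) x < 1 else x <= 1)
  if (!ok)
    stop_invalid("`", name, "` must be in [0, 1", if (upper_open) ")" else "]")
  invisible(x)
}

#' Derive reproducible child seeds from a parent seed
#'
#' Children are drawn with R's RNG seeded at `seed`, so any number of
#' sub-streams (trials, participants, permutations) are reproducible from a
#' single session seed and stay within the 32-bit integer range.
#'
#' @param seed integer parent seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

# Save/restore .Random.seed so package internals do not perturb the caller's
# RNG stream more than documented.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Pearson correlation that tolerates zero-variance inputs (returns 0).
safe_cor <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}

# columnwise Pearson r between two matrices (time x channel)
colwise_cor <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  vapply(seq_len(ncol(a)), function(j) safe_cor(a[, j], b[, j]), numeric(1))
}
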