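# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive an independent seed for a named random stream
#'
#' A single user-facing seed fans out to one derived seed per generator, so
#' that adding or re-running one generator never perturbs the random stream
#' of another. The derived seed is kept below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param label Character stream label (e.g. "methylome").
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(label)
  h <- as.double(seed %% 2147483647)
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer(h %% 2147483646) + 1L
}

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

# Stable quantile convention used across the package: linear interpolation
# between order statistics (type 7).
quantile7 <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

five_number <- function(x) {
  q <- quantile7(x, c(0, 0.25, 0.5, 0.75, 1))
  stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}
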