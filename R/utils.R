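# Shared small helpers: dB aggregation, quantile conventions, seeding.

#' Equivalent continuous level (Leq) of a set of dB values
#'
#' Energy average of sound levels: `10 * log10(mean(10^(L/10)))`. By Jensen's
#' inequality the Leq of a set of dB values is always greater than or equal to
#' their arithmetic mean.
#'
#' @param level_db Numeric vector of levels in dB.
#' @param na.rm Drop missing values before averaging.
#' @return Scalar Leq in dB.
#' @export
#' @examples
#' leq(c(50, 60, 70))
#' mean(c(50, 60, 70)) # always <= leq of the same values
leq <- function(level_db, na.rm = FALSE) {
  if (na.rm) level_db <- level_db[!is.na(level_db)]
  if (!length(level_db)) return(NA_real_)
  10 * log10(mean(10^(level_db / 10)))
}

# Quantiles are always the linear-interpolation definition (type 7), stated
# once here so every module shares the convention.
quantile_li <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

# Decile bin label (1..10) for each value, edges from pooled linear-
# interpolation quantiles; values tied with an internal edge fall in the
# lower bin.
decile_bin <- function(x, edges = NULL) {
  if (is.null(edges)) edges <- quantile_li(x, probs = seq(0, 1, by = 0.1))
  edges[1] <- -Inf
  edges[length(edges)] <- Inf
  # right-closed intervals => ties with an edge go to the lower bin
  findInterval(x, edges, left.open = TRUE, rightmost.closed = TRUE)
}

#' Deterministic substream seed from a parent seed and a string key
#'
#' Stable 31-bit hash of `(key, seed)`, used to split one master seed into
#' independent, order-insensitive streams (per participant, per stage).
#'
#' @param seed Integer parent seed.
#' @param key Character key naming the stream.
#' @return A single integer below 2^31.
#' @export
substream_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(paste0(key, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483647L
  }
  as.integer(h)
}

# Soundscape classes in increasing "complexity" order; used for factor
# levels and for modal tie-breaking (ties resolve to the more complex class).
SOUNDSCAPES <- c("Quiet", "Speech", "SpeechInNoise", "Noise")

soundscape_factor <- function(x) {
  factor(as.character(x), levels = SOUNDSCAPES)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}
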