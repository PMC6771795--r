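# Reproducibility machinery: every simulated column is drawn under its own
# derived seed so that growing n_persons leaves the draws for existing
# persons untouched (draws are consumed in person-major order within each
# substream).

# Deterministic integer seed < 2^31 derived from a master seed and a key.
substream_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0L
  for (ch in utf8ToInt(key)) h <- (h * 31L + ch) %% 100003L
  (abs(as.integer(seed)) %% 20000L) * 100003L + h
}

with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, key))
  expr
}
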