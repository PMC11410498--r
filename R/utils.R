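series_bin_minutes <- function(series) {
  d <- diff(as.numeric(series$timestamp[seq_len(min(100, nrow(series)))]))
  d <- d[d > 0]
  if (!length(d)) return(1)
  round(min(d) / 60)
}

# Lengths of runs where x == 0, as a data frame of start/end indices.
zero_runs <- function(x) {
  r <- rle(x == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

# Stable 31-bit hash of a string; used to derive per-cow RNG streams so that
# adding a cow to a scenario never changes the draws of the others.
stable_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

cow_seed <- function(root_seed, cow_id) {
  as.integer((as.numeric(root_seed) + stable_hash(cow_id)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
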