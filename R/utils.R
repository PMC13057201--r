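# Internal helpers shared across modules.

# Derive a child seed from a master seed and a stream index; kept below 2^31
# so it is always a valid R integer.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647L)
}

# Evaluate `code` under `set.seed(seed)` and restore the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  if (integer && x != as.integer(x)) {
    abort(sprintf("`%s` must be a whole number, got %s.", name, x))
  }
  invisible(x)
}

check_probability <- function(x, name) check_number(x, name, lower = 0, upper = 1)

# Row-wise centered moving average of a matrix with reflect padding
# (edge value not duplicated), used to vectorise boxcar smoothing over
# many aligned trial windows at once.
rowwise_boxcar <- function(m, width) {
  if (width == 1L) return(m)
  h <- (width - 1L) %/% 2L
  l <- ncol(m)
  if (l <= h + 1L) abort("window too short for boxcar width")
  mp <- cbind(m[, (h + 1L):2L, drop = FALSE], m, m[, (l - 1L):(l - h), drop = FALSE])
  cs <- mp
  for (j in seq_len(ncol(mp))[-1L]) cs[, j] <- cs[, j - 1L] + mp[, j]
  out <- m
  for (j in seq_len(l)) {
    lo <- j           # column j in m is column j + h in mp; window j .. j + width - 1
    hi <- j + width - 1L
    out[, j] <- (cs[, hi] - (if (lo > 1L) cs[, lo - 1L] else 0)) / width
  }
  out
}

# Cut aligned windows from a vector trace. `onsets` are 0-based frame indices
# of stimulation onset; the window spans `-baseline .. stim + response - 1`
# frames relative to onset. Returns a matrix with one row per onset.
cut_windows <- function(trace, onsets, window) {
  rel <- seq.int(-window$baseline_frames, window$stim_frames + window$response_frames - 1L)
  idx <- outer(as.integer(onsets), rel, "+") + 1L
  if (any(idx < 1L) || any(idx > length(trace))) {
    abort("trial window falls outside the trace")
  }
  matrix(trace[idx], nrow = length(onsets))
}

# Subtract each row's own baseline mean (frames before onset).
rebaseline_rows <- function(w, window) {
  f0 <- rowMeans(w[, seq_len(window$baseline_frames), drop = FALSE])
  w - f0
}
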