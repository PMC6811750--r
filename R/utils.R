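# Internal numerical helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Analytic signal via the frequency-domain construction (one-sided spectrum).
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Centered moving average with edge replication so output length equals
# input; cumulative-sum implementation, O(n) in the window width.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  half <- width %/% 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], width - half - 1L))
  cs <- c(0, cumsum(xp))
  (cs[(width + 1):(length(xp) + 1)] - cs[1:(length(xp) - width + 1)]) / width
}

# Indices of strict local maxima (greater than both neighbours).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}

# Normalized autocorrelation r(0..max_lag) via FFT, demeaned, r[1] == 1.
norm_autocorr <- function(x, max_lag) {
  n <- length(x)
  x <- x - mean(x)
  m <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(x, rep(0, m - n)))
  r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[seq_len(max_lag + 1L)] / m
  if (r[1] <= 0) return(rep(0, max_lag + 1L))
  r / r[1]
}

# Parabolic vertex interpolation around sample index i (sub-sample offset in
# [-0.5, 0.5]); returns fractional index.
parabolic_vertex <- function(x, i) {
  n <- length(x)
  if (i <= 1 || i >= n) return(as.numeric(i))
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (denom == 0) return(as.numeric(i))
  delta <- 0.5 * (x[i - 1] - x[i + 1]) / denom
  i + max(-0.5, min(0.5, delta))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
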