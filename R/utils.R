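# Internal numerical helpers.

# Hann window (periodic form, as used for averaged periodograms).
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}

# Welch power spectral density estimate.
# x: evenly sampled signal; fs: sampling rate (Hz); nperseg: segment length
# in samples; overlap: fractional segment overlap. Returns one-sided PSD in
# units^2/Hz on frequencies 0..fs/2. Segments are mean-detrended and Hann
# windowed; the window power is compensated so that integrating the PSD
# recovers the signal variance (up to spectral leakage).
welch_psd <- function(x, fs, nperseg = 1024L, overlap = 0.5) {
  n <- length(x)
  nperseg <- as.integer(min(nperseg, n))
  step <- max(1L, as.integer(floor(nperseg * (1 - overlap))))
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  win <- hann_window(nperseg)
  u <- sum(win^2)                         # window power normalisation
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- seg - mean(seg)
    sp <- stats::fft(seg * win)
    p <- (Mod(sp[seq_len(nf)])^2) / (fs * u)
    # one-sided: double everything except DC (and Nyquist when nperseg even)
    dbl <- 2:(nf - (1 - nperseg %% 2L))
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = acc / length(starts))
}

# Linear detrend by least squares.
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2) return(x - mean(x))
  t <- seq_len(n)
  tc <- t - mean(t)
  b <- sum(tc * x) / sum(tc^2)
  x - mean(x) - b * tc
}

# Deterministic content hash of an R object (md5 of its serialisation).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

# Derive independent per-unit RNG seeds from a master seed. Keeping each
# participant on its own seed means regenerating one participant never
# perturbs another's stream.
derive_seeds <- function(master_seed, n) {
  force(master_seed)   # evaluate caller RNG draws before snapshotting state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Run expr under a private RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  force(seed)          # evaluate caller RNG draws before snapshotting state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
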