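# Multitaper spectral estimation internals.
#
# Discrete prolate spheroidal (Slepian) sequences are computed from the
# standard symmetric tridiagonal formulation: the DPSS of length N and
# time-bandwidth product NW are the leading eigenvectors of the matrix with
# diagonal ((N-1-2t)/2)^2 * cos(2*pi*W), t = 0..N-1, and off-diagonal
# t*(N-t)/2. Tapers are normalized to unit energy and oriented so their
# mean (odd orders: leading lobe) is positive.

.dpss_cache <- new.env(parent = emptyenv())

.dpss <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  t <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  diag_off <- (t * (n - t) / 2)[-1]
  m <- diag(diag_main)
  idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
  m[idx] <- diag_off
  m[idx[, 2:1]] <- diag_off
  ev <- eigen(m, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tapers[, j]
    v <- v / sqrt(sum(v^2))
    s <- if (j %% 2 == 1L) sum(v) else sum(v * t)  # even/odd sign convention
    if (s < 0) v <- -v
    tapers[, j] <- v
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

# Taper-averaged one-sided PSD of the columns of x (n_samples x n_series).
# Returns list(freqs, psd [n_freq x n_series]); units x^2/Hz. The DC bin is
# dropped (AC-coupled recordings make it meaningless).
.mtm_psd <- function(x, fs, halfBandwidth) {
  n <- nrow(x)
  tw <- max(1, halfBandwidth * n / fs)
  k <- max(1L, as.integer(floor(2 * tw - 1)))
  tapers <- .dpss(n, tw, k)
  x <- sweep(x, 2L, colMeans(x))            # demean per series
  acc <- 0
  for (j in seq_len(k)) {
    ft <- stats::mvfft(x * tapers[, j])
    acc <- acc + Mod(ft)^2
  }
  nf <- n %/% 2L
  freqs <- (seq_len(nf)) * fs / n           # positive frequencies, DC excluded
  psd <- 2 * acc[2:(nf + 1L), , drop = FALSE] / (k * fs)
  if (n %% 2L == 0L) psd[nf, ] <- psd[nf, ] / 2   # Nyquist bin is not doubled
  list(freqs = freqs, psd = psd)
}

# Average native-resolution PSD bins onto a regular grid of width `width` Hz
# with centres width, 2*width, ..., <= maxFreq.
.bin_freqs <- function(freqs, psd, width, maxFreq) {
  centre_idx <- as.integer(round(freqs / width))
  nbins <- as.integer(floor(maxFreq / width))
  keep <- centre_idx >= 1L & centre_idx <= nbins
  if (!any(keep)) stop("no native frequency bins fall below maxFreq")
  gi <- centre_idx[keep]
  sub <- psd[keep, , drop = FALSE]
  out <- rowsum(sub, gi) / as.vector(table(gi))
  present <- sort(unique(gi))
  list(freqs = present * width, psd = out)
}
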