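# Sharp-wave ripple detection from the multi-tetrode consensus ripple-band
# envelope, with a detection threshold estimated from the empirical noise
# distribution (mode-mirroring construction) rather than a fixed SD cutoff.

# Single-pass zero-phase FIR filtering. The filter is symmetric (linear
# phase), so applying it once and removing the (m-1)/2-sample group delay
# is exactly zero-phase.
firFilterZeroPhase <- function(x, b) {
  n <- length(x); m <- length(b)
  L <- stats::nextn(n + m - 1L)
  y <- Re(fft(fft(c(x, numeric(L - n))) * fft(c(b, numeric(L - m))),
              inverse = TRUE)) / L
  d <- (m - 1L) %/% 2L
  y[(d + 1L):(d + n)]
}

rippleFir <- function(sampleRateHz, band) {
  nyq <- sampleRateHz / 2
  if (nyq <= band[2] * 1.05)
    stop(sprintf("sample rate %g Hz too low for a %g-%g Hz band",
                 sampleRateHz, band[1], band[2]))
  # Hamming-window FIR: ~53 dB stopband; order sized for a <= 25 Hz
  # transition band on either side of the passband.
  ord <- 2L * ceiling(3.3 * sampleRateHz / 25 / 2)
  as.numeric(signal::fir1(ord, band / nyq, type = "pass"))
}

#' Ripple-band filter the LFP
#'
#' Zero-phase band-pass (default 150-250 Hz) of every channel, using a
#' symmetric FIR filter (Hamming design, about 53 dB stopband, transition
#' bands within 25 Hz of the passband edges) applied with exact group-delay
#' compensation.
#'
#' @param lfp an \linkS4class{LfpBundle} (rate > 500 Hz).
#' @param band two-element numeric, passband in Hz.
#' @return Matrix of the same shape as the LFP samples.
#' @export
rippleBandpass <- function(lfp, band = c(150, 250)) {
  if (lfp@sampleRateHz <= 500) stop("sample rate too low for ripple band")
  b <- rippleFir(lfp@sampleRateHz, band)
  out <- lfp@samples
  for (j in seq_len(ncol(out)))
    out[, j] <- firFilterZeroPhase(lfp@samples[, j], b)
  out
}

# Row medians via an O(k^2) pmin/pmax sorting network over columns;
# vectorized over rows, fast for the small channel counts used here.
rowMediansFast <- function(m) {
  k <- ncol(m)
  if (k == 1L) return(m[, 1])
  cols <- lapply(seq_len(k), function(j) m[, j])
  for (i in seq_len(k - 1L)) for (j in seq_len(k - i)) {
    lo <- pmin(cols[[j]], cols[[j + 1L]])
    hi <- pmax(cols[[j]], cols[[j + 1L]])
    cols[[j]] <- lo; cols[[j + 1L]] <- hi
  }
  if (k %% 2L) cols[[(k + 1L) %/% 2L]]
  else (cols[[k %/% 2L]] + cols[[k %/% 2L + 1L]]) / 2
}

#' Consensus ripple-band envelope
#'
#' Per channel, the magnitude of the analytic signal of the ripple-band
#' LFP is smoothed with a Gaussian kernel (default sigma = 4 ms); the
#' consensus envelope is the pointwise median across channels (at least
#' three required), then normalized to immobility: the immobility-period
#' mean is subtracted and the immobility SD divides, so the normalized
#' envelope has mean 0 and SD 1 over immobility samples.
#'
#' @param filtered matrix from \code{\link{rippleBandpass}}.
#' @param sampleRateHz LFP sampling rate (Hz).
#' @param t0S time of the first sample (s).
#' @param immobilityIntervals two-column matrix of immobility intervals
#'   (from \code{\link{segmentMotion}}); \code{NULL} normalizes to the
#'   whole recording.
#' @param smoothingSigmaMs envelope smoothing sigma (ms).
#' @param usePower when \code{TRUE}, the squared smoothed envelope is used
#'   as "envelope power"; the default treats the smoothed magnitude as the
#'   power signal. The mode-mirroring threshold construction is monotone
#'   in scale, so the detected event sets are nearly identical either way.
#' @return List of class \code{ConsensusEnvelope}: \code{timeS},
#'   \code{value} (normalized), \code{normMean}, \code{normSd},
#'   \code{nChannels}, \code{sampleRateHz}, \code{immobilityMask}.
#' @export
consensusEnvelope <- function(filtered, sampleRateHz, t0S = 0,
                              immobilityIntervals = NULL,
                              smoothingSigmaMs = 4, usePower = FALSE) {
  filtered <- as.matrix(filtered)
  if (ncol(filtered) < 3L)
    stop("consensus envelope requires at least 3 channels")
  n <- nrow(filtered)
  sigmaSamples <- smoothingSigmaMs / 1000 * sampleRateHz
  env <- filtered
  for (j in seq_len(ncol(filtered)))
    env[, j] <- gaussianSmooth(Mod(analyticSignal(filtered[, j])), sigmaSamples)
  med <- rowMediansFast(env)
  if (usePower) med <- med^2
  timeS <- t0S + (seq_len(n) - 1L) / sampleRateHz
  mask <- if (is.null(immobilityIntervals)) rep(TRUE, n)
          else pointsInIntervals(timeS, immobilityIntervals)
  if (!any(mask)) stop("no immobility samples to normalize the envelope to")
  mu <- mean(med[mask]); sdv <- sd(med[mask])
  if (!is.finite(sdv) || sdv <= 0) stop("degenerate envelope: zero variance")
  structure(list(timeS = timeS, value = (med - mu) / sdv, normMean = mu,
                 normSd = sdv, nChannels = ncol(filtered),
                 sampleRateHz = sampleRateHz, immobilityMask = mask),
            class = "ConsensusEnvelope")
}

#' Empirical noise model and detection threshold for the envelope
#'
#' Histograms the immobility envelope values, locates the mode (center of
#' the tallest of 200 equal-width bins), mirrors the values below the mode
#' around it to form a symmetric noise distribution, and sets the detection
#' threshold at the 99.99th percentile of that distribution. The long
#' right tail contributed by genuine ripples lies above the mode and is
#' ignored by construction.
#'
#' @param envelope a \code{ConsensusEnvelope}, or a numeric vector of
#'   envelope values.
#' @param immobilityMask logical mask selecting noise-estimation samples
#'   (defaults to the envelope's own immobility mask).
#' @param percentile threshold percentile of the mirrored distribution.
#' @param nBins histogram bin count for mode location.
#' @return List of class \code{NoiseModel}: \code{modeValue},
#'   \code{threshold}, \code{mirroredQuantile} (function of p).
#' @export
estimateNoiseThreshold <- function(envelope, immobilityMask = NULL,
                                   percentile = 99.99, nBins = 200) {
  v <- if (inherits(envelope, "ConsensusEnvelope")) envelope$value else envelope
  if (is.null(immobilityMask) && inherits(envelope, "ConsensusEnvelope"))
    immobilityMask <- envelope$immobilityMask
  if (!is.null(immobilityMask)) v <- v[immobilityMask]
  if (length(v) < 1e4)
    stop("need at least 10^4 immobility samples to estimate the noise model")
  if (sd(v) <= .Machine$double.eps)
    stop("degenerate envelope distribution: zero variance")
  hi <- quantile(v, 0.999, names = FALSE)
  lo <- min(v)
  edges <- seq(lo, hi, length.out = nBins + 1L)
  counts <- tabulate(findInterval(v[v <= hi], edges, rightmost.closed = TRUE),
                     nbins = nBins)
  modeValue <- (edges[which.max(counts)] + edges[which.max(counts) + 1L]) / 2
  below <- v[v <= modeValue]
  mirrored <- c(below, 2 * modeValue - below)
  threshold <- quantile(mirrored, percentile / 100, names = FALSE)
  structure(list(modeValue = modeValue, threshold = threshold,
                 mirroredQuantile = function(p) quantile(mirrored, p, names = FALSE)),
            class = "NoiseModel")
}

#' Detect sharp-wave ripples
#'
#' Finds runs where the normalized consensus envelope exceeds the noise
#' threshold for at least \code{minEventS} (20 ms), extends each run
#' backward and forward to the nearest crossing of the immobility mean
#' (zero on the normalized scale), merges overlapping extended events,
#' discards events starting during movement, and truncates events that
#' extend across a movement boundary.
#'
#' @param envelope a \code{ConsensusEnvelope}.
#' @param noiseModel a \code{NoiseModel} from
#'   \code{\link{estimateNoiseThreshold}}.
#' @param segments motion segmentation (data.frame from
#'   \code{\link{segmentMotion}}); \code{NULL} skips the speed gate.
#' @param minEventS minimum supra-threshold duration (s).
#' @return data.frame of events: \code{event_id, start_s, end_s,
#'   duration_s, peak_env}, sorted and non-overlapping.
#' @export
detectSwrs <- function(envelope, noiseModel, segments = NULL,
                       minEventS = 0.020) {
  v <- envelope$value; t <- envelope$timeS
  n <- length(v)
  dt <- 1 / envelope$sampleRateHz
  above <- v > noiseModel$threshold
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * dt >= minEventS - 1e-9)
  runs <- cbind(starts[keep], ends[keep])
  if (!nrow(runs))
    return(data.frame(event_id = integer(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      peak_env = numeric(0)))
  idx <- seq_len(n)
  belowMean <- v <= 0
  lastBelow <- cummax(ifelse(belowMean, idx, 0L))            # <= i
  nextBelow <- rev(n + 1L - cummax(rev(ifelse(belowMean, n + 1L - idx, 0L))))
  s <- pmax(lastBelow[runs[, 1]], 1L)
  e <- pmin(nextBelow[runs[, 2]], n)
  iv <- normalizeIntervals(cbind(t[s], t[e]))
  if (!is.null(segments)) {
    immo <- normalizeIntervals(segmentsToIntervals(segments, "immobility"))
    out <- matrix(numeric(0), 0, 2)
    for (i in seq_len(nrow(iv))) {
      j <- which(immo[, 1] <= iv[i, 1] & immo[, 2] > iv[i, 1])
      if (!length(j)) next                       # starts during movement
      out <- rbind(out, c(iv[i, 1], min(iv[i, 2], immo[j[1], 2])))
    }
    iv <- out
  }
  if (nrow(iv)) iv <- iv[iv[, 2] - iv[, 1] >= minEventS - 1e-9, , drop = FALSE]
  if (!nrow(iv))
    return(data.frame(event_id = integer(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      peak_env = numeric(0)))
  peak <- vapply(seq_len(nrow(iv)), function(i) {
    a <- findInterval(iv[i, 1] - 1e-12, t) + 1L
    b <- findInterval(iv[i, 2] - 1e-12, t)
    max(v[a:b])
  }, numeric(1))
  data.frame(event_id = seq_len(nrow(iv)), start_s = iv[, 1], end_s = iv[, 2],
             duration_s = iv[, 2] - iv[, 1], peak_env = peak)
}

#' Event-aligned ripple-band spectral power
#'
#' Computes a sliding-window periodogram (default 100 ms windows, 10 ms
#' step) of the channel-averaged LFP, averages power across 150-250 Hz per
#' window, z-normalizes over all windows in the session, and reports per
#' event the z-scored band power of the first 100 ms after onset. Events
#' within one window of the end of the recording get \code{NA}.
#'
#' @param lfp an \linkS4class{LfpBundle}.
#' @param events event table from \code{\link{detectSwrs}} (or any
#'   data.frame with \code{start_s}).
#' @param band frequency band (Hz).
#' @param windowS,stepS spectrogram window and step (s).
#' @return List: \code{eventZ} (numeric per event), \code{windowStartS},
#'   \code{windowZ}.
#' @export
swrBandPower <- function(lfp, events, band = c(150, 250),
                         windowS = 0.1, stepS = 0.01) {
  fs <- lfp@sampleRateHz
  x <- if (ncol(lfp@samples) > 1L) rowMeans(lfp@samples) else lfp@samples[, 1]
  wlen <- round(windowS * fs); step <- round(stepS * fs)
  n <- length(x)
  nwin <- max(0L, (n - wlen) %/% step + 1L)
  if (nwin < 2L) stop("recording too short for the spectrogram window")
  startsIdx <- (seq_len(nwin) - 1L) * step + 1L
  W <- matrix(x[outer(seq_len(wlen) - 1L, startsIdx, "+")], nrow = wlen)
  W <- W - rep(colMeans(W), each = wlen)
  F <- stats::mvfft(W)
  freqs <- (seq_len(wlen) - 1L) / wlen * fs
  sel <- freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2
  power <- colMeans(Mod(F[sel, , drop = FALSE])^2)
  z <- (power - mean(power)) / sd(power)
  wstart <- lfp@t0S + (startsIdx - 1L) / fs
  eventZ <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(events))) {
    s <- events$start_s[i]
    if (s + windowS > lfp@t0S + n / fs) next    # flagged: power undefined
    j <- which.min(abs(wstart - s))
    eventZ[i] <- z[j]
  }
  list(eventZ = eventZ, windowStartS = wstart, windowZ = z)
}
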