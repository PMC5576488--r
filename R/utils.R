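# Internal numeric utilities shared across stages. All intervals are
# half-open [start, end) matrices with two columns.

# Sort and merge possibly overlapping intervals into disjoint sorted form.
normalizeIntervals <- function(iv) {
  iv <- as.matrix(iv)
  if (!nrow(iv)) return(matrix(numeric(0), 0, 2))
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  if (!nrow(iv)) return(matrix(numeric(0), 0, 2))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out <- matrix(NA_real_, nrow(iv), 2)
  k <- 1L; out[1, ] <- iv[1, ]
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= out[k, 2]) out[k, 2] <- max(out[k, 2], iv[i, 2])
    else { k <- k + 1L; out[k, ] <- iv[i, ] }
  }
  out[seq_len(k), , drop = FALSE]
}

# Intersection of two disjoint-sorted interval sets.
intersectIntervals <- function(a, b) {
  a <- normalizeIntervals(a); b <- normalizeIntervals(b)
  if (!nrow(a) || !nrow(b)) return(matrix(numeric(0), 0, 2))
  res <- matrix(NA_real_, nrow(a) + nrow(b), 2); k <- 0L
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) { k <- k + 1L; res[k, ] <- c(lo, hi) }
    if (a[i, 2] <= b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  res[seq_len(k), , drop = FALSE]
}

# Set difference a \ b for disjoint-sorted interval sets.
setdiffIntervals <- function(a, b) {
  a <- normalizeIntervals(a); b <- normalizeIntervals(b)
  if (!nrow(a) || !nrow(b)) return(a)
  out <- vector("list", nrow(a))
  for (i in seq_len(nrow(a))) {
    lo <- a[i, 1]; hi <- a[i, 2]
    cur <- lo; pieces <- NULL
    ov <- b[b[, 2] > lo & b[, 1] < hi, , drop = FALSE]
    if (nrow(ov)) for (j in seq_len(nrow(ov))) {
      if (ov[j, 1] > cur) pieces <- rbind(pieces, c(cur, ov[j, 1]))
      cur <- max(cur, ov[j, 2])
    }
    if (cur < hi) pieces <- rbind(pieces, c(cur, hi))
    out[[i]] <- pieces
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(numeric(0), 0, 2) else res
}

totalIntervalTime <- function(iv) {
  iv <- as.matrix(iv)
  if (!nrow(iv)) return(0)
  sum(iv[, 2] - iv[, 1])
}

# TRUE for points lying in any half-open interval (disjoint sorted set).
pointsInIntervals <- function(x, iv) {
  iv <- normalizeIntervals(iv)
  if (!nrow(iv)) return(rep(FALSE, length(x)))
  idx <- findInterval(x, as.vector(t(iv)), left.open = FALSE)
  idx %% 2L == 1L
}

# Count spikes per interval (half-open), intervals need not be disjoint.
countInIntervals <- function(spikes, iv) {
  iv <- as.matrix(iv)
  if (!nrow(iv)) return(integer(0))
  findInterval(iv[, 2], spikes, left.open = TRUE) -
    findInterval(iv[, 1], spikes, left.open = TRUE)
}

# Convert a logical mask over sample times to half-open intervals; the end
# of a run extends to the time of the next sample (or last time + dt).
maskToIntervals <- function(timeS, mask) {
  n <- length(timeS)
  if (!n || !any(mask)) return(matrix(numeric(0), 0, 2))
  dt <- if (n > 1L) median(diff(timeS)) else 1 / 30
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values
  s <- timeS[starts[keep]]
  e <- ifelse(ends[keep] < n, timeS[ends[keep] + 1L], timeS[n] + dt)
  cbind(s, e, deparse.level = 0)
}

# Linear convolution keeping the central (valid) part; direct C filtering
# for small kernels, padded FFT otherwise (unpadded FFT lengths can be
# near-prime and degrade badly).
convolveValid <- function(xPadded, k) {
  n <- length(xPadded); m <- length(k)
  if (m <= 512) {
    out <- stats::filter(xPadded, k, sides = 2)
    as.numeric(out[!is.na(out)])
  } else {
    L <- stats::nextn(n + m - 1L)
    y <- Re(fft(fft(c(xPadded, numeric(L - n))) * fft(c(k, numeric(L - m))),
                inverse = TRUE)) / L
    d <- (m - 1L) %/% 2L
    y[(d + 1L):(d + n)][(d + 1L):(n - d)]
  }
}

# Gaussian smoothing of a regularly sampled vector with edge renormalization.
gaussianSmooth <- function(x, sigmaSamples, extentSigmas = 4) {
  if (sigmaSamples <= 0) return(x)
  half <- max(1L, ceiling(sigmaSamples * extentSigmas))
  k <- exp(-0.5 * ((-half:half) / sigmaSamples)^2)
  k <- k / sum(k)
  n <- length(x)
  num <- convolveValid(c(rep(0, half), x, rep(0, half)), k)
  den <- convolveValid(c(rep(0, half), rep(1, n), rep(0, half)), k)
  num / den
}

# 2-D Gaussian smoothing of a matrix (separable kernel), NA-aware: NA cells
# contribute no mass and keep NA where the local weight is zero.
gaussianSmooth2d <- function(m, sigmaBins, extentBins) {
  half <- max(1L, floor(extentBins / 2))
  k <- exp(-0.5 * ((-half:half) / sigmaBins)^2)
  k <- k / sum(k)
  w <- !is.na(m)
  m0 <- m; m0[!w] <- 0
  smooth1 <- function(a) {
    t(apply(a, 1, function(r) convolve(c(rep(0, half), r, rep(0, half)), k,
                                       type = "filter")))
  }
  num <- smooth1(t(smooth1(m0)))
  den <- smooth1(t(smooth1(w * 1)))
  out <- t(num) / t(den)
  out[t(den) <= 0] <- NA_real_
  out
}

# Analytic signal via FFT (positive-frequency doubling).
analyticSignal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Pink (1/f amplitude) noise, unit standard deviation.
pinkNoise <- function(n) {
  nfft <- 2L * n
  f <- seq_len(nfft / 2)
  amp <- 1 / sqrt(f)
  ph <- runif(nfft / 2, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- c(0 + 0i, spec, Conj(rev(spec[-length(spec)])))
  x <- Re(fft(full, inverse = TRUE))[seq_len(n)]
  (x - mean(x)) / sd(x)
}

# Deterministic derived seed below 2^31 from a base seed and a stage tag.
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

# Deterministic CSV writer: numerics as %.17g (exact round trip), LF only.
writeCsv17 <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col)
    else as.character(col)
  })
  header <- paste(names(df), collapse = ",")
  if (nrow(df)) {
    body <- do.call(paste, c(cols, sep = ","))
    lines <- c(header, body)
  } else lines <- header
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(NULL)
}

# Linear interpolation wrapper that errors on extrapolation.
interpAt <- function(t, v, at, what = "value") {
  if (any(at < t[1] - 1e-9 | at > t[length(t)] + 1e-9))
    stop(sprintf("%s requested outside tracked time range", what))
  approx(t, v, xout = at, rule = 2)$y
}
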