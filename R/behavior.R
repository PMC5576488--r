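# Behavioral state: speed, movement/immobility segmentation, well occupancy
# and occupancy maps. Movement is speed > 4 cm/s; immobility is the
# complement. All intervals are half-open [start, end) in seconds.

#' Estimate running speed from a position trace
#'
#' Speed is computed as the central difference of position (one-sided at the
#' edges) followed by Gaussian temporal smoothing (default sigma = 0.25 s),
#' which suppresses frame-jitter flicker across the movement threshold.
#'
#' @param position a \linkS4class{PositionTrace} (>= 3 samples).
#' @param smoothingSigmaS temporal smoothing sigma in seconds.
#' @return The same \linkS4class{PositionTrace} with the speed slot filled.
#' @export
computeSpeed <- function(position, smoothingSigmaS = 0.25) {
  t <- position@timeS; x <- position@xCm; y <- position@yCm
  n <- length(t)
  if (n < 3L) stop("computeSpeed needs at least 3 position samples")
  if (any(diff(t) <= 0)) stop("position time stamps are not strictly increasing")
  vx <- numeric(n); vy <- numeric(n)
  idx <- 2:(n - 1)
  dt2 <- t[idx + 1L] - t[idx - 1L]
  vx[idx] <- (x[idx + 1L] - x[idx - 1L]) / dt2
  vy[idx] <- (y[idx + 1L] - y[idx - 1L]) / dt2
  vx[1] <- (x[2] - x[1]) / (t[2] - t[1]); vy[1] <- (y[2] - y[1]) / (t[2] - t[1])
  vx[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  vy[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  sp <- sqrt(vx^2 + vy^2)
  dt <- median(diff(t))
  if (smoothingSigmaS > 0) sp <- gaussianSmooth(sp, smoothingSigmaS / dt)
  sp[sp < 0] <- 0
  initialize(position, speedCmS = sp)
}

#' Segment a session into movement and immobility intervals
#'
#' Applies the single-threshold rule: a sample is in the movement state when
#' speed exceeds \code{thresholdCmS}, otherwise immobility. Runs of equal
#' state become half-open intervals that tile the tracked session without
#' overlap; no hysteresis or minimum duration is imposed.
#'
#' @param position a \linkS4class{PositionTrace} with speed computed.
#' @param thresholdCmS movement threshold (cm/s), default 4.
#' @return data.frame with columns \code{label} ("movement"/"immobility"),
#'   \code{start_s}, \code{end_s}, alternating states.
#' @export
segmentMotion <- function(position, thresholdCmS = 4) {
  t <- position@timeS
  sp <- position@speedCmS
  if (!length(sp)) stop("speed not computed; call computeSpeed() first")
  n <- length(t)
  dt <- if (n > 1L) median(diff(t)) else 1 / 30
  moving <- sp > thresholdCmS
  r <- rle(moving)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  start_s <- t[starts]
  end_s <- c(t[starts[-1]], t[n] + dt)
  data.frame(label = ifelse(r$values, "movement", "immobility"),
             start_s = start_s, end_s = end_s, stringsAsFactors = FALSE)
}

segmentsToIntervals <- function(segments, label) {
  sel <- segments$label == label
  cbind(segments$start_s[sel], segments$end_s[sel])
}

# Per-sample well occupancy: recorded entry/exit intervals take precedence
# over the radius rule.
wellAtSamples <- function(session) {
  p <- session@position
  wells <- session@wells
  at <- rep(NA_character_, length(p@timeS))
  dist2 <- matrix(Inf, length(p@timeS), nrow(wells))
  for (i in seq_len(nrow(wells)))
    dist2[, i] <- (p@xCm - wells$x_cm[i])^2 + (p@yCm - wells$y_cm[i])^2
  nearest <- max.col(-dist2)
  inRadius <- dist2[cbind(seq_along(nearest), nearest)] <=
    wells$radius_cm[nearest]^2
  at[inRadius] <- wells$well_id[nearest[inRadius]]
  ev <- session@wellEvents
  if (nrow(ev)) for (wid in unique(ev$well_id)) {
    e <- ev[ev$well_id == wid, ]
    e <- e[order(e$time_s), ]
    ent <- e$time_s[e$kind == "entry"]
    ext <- e$time_s[e$kind == "exit"]
    m <- min(length(ent), length(ext))
    if (m) {
      iv <- normalizeIntervals(cbind(ent[seq_len(m)], ext[seq_len(m)]))
      at[pointsInIntervals(p@timeS, iv)] <- wid
    }
  }
  at
}

#' Immobility-at-well occupancy intervals
#'
#' Intersects the immobility intervals of the motion segmentation with
#' periods when the animal is at each reward well. A position sample counts
#' as at a well when it falls inside a recorded entry-exit interval for that
#' well (beam-break events take precedence) or within the well radius.
#'
#' @param session a \linkS4class{Session} with speed computed.
#' @param segments motion segmentation from \code{\link{segmentMotion}}.
#' @param wellIds wells to report (default: all in the session).
#' @return Named list of two-column matrices of half-open intervals.
#' @export
wellOccupancyIntervals <- function(session, segments, wellIds = NULL) {
  wells <- session@wells
  if (is.null(wellIds)) wellIds <- wells$well_id
  unknown <- setdiff(wellIds, wells$well_id)
  if (length(unknown))
    stop("unknown well id(s): ", paste(unknown, collapse = ", "))
  immo <- segmentsToIntervals(segments, "immobility")
  at <- wellAtSamples(session)
  t <- session@position@timeS
  out <- vector("list", length(wellIds)); names(out) <- wellIds
  for (wid in wellIds) {
    iv <- maskToIntervals(t, !is.na(at) & at == wid)
    out[[wid]] <- intersectIntervals(iv, immo)
  }
  out
}

#' Spatial occupancy map
#'
#' Bins tracked time into square spatial bins (default 2 cm). Each sample
#' contributes its frame duration to the bin containing it, so the summed
#' map equals the tracked duration to within one frame.
#'
#' @param position a \linkS4class{PositionTrace}.
#' @param binCm bin side length (cm).
#' @return List with \code{binEdgesX}, \code{binEdgesY}, \code{seconds}
#'   (matrix, x bins in rows, y in columns).
#' @export
occupancyMap <- function(position, binCm = 2) {
  t <- position@timeS; x <- position@xCm; y <- position@yCm
  n <- length(t)
  dt <- c(diff(t), if (n > 1L) median(diff(t)) else 1 / 30)
  ex <- seq(floor(min(x) / binCm) * binCm, ceiling(max(x) / binCm) * binCm + binCm,
            by = binCm)
  ey <- seq(floor(min(y) / binCm) * binCm, ceiling(max(y) / binCm) * binCm + binCm,
            by = binCm)
  ix <- findInterval(x, ex, rightmost.closed = TRUE)
  iy <- findInterval(y, ey, rightmost.closed = TRUE)
  seconds <- matrix(0, length(ex) - 1L, length(ey) - 1L)
  agg <- rowsum(dt, group = (iy - 1L) * (length(ex) - 1L) + ix)
  seconds[as.integer(rownames(agg))] <- agg[, 1]
  list(binEdgesX = ex, binEdgesY = ey, seconds = seconds)
}
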