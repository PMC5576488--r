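# Synthetic session generator with ground truth. Emulates the statistical
# structure the analysis assumes: alternating ~6.6 s movement/immobility
# bouts between reward wells, CA1 units with movement place fields (MAPs)
# or single-well immobility fields (IAPs), ripple-band bursts injected into
# pink-noise LFP during immobility with labelled spike content, and PFC
# units with behavior-locked firing and SWR-class-specific gain.

wellLayout <- function(nWells, arenaCm) {
  ang <- 2 * pi * (seq_len(nWells) - 1L) / nWells + pi / 4
  data.frame(well_id = paste0("W", seq_len(nWells)),
             x_cm = arenaCm / 2 + 0.35 * arenaCm * cos(ang),
             y_cm = arenaCm / 2 + 0.35 * arenaCm * sin(ang),
             radius_cm = NA_real_, stringsAsFactors = FALSE)
}

# Bout durations: gamma with the configured mean and CV ~ 0.3.
drawBout <- function(n, meanS) stats::rgamma(n, shape = 10, scale = meanS / 10)

#' Generate behavior: trajectory, wells, well events and bout schedule
#'
#' Produces an alternating schedule of immobility bouts at reward wells
#' (slow sub-centimetre position jitter) and movement bouts along straight
#' well-to-well paths with a smooth trapezoidal speed profile (0.25 s
#' acceleration ramps around a constant plateau), bout durations drawn
#' around \code{generator$mean_bout_s}. Beam-break style entry/exit events
#' are emitted at the start and end of every immobility bout.
#'
#' @param config pipeline configuration (\code{\link{defaultConfig}}).
#' @param seed integer seed.
#' @return List: \code{position} (\linkS4class{PositionTrace}),
#'   \code{wells}, \code{wellEvents}, \code{boutSchedule} (data.frames).
#' @export
generateBehavior <- function(config = defaultConfig(), seed = 1) {
  g <- config$generator
  set.seed(deriveSeed(seed, "behavior"))
  wells <- wellLayout(g$n_wells, g$arena_cm)
  wells$radius_cm <- g$well_radius_cm
  T <- g$session_length_s
  if (T < 2 * g$mean_bout_s)
    stop("session too short for one full movement/immobility bout")

  state <- character(0); s0 <- numeric(0); s1 <- numeric(0)
  wellIdx <- integer(0); fromIdx <- integer(0)
  cur <- 1L; t <- 0
  immobile <- TRUE
  while (t < T) {
    d <- drawBout(1, g$mean_bout_s)
    end <- min(t + d, T)
    if (immobile) {
      state <- c(state, "immobility"); wellIdx <- c(wellIdx, cur)
      fromIdx <- c(fromIdx, NA_integer_)
    } else {
      nxt <- sample(setdiff(seq_len(g$n_wells), cur), 1L)
      state <- c(state, "movement"); fromIdx <- c(fromIdx, cur)
      wellIdx <- c(wellIdx, nxt)
      cur <- nxt
    }
    s0 <- c(s0, t); s1 <- c(s1, end)
    t <- end
    immobile <- !immobile
  }
  sched <- data.frame(state = state, start_s = s0, end_s = s1,
                      well_id = wells$well_id[wellIdx],
                      from_well = ifelse(is.na(fromIdx), NA_character_,
                                         wells$well_id[fromIdx]),
                      stringsAsFactors = FALSE)

  fps <- g$position_rate_hz
  tt <- seq(0, T, by = 1 / fps)
  x <- numeric(length(tt)); y <- numeric(length(tt))
  for (i in seq_len(nrow(sched))) {
    sel <- tt >= sched$start_s[i] &
      (if (i == nrow(sched)) tt <= sched$end_s[i] else tt < sched$end_s[i])
    if (!any(sel)) next
    wTo <- match(sched$well_id[i], wells$well_id)
    if (sched$state[i] == "immobility") {
      x[sel] <- wells$x_cm[wTo]; y[sel] <- wells$y_cm[wTo]
    } else {
      wFrom <- match(sched$from_well[i], wells$well_id)
      D <- sched$end_s[i] - sched$start_s[i]
      tloc <- tt[sel] - sched$start_s[i]
      # trapezoidal speed profile: linear acceleration over rampS at each
      # end, constant plateau between; sharp enough that the 4 cm/s
      # threshold is crossed within ~0.2 s of the bout boundary
      rampS <- min(0.25, D / 4)
      dx <- wells$x_cm[wTo] - wells$x_cm[wFrom]
      dy <- wells$y_cm[wTo] - wells$y_cm[wFrom]
      L <- sqrt(dx^2 + dy^2)
      V <- L / (D - rampS)
      dist <- ifelse(tloc <= rampS, V * tloc^2 / (2 * rampS),
              ifelse(tloc <= D - rampS, V * (tloc - rampS / 2),
                     L - V * pmax(D - tloc, 0)^2 / (2 * rampS)))
      frac <- pmin(dist / L, 1)
      x[sel] <- wells$x_cm[wFrom] + frac * dx
      y[sel] <- wells$y_cm[wFrom] + frac * dy
    }
  }
  # slow tracking jitter (SD 0.15 cm, ~0.5 s correlation time)
  jit <- function() gaussianSmooth(rnorm(length(tt)), 0.5 * fps)
  jx <- jit(); jy <- jit()
  x <- x + 0.15 * jx / sd(jx)
  y <- y + 0.15 * jy / sd(jy)

  immoSel <- sched$state == "immobility"
  wellEvents <- data.frame(
    time_s = c(sched$start_s[immoSel], sched$end_s[immoSel]),
    well_id = rep(sched$well_id[immoSel], 2L),
    kind = rep(c("entry", "exit"), each = sum(immoSel)),
    stringsAsFactors = FALSE)
  wellEvents <- wellEvents[order(wellEvents$time_s), ]
  rownames(wellEvents) <- NULL

  list(position = PositionTrace(tt, x, y), wells = wells,
       wellEvents = wellEvents, boutSchedule = sched)
}

scheduleIntervals <- function(sched, state, wellId = NULL) {
  sel <- sched$state == state
  if (!is.null(wellId)) sel <- sel & sched$well_id == wellId
  cbind(sched$start_s[sel], sched$end_s[sel])
}

# Homogeneous Poisson times on a union of intervals.
poissonOnIntervals <- function(iv, rateHz) {
  iv <- normalizeIntervals(iv)
  if (!nrow(iv) || rateHz <= 0) return(numeric(0))
  out <- lapply(seq_len(nrow(iv)), function(i) {
    len <- iv[i, 2] - iv[i, 1]
    k <- rpois(1, rateHz * len)
    if (k) sort(runif(k, iv[i, 1], iv[i, 2])) else numeric(0)
  })
  unlist(out, use.names = FALSE)
}

#' Generate CA1 place-cell spike trains
#'
#' MAP units fire as inhomogeneous Poisson processes with 2-D Gaussian
#' place fields centred on well-to-well paths, gated to movement bouts and
#' multiplicatively theta-modulated (default 8 Hz). IAP units fire as
#' homogeneous Poisson at \code{generator$iap_rate_hz} during immobility at
#' their home well only. Outside those states the units are silent; SWR
#' content spikes are added later by \code{\link{generateLfpWithSwrs}}.
#'
#' @param config pipeline configuration.
#' @param behavior output of \code{\link{generateBehavior}}.
#' @param seed integer seed.
#' @return List: \code{units} (list of \linkS4class{SpikeTrain}),
#'   \code{labels} (data.frame \code{unit_id, label, home_well,
#'   field_x_cm, field_y_cm}).
#' @export
generateCa1Units <- function(config, behavior, seed = 1) {
  g <- config$generator
  if (g$n_map + g$n_iap == 0) stop("need at least one CA1 unit (n_map + n_iap = 0)")
  set.seed(deriveSeed(seed, "ca1"))
  sched <- behavior$boutSchedule
  wells <- behavior$wells
  pos <- behavior$position
  units <- list(); labels <- NULL
  moveIv <- scheduleIntervals(sched, "movement")

  for (i in seq_len(g$n_map)) {
    pair <- sample(nrow(wells), 2L)
    frac <- runif(1, 0.25, 0.75)
    fx <- wells$x_cm[pair[1]] + frac * (wells$x_cm[pair[2]] - wells$x_cm[pair[1]])
    fy <- wells$y_cm[pair[1]] + frac * (wells$y_cm[pair[2]] - wells$y_cm[pair[1]])
    lmax <- g$field_peak_hz * (1 + g$theta_depth)
    cand <- poissonOnIntervals(moveIv, lmax)
    if (length(cand)) {
      cx <- interpAt(pos@timeS, pos@xCm, cand)
      cy <- interpAt(pos@timeS, pos@yCm, cand)
      lam <- g$field_peak_hz *
        exp(-((cx - fx)^2 + (cy - fy)^2) / (2 * g$field_sigma_cm^2)) *
        (1 + g$theta_depth * sin(2 * pi * g$theta_freq_hz * cand))
      st <- cand[runif(length(cand)) < lam / lmax]
    } else st <- numeric(0)
    uid <- sprintf("MAP%02d", i)
    units[[uid]] <- SpikeTrain(uid, "CA1", unique(st), runif(1, 0.5, 0.8))
    labels <- rbind(labels, data.frame(unit_id = uid, label = "MAP",
                                       home_well = NA_character_,
                                       field_x_cm = fx, field_y_cm = fy,
                                       stringsAsFactors = FALSE))
  }
  for (i in seq_len(g$n_iap)) {
    home <- wells$well_id[((i - 1L) %% nrow(wells)) + 1L]
    iv <- scheduleIntervals(sched, "immobility", home)
    st <- poissonOnIntervals(iv, g$iap_rate_hz)
    uid <- sprintf("IAP%02d", i)
    units[[uid]] <- SpikeTrain(uid, "CA1", unique(st), runif(1, 0.5, 0.8))
    labels <- rbind(labels, data.frame(unit_id = uid, label = "IAP",
                                       home_well = home,
                                       field_x_cm = wells$x_cm[wells$well_id == home],
                                       field_y_cm = wells$y_cm[wells$well_id == home],
                                       stringsAsFactors = FALSE))
  }
  list(units = units, labels = labels)
}

#' Generate LFP with injected sharp-wave ripples and labelled content
#'
#' Builds per-channel pink-noise LFP, then at Poisson times inside
#' immobility bouts injects ripple bursts: a sinusoid at
#' \code{generator$ripple_freq_hz} under a raised-cosine envelope of
#' lognormal duration, with peak envelope \code{ripple_snr * sqrt(2)}
#' times the channel's ripple-band noise SD, added to every channel with
#' small per-channel amplitude jitter. Each event draws a content class
#' from \code{class_probs}; participating units (per-unit Bernoulli with
#' \code{participation_prob}, at least one per required class) receive
#' spikes uniform within the event. Background CA1 spikes inside injected
#' event windows are removed first, so the recorded ground-truth class is
#' exact.
#'
#' @param config pipeline configuration.
#' @param behavior output of \code{\link{generateBehavior}}.
#' @param ca1 output of \code{\link{generateCa1Units}}.
#' @param seed integer seed.
#' @return List: \code{lfp} (\linkS4class{LfpBundle}), \code{swrTruth}
#'   (data.frame), \code{units} (CA1 trains with content spikes appended).
#' @export
generateLfpWithSwrs <- function(config, behavior, ca1, seed = 1) {
  g <- config$generator
  if (g$ripple_snr <= 0) stop("ripple_snr must be > 0")
  set.seed(deriveSeed(seed, "lfp"))
  fs <- g$lfp_sample_rate_hz
  T <- g$session_length_s
  n <- round(T * fs)
  nch <- g$n_channels
  noise <- matrix(0, n, nch)
  for (j in seq_len(nch)) noise[, j] <- pinkNoise(n) * g$lfp_noise_sd_uv
  b <- rippleFir(fs, c(150, 250))
  bandSd <- vapply(seq_len(nch),
                   function(j) sd(firFilterZeroPhase(noise[, j], b)), numeric(1))

  sched <- behavior$boutSchedule
  immo <- sched[sched$state == "immobility", , drop = FALSE]
  classes <- c("MAP-only", "IAP-only", "joint")
  ev <- NULL
  if (g$swr_rate_hz > 0) for (i in seq_len(nrow(immo))) {
    cur <- immo$start_s[i] + 0.1
    bend <- immo$end_s[i] - 0.1
    repeat {
      start <- cur + rexp(1, g$swr_rate_hz)
      cls <- sample(classes, 1L, prob = g$class_probs)
      dur <- rlnorm(1, g$swr_duration_mu_log, g$swr_duration_sigma_log)
      if (cls == "IAP-only") dur <- dur * g$iap_duration_scale
      dur <- min(max(dur, 0.03), 0.4)
      if (start + dur > bend) break
      ev <- rbind(ev, data.frame(start_s = start, end_s = start + dur,
                                 class = cls,
                                 amplitude_scale = rlnorm(1, 0, 0.2),
                                 well_id = immo$well_id[i],
                                 stringsAsFactors = FALSE))
      cur <- start + dur + g$min_event_gap_s
    }
  }
  units <- ca1$units
  labels <- ca1$labels
  mapIds <- labels$unit_id[labels$label == "MAP"]
  iapIds <- labels$unit_id[labels$label == "IAP"]
  participants <- character(0)

  if (!is.null(ev) && nrow(ev)) {
    ev <- ev[order(ev$start_s), ]; rownames(ev) <- NULL
    # injected content is authoritative: strip background spikes in the
    # event windows plus a guard margin, so the labelled class describes
    # the event as any detector bounding it at the envelope mean crossing
    # will see it
    guard <- g$content_guard_s
    evIv <- cbind(ev$start_s - guard, ev$end_s + guard)
    contentBuffer <- lapply(units, function(u)
      u@spikeTimes[!pointsInIntervals(u@spikeTimes, evIv)])
    drawParticipants <- function(ids) {
      if (!length(ids)) return(character(0))
      sel <- ids[runif(length(ids)) < g$participation_prob]
      if (!length(sel)) sel <- sample(ids, 1L)
      sel
    }
    participants <- character(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      who <- switch(ev$class[i],
        "MAP-only" = drawParticipants(mapIds),
        "IAP-only" = drawParticipants(iapIds),
        "joint" = c(drawParticipants(mapIds), drawParticipants(iapIds)))
      participants[i] <- paste(who, collapse = ",")
      D <- ev$end_s[i] - ev$start_s[i]
      for (uid in who) {
        k <- 1L + rpois(1, max(0, g$content_spike_mean - 1))
        isIap <- uid %in% iapIds
        span <- if (isIap && g$iap_early_offset_s > 0)
          max(D - g$iap_early_offset_s, D / 2) else D
        stimes <- ev$start_s[i] + runif(k, 0, span) * (1 - 1e-9)
        contentBuffer[[uid]] <- c(contentBuffer[[uid]], stimes)
      }
    }
    for (uid in names(units)) {
      st <- sort(unique(contentBuffer[[uid]]))
      units[[uid]] <- initialize(units[[uid]], spikeTimes = st)
    }
    # inject ripple bursts
    phase <- runif(nrow(ev), 0, 2 * pi)
    for (i in seq_len(nrow(ev))) {
      i0 <- floor(ev$start_s[i] * fs) + 1L
      i1 <- min(ceiling(ev$end_s[i] * fs), n)
      if (i1 <= i0) next
      tloc <- ((i0:i1) - 1L) / fs - ev$start_s[i]
      D <- ev$end_s[i] - ev$start_s[i]
      envl <- 0.5 * (1 - cos(2 * pi * pmin(pmax(tloc / D, 0), 1)))
      carrier <- sin(2 * pi * g$ripple_freq_hz * tloc + phase[i])
      for (j in seq_len(nch)) {
        amp <- g$ripple_snr * sqrt(2) * bandSd[j] * ev$amplitude_scale[i] *
          runif(1, 0.8, 1.2)
        noise[i0:i1, j] <- noise[i0:i1, j] + amp * envl * carrier
      }
    }
    ev$participants <- participants
  } else {
    ev <- data.frame(start_s = numeric(0), end_s = numeric(0),
                     class = character(0), amplitude_scale = numeric(0),
                     well_id = character(0), participants = character(0),
                     stringsAsFactors = FALSE)
  }
  lfp <- LfpBundle(noise, fs, paste0("tet", seq_len(nch)), t0S = 0)
  list(lfp = lfp, swrTruth = ev, units = units)
}

pfcGroupPlan <- function(nPfc) {
  base <- c("IAP+", "MAP+", "inhibited", "IAP+", "MAP+", "inhibited",
            "both+", "flat")
  base[((seq_len(nPfc) - 1L) %% length(base)) + 1L]
}

pfcGains <- function(group, gE, gI) {
  switch(group,
    "IAP+" = c(map = 1, iap = gE, joint = sqrt(gE)),
    "MAP+" = c(map = gE, iap = 1, joint = sqrt(gE)),
    "inhibited" = c(map = gI, iap = gI, joint = gI),
    "both+" = c(map = gE, iap = gE, joint = gE),
    "flat" = c(map = 1, iap = 1, joint = 1))
}

#' Generate PFC spike trains with behavior- and SWR-locked gain
#'
#' Each PFC unit fires as an inhomogeneous Poisson process: a baseline
#' rate, a behavior-locked multiplier (movement-tuned units are elevated
#' during movement bouts; immobility-onset units carry an exponentially
#' decaying elevation after reward-well entry; others are flat), and a
#' multiplicative per-class gain inside injected SWR windows (gain > 1
#' excitation, < 1 inhibition). Groups cycle through IAP-excited,
#' MAP-excited, inhibited-both, both-excited and flat.
#'
#' @param config pipeline configuration.
#' @param behavior output of \code{\link{generateBehavior}}.
#' @param swrTruth truth table from \code{\link{generateLfpWithSwrs}}.
#' @param seed integer seed.
#' @return List: \code{units} (list of \linkS4class{SpikeTrain}),
#'   \code{labels} (data.frame with group and per-class gains).
#' @export
generatePfcUnits <- function(config, behavior, swrTruth, seed = 1) {
  g <- config$generator
  set.seed(deriveSeed(seed, "pfc"))
  sched <- behavior$boutSchedule
  T <- g$session_length_s
  groups <- pfcGroupPlan(g$n_pfc)
  immo <- sched[sched$state == "immobility", , drop = FALSE]
  moveIv <- scheduleIntervals(sched, "movement")
  bg <- g$pfc_behavior_gain

  behaviorMult <- function(t, profile) {
    m <- rep(1, length(t))
    if (profile == "movement") {
      m[pointsInIntervals(t, moveIv)] <- bg
    } else if (profile == "immobility_onset" && nrow(immo)) {
      idx <- findInterval(t, immo$start_s)
      ok <- idx >= 1L & t < immo$end_s[pmax(idx, 1L)]
      dt <- t[ok] - immo$start_s[idx[ok]]
      m[ok] <- 1 + (bg - 1) * exp(-dt / 2)
    }
    m
  }
  swrMult <- function(t, gains) {
    m <- rep(1, length(t))
    if (nrow(swrTruth)) {
      idx <- findInterval(t, swrTruth$start_s)
      ok <- idx >= 1L & t < swrTruth$end_s[pmax(idx, 1L)]
      cls <- swrTruth$class[idx[ok]]
      m[ok] <- gains[match(cls, c("MAP-only", "IAP-only", "joint"))]
    }
    m
  }
  units <- list(); labels <- NULL
  for (i in seq_len(g$n_pfc)) {
    grp <- groups[i]
    gains <- pfcGains(grp, g$pfc_gain_excited, g$pfc_gain_inhibited)
    profile <- switch(grp, "IAP+" = "immobility_onset", "MAP+" = "movement",
                      "flat")
    lmax <- g$pfc_baseline_hz * max(1, bg) * max(1, gains)
    cand <- sort(runif(rpois(1, lmax * T), 0, T))
    lam <- g$pfc_baseline_hz * behaviorMult(cand, profile) * swrMult(cand, gains)
    st <- cand[runif(length(cand)) < lam / lmax]
    uid <- sprintf("PFC%02d", i)
    units[[uid]] <- SpikeTrain(uid, "PFC", unique(st), runif(1, 0.5, 0.9))
    labels <- rbind(labels, data.frame(
      unit_id = uid, label = "PFC", pfc_group = grp,
      gain_map = gains[["map"]], gain_iap = gains[["iap"]],
      gain_joint = gains[["joint"]], stringsAsFactors = FALSE))
  }
  list(units = units, labels = labels)
}

#' Generate a complete synthetic session with ground truth
#'
#' Composes \code{\link{generateBehavior}},
#' \code{\link{generateCa1Units}}, \code{\link{generateLfpWithSwrs}} and
#' \code{\link{generatePfcUnits}} with seeds derived deterministically from
#' \code{seed}; the same seed always yields the identical session.
#'
#' @param config pipeline configuration.
#' @param seed integer seed.
#' @return List with \code{session} (\linkS4class{Session}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' cfg <- defaultConfig()
#' cfg$generator$session_length_s <- 60
#' cfg$generator$lfp_sample_rate_hz <- 1000
#' out <- generateSession(cfg, seed = 7)
#' out$session
#' @export
generateSession <- function(config = defaultConfig(), seed = 1) {
  validateConfig(config)
  beh <- generateBehavior(config, seed)
  ca1 <- generateCa1Units(config, beh, seed)
  lfpOut <- generateLfpWithSwrs(config, beh, ca1, seed)
  pfc <- generatePfcUnits(config, beh, lfpOut$swrTruth, seed)
  units <- c(lfpOut$units, pfc$units)
  # a recordable (spike-sorted) unit has spikes by construction; in very
  # short sessions a unit whose field or home well was never visited may
  # end up silent and is dropped from the session and the truth table
  silent <- vapply(units, function(u) length(u@spikeTimes) == 0L, logical(1))
  units <- units[!silent]
  ca1$labels <- ca1$labels[ca1$labels$unit_id %in% names(units), , drop = FALSE]
  pfc$labels <- pfc$labels[pfc$labels$unit_id %in% names(units), , drop = FALSE]
  ca1Lab <- ca1$labels
  ca1Lab$pfc_group <- NA_character_
  ca1Lab$gain_map <- NA_real_; ca1Lab$gain_iap <- NA_real_
  ca1Lab$gain_joint <- NA_real_
  pfcLab <- pfc$labels
  pfcLab$home_well <- NA_character_
  pfcLab$field_x_cm <- NA_real_; pfcLab$field_y_cm <- NA_real_
  unitLabels <- rbind(ca1Lab, pfcLab[, names(ca1Lab)])
  epochs <- data.frame(label = beh$boutSchedule$state,
                       start_s = beh$boutSchedule$start_s,
                       end_s = beh$boutSchedule$end_s,
                       stringsAsFactors = FALSE)
  session <- Session(beh$position, units, lfpOut$lfp, beh$wells,
                     beh$wellEvents, epochs,
                     metadata = list(generator_seed = seed))
  truth <- new("GroundTruth", unitLabels = unitLabels,
               swrTruth = lfpOut$swrTruth, boutSchedule = beh$boutSchedule)
  list(session = session, truth = truth)
}
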