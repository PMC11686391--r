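# Intracardiac electrogram (iEGM) analysis.
#
# 1-kHz records with a 12-lead-style ECG, a bipolar channel (30-500 Hz) and
# a broadened-band unipolar channel (0.5-500 Hz). QRS complexes detected on
# the best ECG lead (slope-threshold detector with adaptive threshold) serve
# as fiducial points; per beat we measure the bipolar peak-to-peak amplitude
# in a 400-ms window and the unipolar current of injury (COI): the area
# under the ST segment relative to the pre-QRS isoelectric baseline,
# divided by the window length so T-wave-onset uncertainty cancels to first
# order. 10-s segment medians and pre / 30 s / 3.5 min timepoints summarise
# the time course.

#' Construct a signal record
#'
#' @param ecg matrix (samples x leads) or named list of numeric vectors, mV.
#' @param unipolar,bipolar numeric vectors, mV.
#' @param fs sampling frequency, Hz (the pipeline assumes 1000).
#' @param ablation_time time of the PFA delivery, s.
#' @param saturation_mask optional logical per sample (amplifier saturated).
#' @return object of class `pfa_signal_record`.
#' @export
signal_record <- function(ecg, unipolar, bipolar, fs = 1000,
                          ablation_time = NA_real_, saturation_mask = NULL) {
  ecg <- as.matrix(as.data.frame(ecg))
  n <- nrow(ecg)
  stopifnot(length(unipolar) == n, length(bipolar) == n, fs > 0)
  if (is.null(saturation_mask)) saturation_mask <- rep(FALSE, n)
  stopifnot(length(saturation_mask) == n)
  if (!is.na(ablation_time)) stopifnot(ablation_time >= 0, ablation_time <= n / fs)
  r <- list(ecg = ecg, unipolar = as.numeric(unipolar),
            bipolar = as.numeric(bipolar), fs = fs,
            ablation_time = ablation_time,
            saturation_mask = saturation_mask, duration = n / fs)
  class(r) <- "pfa_signal_record"
  r
}

#' QRS detection (slope-threshold, So-Chan style)
#'
#' The lead is high-pass pre-filtered at 10 Hz and its first 50 samples are
#' zeroed (a segment-initial QRS would otherwise lock the adaptive
#' threshold). Detection uses the smoothed slope
#' `s(n) = -2x(n-2) - x(n-1) + x(n+1) + 2x(n+2)`: a beat is declared when
#' the slope exceeds `threshold_frac` of the running slope maximum (seeded
#' from the first `init_s` seconds), the R peak is the absolute filtered
#' maximum within the following 150 ms, and a 200 ms refractory period is
#' enforced. The running maximum adapts as an exponential moving average of
#' detected peak slopes.
#'
#' @param record a [signal_record()].
#' @param lead ECG lead index or name.
#' @param threshold_frac fraction of the adaptive slope maximum.
#' @param refractory_s refractory period, s.
#' @param init_s initialization window for the slope maximum, s.
#' @return object of class `pfa_beat_set`: `qrs_indices` (sample index of
#'   each R peak), `valid` flags, and the filtered lead.
#' @export
detect_qrs <- function(record, lead = 1, threshold_frac = 0.6,
                       refractory_s = 0.2, init_s = 3) {
  x <- record$ecg[, lead]
  fs <- record$fs
  x <- hp_filter(x, fs, 10)
  x[seq_len(min(50L, length(x)))] <- 0
  n <- length(x)
  if (all(abs(x) < 1e-9)) {
    warning("flat-line lead: no beats detected")
    return(structure(list(qrs_indices = integer(0), valid = logical(0),
                          filtered = x), class = "pfa_beat_set"))
  }
  sl <- numeric(n)
  sl[3:(n - 2)] <- -2 * x[1:(n - 4)] - x[2:(n - 3)] + x[4:(n - 1)] + 2 * x[5:n]
  sl <- abs(sl)
  sl[seq_len(min(n, 75L))] <- 0   # ignore the zeroed prefix and its step edge
  ref <- round(refractory_s * fs)
  maxi <- max(sl[seq_len(min(n, round(init_s * fs)))])
  if (maxi <= 0) maxi <- max(sl)
  peaks <- integer(0)
  i <- 3L
  while (i <= n - 2L) {
    if (sl[i] > threshold_frac * maxi && sl[i + 1] > threshold_frac * maxi) {
      win <- i:min(n, i + round(0.15 * fs))
      pk <- win[which.max(abs(x[win]))]
      peaks <- c(peaks, pk)
      maxi <- (15 * maxi + max(sl[win])) / 16
      i <- pk + ref
    } else i <- i + 1L
  }
  valid <- rep(TRUE, length(peaks))
  if (length(peaks) > 1) valid[c(Inf, diff(peaks)) < ref] <- FALSE
  structure(list(qrs_indices = peaks, valid = valid, filtered = x,
                 lead = lead), class = "pfa_beat_set")
}

# zero-phase Butterworth high-pass
hp_filter <- function(x, fs, fc, order = 2) {
  bf <- signal::butter(order, fc / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

# zero-phase Butterworth low-pass
lp_filter <- function(x, fs, fc, order = 2) {
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Per-beat bipolar peak-to-peak amplitude
#'
#' Max minus min of the raw bipolar channel in a 400-ms window starting
#' 200 ms before each detected R peak. Beats whose window leaves the record
#' or touches saturated samples are marked invalid.
#'
#' @param record a [signal_record()].
#' @param beats a [detect_qrs()] result.
#' @return data.frame with `beat`, `qrs_index`, `time_s`, `pp_bipolar`
#'   (mV), `valid`.
#' @export
bipolar_peak_to_peak <- function(record, beats) {
  fs <- record$fs
  half <- round(0.2 * fs)
  out <- data.frame(beat = seq_along(beats$qrs_indices),
                    qrs_index = beats$qrs_indices,
                    time_s = beats$qrs_indices / fs,
                    pp_bipolar = NA_real_,
                    valid = beats$valid)
  for (b in seq_len(nrow(out))) {
    i0 <- out$qrs_index[b] - half; i1 <- out$qrs_index[b] + half
    if (i0 < 1 || i1 > length(record$bipolar)) { out$valid[b] <- FALSE; next }
    if (any(record$saturation_mask[i0:i1])) { out$valid[b] <- FALSE; next }
    w <- record$bipolar[i0:i1]
    out$pp_bipolar[b] <- max(w) - min(w)
  }
  out
}

#' Per-beat unipolar current of injury (COI)
#'
#' Baseline: mean of the latest 50-ms span ending at least 20 ms before the
#' QRS onset whose peak-to-peak is below `iso_tol` (falling back to the
#' 50 ms immediately before onset). AUC window: from the QRS end (filtered
#' envelope below 10% of the R amplitude for 40 ms) to the estimated T-wave
#' onset (`R + 0.25 * median RR`, capped at R + 350 ms). COI = AUC / window
#' length, in mV.
#'
#' @param record a [signal_record()].
#' @param beats a [detect_qrs()] result.
#' @param iso_tol isoelectric peak-to-peak tolerance, mV.
#' @return data.frame with `beat`, `qrs_index`, `time_s`, `coi` (mV),
#'   `auc_start`, `auc_end`, `baseline`, `valid`.
#' @export
compute_coi <- function(record, beats, iso_tol = 0.1) {
  fs <- record$fs
  x <- record$unipolar
  xf <- beats$filtered
  qrs <- beats$qrs_indices
  rr <- if (length(qrs) > 1) stats::median(diff(qrs)) else round(0.8 * fs)
  w50 <- round(0.05 * fs); w20 <- round(0.02 * fs); w40 <- round(0.04 * fs)
  out <- data.frame(beat = seq_along(qrs), qrs_index = qrs, time_s = qrs / fs,
                    coi = NA_real_, auc_start = NA_integer_,
                    auc_end = NA_integer_, baseline = NA_real_,
                    valid = beats$valid)
  for (b in seq_along(qrs)) {
    if (!out$valid[b]) next
    pk <- qrs[b]
    ramp <- abs(xf[pk])
    # QRS onset: envelope below 10% of R for >= 20 ms, scanning backwards
    onset <- NA_integer_
    i <- pk - 1L
    lim <- max(1L, pk - round(0.12 * fs))
    while (i > lim) {
      if (all(abs(xf[max(1, i - w20):i]) < 0.1 * ramp)) { onset <- i; break }
      i <- i - 1L
    }
    if (is.na(onset)) onset <- max(1L, pk - round(0.06 * fs))
    # QRS end: envelope below 10% of R for >= 40 ms, scanning forwards
    qend <- NA_integer_
    i <- pk + 1L
    lim <- min(length(xf) - w40, pk + round(0.15 * fs))
    while (i < lim) {
      if (all(abs(xf[i:(i + w40)]) < 0.1 * ramp)) { qend <- i + w40; break }
      i <- i + 1L
    }
    if (is.na(qend)) qend <- pk + round(0.08 * fs)
    t_on <- pk + min(round(0.25 * rr), round(0.35 * fs))
    if (t_on <= qend + 2 || t_on > length(x)) { out$valid[b] <- FALSE; next }
    # isoelectric baseline search
    base <- NA_real_
    e <- onset - w20
    while (e - w50 >= 1) {
      seg <- x[(e - w50):e]
      if (any(record$saturation_mask[(e - w50):e])) break
      if (max(seg) - min(seg) < iso_tol) { base <- mean(seg); break }
      e <- e - w20
      if (e < onset - w20 - 4 * w50) break
    }
    if (is.na(base)) {
      s0 <- max(1L, onset - w50)
      base <- mean(x[s0:onset])
    }
    if (any(record$saturation_mask[qend:t_on])) { out$valid[b] <- FALSE; next }
    seg <- x[qend:t_on] - base
    auc <- sum((seg[-1] + seg[-length(seg)]) / 2) / fs    # trapezoid, mV*s
    out$coi[b] <- auc / ((t_on - qend) / fs)
    out$auc_start[b] <- qend
    out$auc_end[b] <- t_on
    out$baseline[b] <- base
  }
  out
}

#' Summarise beat metrics over 10-s segments
#'
#' Non-overlapping 10-s windows; a window contributes a median only with at
#' least `min_beats` valid beats and at most `max_contaminated` fraction of
#' contaminated beats. Unipolar (COI) windows overlapping the 30 s of
#' amplifier saturation after the delivery are excluded by rule.
#'
#' @param pp result of [bipolar_peak_to_peak()].
#' @param coi result of [compute_coi()].
#' @param record the [signal_record()].
#' @param window_s window length, s.
#' @param min_beats minimum valid beats per window.
#' @param max_contaminated maximum contaminated-beat fraction.
#' @param saturation_recovery_s unipolar post-ablation blanking, s.
#' @return object of class `pfa_segment_summary`: data.frame `windows` with
#'   medians and exclusion reasons.
#' @export
summarize_segments <- function(pp, coi, record, window_s = 10,
                               min_beats = 10L, max_contaminated = 0.2,
                               saturation_recovery_s = 30) {
  dur <- record$duration
  nwin <- floor(dur / window_s)
  t_abl <- record$ablation_time
  rows <- lapply(seq_len(nwin), function(w) {
    t0 <- (w - 1) * window_s; t1 <- w * window_s
    inw <- pp$time_s >= t0 & pp$time_s < t1
    nb <- sum(inw)
    nvalid <- sum(inw & pp$valid)
    contam <- if (nb == 0) 1 else (nb - nvalid) / nb
    reason <- NA_character_
    if (nb > 0 && contam > max_contaminated) reason <- "artefacts"
    else if (nvalid < min_beats) reason <- "min-beats"
    med_pp <- if (is.na(reason)) stats::median(pp$pp_bipolar[inw & pp$valid]) else NA_real_
    # unipolar additionally blanked for 30 s after the delivery
    uni_blank <- !is.na(t_abl) && t0 < t_abl + saturation_recovery_s && t1 > t_abl
    inc <- coi$time_s >= t0 & coi$time_s < t1 & coi$valid & !is.na(coi$coi)
    med_coi <- if (is.na(reason) && !uni_blank && sum(inc) >= min_beats)
      stats::median(coi$coi[inc]) else NA_real_
    coi_reason <- if (!is.na(reason)) reason
      else if (uni_blank) "saturation-recovery"
      else if (sum(inc) < min_beats) "min-beats" else NA_character_
    data.frame(window = w, t_center = (t0 + t1) / 2, n_beats = nb,
               n_valid = nvalid, median_pp = med_pp, median_coi = med_coi,
               excluded = reason, coi_excluded = coi_reason,
               stringsAsFactors = FALSE)
  })
  out <- list(windows = do.call(rbind, rows), window_s = window_s,
              ablation_time = t_abl)
  class(out) <- "pfa_segment_summary"
  out
}

#' Extract pre/post-ablation timepoint values
#'
#' `pre`: median of the window medians before the delivery. `post_30s`:
#' first valid window starting at or after 30 s post delivery.
#' `post_3p5min`: window covering 3.5 min post delivery. Normalisations:
#' bipolar peak-to-peak relative to `pre`; COI at 3.5 min relative to 30 s.
#'
#' @param summary a [summarize_segments()] result.
#' @param ablation_time override of the record's delivery time, s.
#' @return list with `pp`, `coi` and `normalized` components (absent
#'   timepoints are `NA`).
#' @export
extract_timepoints <- function(summary, ablation_time = summary$ablation_time) {
  w <- summary$windows
  ws <- summary$window_s
  pre_w <- w[w$t_center + ws / 2 <= ablation_time, ]
  pick_at <- function(col, t_target) {
    cand <- w[w$t_center + ws / 2 > t_target & !is.na(w[[col]]), ]
    if (nrow(cand) == 0) return(NA_real_)
    cand[[col]][1]
  }
  pp_pre <- stats::median(pre_w$median_pp, na.rm = TRUE)
  coi_pre <- stats::median(pre_w$median_coi, na.rm = TRUE)
  pp_30 <- pick_at("median_pp", ablation_time + 30)
  coi_30 <- pick_at("median_coi", ablation_time + 30)
  cover <- function(col, t_target) {
    cand <- w[abs(w$t_center - t_target) <= ws / 2 & !is.na(w[[col]]), ]
    if (nrow(cand) == 0) return(NA_real_)
    cand[[col]][which.min(abs(cand$t_center - t_target))]
  }
  pp_210 <- cover("median_pp", ablation_time + 210)
  coi_210 <- cover("median_coi", ablation_time + 210)
  list(pp = c(pre = pp_pre, post_30s = pp_30, post_3p5min = pp_210),
       coi = c(pre = coi_pre, post_30s = coi_30, post_3p5min = coi_210),
       normalized = c(pp_post_over_pre = unname(pp_30 / pp_pre),
                      coi_3p5min_over_30s = unname(coi_210 / coi_30)))
}

#' Full iEGM analysis of one record
#'
#' QRS detection, per-beat metrics, segment medians and timepoints.
#' @param record a [signal_record()].
#' @param lead ECG lead used for QRS detection.
#' @return list with `beats`, `pp`, `coi`, `summary`, `timepoints`.
#' @export
analyze_iegm <- function(record, lead = 1) {
  beats <- detect_qrs(record, lead)
  pp <- bipolar_peak_to_peak(record, beats)
  coi <- compute_coi(record, beats)
  summ <- summarize_segments(pp, coi, record)
  tp <- if (!is.na(record$ablation_time)) extract_timepoints(summ) else NULL
  list(beats = beats, pp = pp, coi = coi, summary = summ, timepoints = tp)
}
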