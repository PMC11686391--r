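# Synthetic-data generators.
#
# Every pipeline input can be generated with known ground truth: lesion
# volume tables from forward field solves plus multiplicative lognormal
# measurement noise, scar intensity maps in the 40/60% convention, 1-kHz
# ECG/iEGM records with an injected, exponentially decaying current of
# injury, and biplane projections of 3-D catheter curves. All randomness is
# seeded explicitly; a fixed seed reproduces outputs exactly.

#' Generate a lesion-volume observation table
#'
#' Forward volumes `volume_above(solution, true_let)` per dose, multiplied
#' by lognormal noise `exp(N(0, sigma_log^2))`, emulating MRI-derived lesion
#' volume measurements at a known ground-truth lethal threshold.
#'
#' @param solutions a single [solve_field()] result (applied to every dose)
#'   or a list parallel to the rows of `doses`.
#' @param mesh the mesh (or list parallel to `doses`).
#' @param doses data.frame with `amplitude` (V) and `n_trains`.
#' @param true_let ground-truth threshold, V/cm; either one value or one per
#'   dose row.
#' @param lesions_per_dose observations per dose.
#' @param sigma_log lognormal noise scale (0.15 reflects the wide,
#'   right-skewed spread of in vivo lesion volumes).
#' @param timepoint imaging timepoint label.
#' @param n_animals animals to cycle lesions over.
#' @param seed RNG seed.
#' @return data.frame of LesionObservation rows with the generating
#'   ground truth attached as attributes `true_let` and `forward_volume`.
#' @export
gen_lesion_observations <- function(solutions, mesh,
                                    doses = data.frame(amplitude = 1500,
                                                       n_trains = 16),
                                    true_let = 400, lesions_per_dose = 12,
                                    sigma_log = 0.15, timepoint = "7d",
                                    n_animals = 6, seed = 1) {
  set.seed(seed)
  single <- inherits(solutions, "pfa_field")
  true_let <- rep_len(true_let, nrow(doses))
  rows <- list()
  lid <- 0L
  fwd <- numeric(0)
  for (d in seq_len(nrow(doses))) {
    sol <- if (single) solutions else solutions[[d]]
    msh <- if (inherits(mesh, "pfa_mesh")) mesh else mesh[[d]]
    v_fwd <- volume_above(sol, msh, true_let[d])
    if (v_fwd <= 0) {
      warning(sprintf("dose row %d: true LET %.0f V/cm outside achievable range; skipped",
                      d, true_let[d]))
      next
    }
    fwd <- c(fwd, v_fwd)
    seg <- if (!is.null(msh$abl)) msh$abl$segment_id else NA_integer_
    for (l in seq_len(lesions_per_dose)) {
      lid <- lid + 1L
      rows[[lid]] <- data.frame(
        lesion_id = lid,
        animal_id = ((lid - 1L) %% n_animals) + 1L,
        segment_id = seg,
        amplitude = doses$amplitude[d],
        n_trains = doses$n_trains[d],
        timepoint = timepoint,
        measured_volume = v_fwd * exp(stats::rnorm(1, 0, sigma_log)),
        tissue_class = "healthy",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(lesion_id = integer(0), animal_id = integer(0),
                      segment_id = integer(0), amplitude = numeric(0),
                      n_trains = integer(0), timepoint = character(0),
                      measured_volume = numeric(0),
                      tissue_class = character(0))
  } else out <- do.call(rbind, rows)
  attr(out, "true_let") <- true_let
  attr(out, "forward_volume") <- fwd
  out
}

#' Generate a synthetic scar intensity field
#'
#' Smooth normalized intensity in `[0, 1]` over the myocardium realizing
#' the requested pattern; thresholding at 40/60% produces remote tissue, a
#' border zone and a dense core.
#'
#' @param mesh classified mesh.
#' @param pattern `"none"`, `"anterior_patch"` (Gaussian patch centred on
#'   the mid anterior wall) or `"transmural_band"` (circumferential band at
#'   mid height).
#' @param peak peak intensity of the pattern.
#' @return a [scar_field()] over all mesh cells (zero outside the pattern).
#' @export
gen_scar_intensity <- function(mesh, pattern = c("none", "anterior_patch",
                                                 "transmural_band"),
                               peak = 0.9) {
  pattern <- match.arg(pattern)
  p <- cell_centers(mesh)
  intensity <- numeric(mesh$n_cells)
  myo <- mesh$region == REGION["myocardium"]
  if (pattern != "none" && any(myo)) {
    prm <- mesh$params
    zb <- segment_z_bounds(prm)
    z_mid <- mean(c(zb["z2"], zb["z1"]))
    if (pattern == "anterior_patch") {
      ang <- atan2(p[, 2], p[, 1])
      dang <- abs(((ang - pi / 2) + pi) %% (2 * pi) - pi)
      intensity <- peak * exp(-(dang^2 / (2 * 0.5^2) +
                                (p[, 3] - z_mid)^2 / (2 * 0.008^2)))
    } else {
      intensity <- peak * exp(-(p[, 3] - z_mid)^2 / (2 * 0.006^2))
    }
    intensity[!myo] <- 0
  }
  scar_field(intensity)
}

# single ECG beat template (sum of Gaussians), t in seconds relative to R
.beat_template <- function(t) {
  g <- function(a, mu, sd) a * exp(-(t - mu)^2 / (2 * sd^2))
  g(0.15, -0.19, 0.025) +      # P
    g(-0.10, -0.022, 0.008) +  # Q
    g(1.20, 0, 0.010) +        # R
    g(-0.22, 0.022, 0.008) +   # S
    g(0.35, 0.33, 0.045)       # T
}

# smooth boxcar (raised-cosine edges) for the injected ST component
.st_shape <- function(t, t0 = 0.035, t1 = 0.285, ramp = 0.02) {
  up <- (t - t0) / ramp; dn <- (t1 - t) / ramp
  s <- pmin(pmax(pmin(up, dn), 0), 1)
  0.5 - 0.5 * cos(pi * s)
}

#' Generate a synthetic ECG/iEGM record with ground truth
#'
#' 1-kHz record with `n_leads` scaled ECG leads (P-QRS-T Gaussians with RR
#' jitter), a band-limited bipolar channel whose depolarisation amplitude
#' drops after the delivery, and a unipolar channel with an injected ST
#' plateau of `st_plateau` mV decaying with time constant `st_decay_tau`
#' after `ablation_time`, plus slow baseline drift and additive noise.
#' Optionally the unipolar channel saturates for 25 s after the delivery.
#'
#' @param duration_s record length, s.
#' @param fs sampling frequency, Hz.
#' @param heart_rate beats per minute.
#' @param ablation_time delivery time, s (NA for a baseline-only record).
#' @param st_plateau injected current-of-injury plateau, mV.
#' @param st_decay_tau COI decay time constant, s.
#' @param bipolar_amp_pre,bipolar_drop bipolar depolarisation amplitude
#'   before the delivery (mV) and its post/pre ratio.
#' @param noise_snr_db additive-noise SNR relative to each channel's RMS.
#' @param rr_jitter_sd RR-interval jitter, s.
#' @param saturate saturate the unipolar amplifier after the delivery.
#' @param drift_mV,drift_Hz baseline-drift amplitude and frequency
#'   (unipolar channel).
#' @param n_leads number of ECG leads.
#' @param seed RNG seed.
#' @return list: `record` (a [signal_record()]) and `truth` (data.frame of
#'   beat times with the injected per-beat COI and bipolar amplitude).
#' @export
gen_iegm_record <- function(duration_s = 300, fs = 1000, heart_rate = 60,
                            ablation_time = NA, st_plateau = 4,
                            st_decay_tau = 120, bipolar_amp_pre = 6,
                            bipolar_drop = 0.5, noise_snr_db = 25,
                            rr_jitter_sd = 0.01, saturate = TRUE,
                            drift_mV = 0.25, drift_Hz = 0.05,
                            n_leads = 12, seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  rr <- 60 / heart_rate
  beat_t <- numeric(0)
  t <- 0.5
  while (t < duration_s - 0.5) {
    beat_t <- c(beat_t, t)
    t <- t + rr + stats::rnorm(1, 0, rr_jitter_sd)
  }
  nb <- length(beat_t)
  ecg1 <- numeric(n)
  uni <- numeric(n)
  bip <- numeric(n)
  post <- !is.na(ablation_time) & beat_t > ablation_time
  coi_true <- ifelse(post,
                     st_plateau * exp(-(beat_t - ablation_time) / st_decay_tau),
                     0)
  bip_true <- ifelse(post, bipolar_amp_pre * bipolar_drop, bipolar_amp_pre)
  for (b in seq_len(nb)) {
    i0 <- max(1L, round((beat_t[b] - 0.30) * fs))
    i1 <- min(n, round((beat_t[b] + 0.55) * fs))
    trel <- tt[i0:i1] - beat_t[b]
    w <- .beat_template(trel)
    ecg1[i0:i1] <- ecg1[i0:i1] + w
    uni[i0:i1] <- uni[i0:i1] + 0.8 * w + coi_true[b] * .st_shape(trel)
    # bipolar: high-frequency depolarisation burst (80 Hz Gabor)
    bip[i0:i1] <- bip[i0:i1] + bip_true[b] / 2 *
      sin(2 * pi * 80 * trel) * exp(-trel^2 / (2 * 0.006^2))
  }
  uni <- uni + drift_mV * sin(2 * pi * drift_Hz * tt)
  addnoise <- function(x) {
    s <- sqrt(mean(x^2)) * 10^(-noise_snr_db / 20)
    x + stats::rnorm(length(x), 0, s)
  }
  gains <- seq(0.5, 1.25, length.out = n_leads)
  ecg <- vapply(gains, function(g) addnoise(g * ecg1), numeric(n))
  colnames(ecg) <- paste0("lead", seq_len(n_leads))
  uni <- addnoise(uni)
  bip <- addnoise(bip)
  sat <- rep(FALSE, n)
  if (!is.na(ablation_time) && saturate) {
    si <- tt >= ablation_time & tt < ablation_time + 25
    uni[si] <- 20
    sat[si] <- TRUE
  }
  rec <- signal_record(ecg, uni, bip, fs = fs, ablation_time = ablation_time,
                       saturation_mask = sat)
  list(record = rec,
       truth = data.frame(beat = seq_len(nb), time_s = beat_t,
                          true_coi = coi_true, true_pp = bip_true))
}

#' Project a 3-D curve into a biplane view pair
#'
#' Perspective projection of the curve onto each detector with optional
#' pixel noise; the ground-truth curve is retained.
#'
#' @param curve matrix (n x 3) of 3-D points, m.
#' @param viewA,viewB [projection_view()] geometries (>= 45 degrees apart).
#' @param noise_px Gaussian pixel-noise standard deviation.
#' @param seed RNG seed.
#' @return list: the two views with `trace` (pixels) set, and `truth`.
#' @export
gen_biplane_views <- function(curve, viewA = projection_view(0),
                              viewB = projection_view(90), noise_px = 0,
                              seed = 1) {
  set.seed(seed)
  project <- function(view) {
    S <- view$source_position; O <- view$detector_origin
    nrm <- view$normal; ps <- view$pixel_spacing
    tr <- t(apply(curve, 1, function(X) {
      d <- X - S
      t <- sum((O - S) * nrm) / sum(d * nrm)
      P <- S + t * d
      c(sum((P - O) * view$u_axis), sum((P - O) * view$v_axis)) / ps
    }))
    if (noise_px > 0)
      tr <- tr + matrix(stats::rnorm(length(tr), 0, noise_px), nrow(tr), 2)
    view$trace <- tr
    view
  }
  list(viewA = project(viewA), viewB = project(viewB), truth = curve)
}
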