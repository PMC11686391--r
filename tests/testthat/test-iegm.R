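# Electrogram analysis: QRS detection on generated records, window metrics
# against brute-force oracles, segment medians and timepoint extraction.

test_that("QRS detection matches the generator's beat times", {
  g <- gen_iegm_record(duration_s = 60, heart_rate = 60, seed = 11,
                       ablation_time = NA)
  b <- detect_qrs(g$record, lead = 12)
  dt <- b$qrs_indices / g$record$fs
  offs <- vapply(g$truth$time_s, function(t) min(abs(dt - t)), 0)
  expect_true(all(offs < 0.02))                 # every true beat found
  extra <- vapply(dt, function(t) min(abs(g$truth$time_s - t)), 0)
  expect_true(all(extra < 0.02))                # no false detections
  expect_true(all(diff(b$qrs_indices) > 0.2 * g$record$fs))
})

test_that("a flat lead yields an empty beat set and zeroing hides early QRS", {
  n <- 10000
  rec0 <- signal_record(matrix(0, n, 1), numeric(n), numeric(n))
  expect_warning(b0 <- detect_qrs(rec0, 1), "flat")
  expect_length(b0$qrs_indices, 0)
  # beats at 30 ms (inside the zeroed 50 samples) and each second after
  tt <- (seq_len(n) - 1) / 1000
  ecg <- numeric(n)
  for (bt in c(0.03, seq(1, 9)))
    ecg <- ecg + pfasim:::.beat_template(tt - bt)
  rec <- signal_record(matrix(ecg, ncol = 1), numeric(n), numeric(n))
  b <- detect_qrs(rec, 1)
  dt <- b$qrs_indices / 1000
  expect_false(any(abs(dt - 0.03) < 0.05))      # zeroed-out first beat
  expect_true(all(vapply(seq(1, 9), function(t) any(abs(dt - t) < 0.02),
                         TRUE)))
})

test_that("bipolar peak-to-peak equals the brute-force window extremes", {
  n <- 5000
  tt <- (seq_len(n) - 1) / 1000
  ecg <- numeric(n)
  for (bt in c(1, 2, 3, 4)) ecg <- ecg + pfasim:::.beat_template(tt - bt)
  # deterministic bipolar with spikes of known amplitude near each beat
  bip <- 0.3 * sin(2 * pi * 40 * tt)
  bip[1012] <- 4; bip[1100] <- -2.5             # inside beat-1 window
  rec <- signal_record(matrix(ecg, ncol = 1), numeric(n), bip)
  beats <- detect_qrs(rec, 1)
  pp <- bipolar_peak_to_peak(rec, beats)
  # brute-force oracle
  for (b in seq_len(nrow(pp))) {
    if (!pp$valid[b]) next
    w <- bip[(pp$qrs_index[b] - 200):(pp$qrs_index[b] + 200)]
    expect_equal(pp$pp_bipolar[b], max(w) - min(w), tolerance = 1e-12)
  }
  expect_gt(pp$pp_bipolar[1], 6)                 # 4 - (-2.5)
  # sine of amplitude a across the window: pp = 2a
  rec2 <- signal_record(matrix(ecg, ncol = 1), numeric(n),
                        1.7 * sin(2 * pi * 25 * tt))
  pp2 <- bipolar_peak_to_peak(rec2, detect_qrs(rec2, 1))
  expect_equal(pp2$pp_bipolar[pp2$valid], rep(2 * 1.7, sum(pp2$valid)),
               tolerance = 1e-3)
  # constant signal: pp = 0
  rec3 <- signal_record(matrix(ecg, ncol = 1), numeric(n), rep(2, n))
  pp3 <- bipolar_peak_to_peak(rec3, detect_qrs(rec3, 1))
  expect_true(all(pp3$pp_bipolar[pp3$valid] == 0))
})

test_that("COI equals the mean ST deflection for known shapes", {
  n <- 6000
  tt <- (seq_len(n) - 1) / 1000
  ecg <- numeric(n)
  for (bt in 1:5) ecg <- ecg + pfasim:::.beat_template(tt - bt)
  mkrec <- function(st_fun) {
    uni <- 0.8 * ecg
    for (bt in 1:5) {
      sel <- tt >= bt - 0.3 & tt <= bt + 0.55
      uni[sel] <- uni[sel] + st_fun(tt[sel] - bt)
    }
    signal_record(matrix(ecg, ncol = 1), uni, numeric(n))
  }
  # flat plateau h across the whole ST region: coi = h
  h <- 3
  rec <- mkrec(function(tr) h * pfasim:::.st_shape(tr))
  res <- compute_coi(rec, detect_qrs(rec, 1))
  ok <- res$valid & !is.na(res$coi)
  expect_true(any(ok))
  expect_true(all(abs(res$coi[ok] - h) < 0.05 * h))
  # triangular deflection 0 -> h -> 0 over the AUC window: coi ~ h/2
  tri <- function(tr) {
    s <- pmax(0, 1 - abs(tr - 0.16) / 0.12)     # peak at 160 ms, base 240 ms
    h * s
  }
  rec2 <- mkrec(tri)
  res2 <- compute_coi(rec2, detect_qrs(rec2, 1))
  ok2 <- res2$valid & !is.na(res2$coi)
  # trapezoid-rule oracle over the stored window
  for (b in which(ok2)) {
    seg <- rec2$unipolar[res2$auc_start[b]:res2$auc_end[b]] - res2$baseline[b]
    auc <- sum((seg[-1] + seg[-length(seg)]) / 2) / 1000
    expect_equal(res2$coi[b],
                 auc / ((res2$auc_end[b] - res2$auc_start[b]) / 1000),
                 tolerance = 1e-9)
  }
})

test_that("segment windows enforce the beat-count and contamination rules", {
  fs <- 1000
  mk_metrics <- function(times, valid, value = 4) {
    data.frame(beat = seq_along(times), qrs_index = round(times * fs),
               time_s = times, pp_bipolar = value, coi = value,
               valid = valid)
  }
  dummy <- signal_record(matrix(0, 40000, 1), numeric(40000), numeric(40000),
                         ablation_time = NA)
  # window 1: only 9 valid beats -> excluded as min-beats
  t1 <- seq(0.5, 9.5, length.out = 9)
  # window 2 (10-20 s): 12 beats, 3 contaminated (25%) -> artefacts
  t2 <- seq(10.4, 19.6, length.out = 12)
  v2 <- rep(TRUE, 12); v2[1:3] <- FALSE
  # window 3 (20-30 s): 11 identical valid beats -> median 4
  t3 <- seq(20.4, 29.6, length.out = 11)
  pp <- mk_metrics(c(t1, t2, t3), c(rep(TRUE, 9), v2, rep(TRUE, 11)))
  coi <- pp
  s <- summarize_segments(pp, coi, dummy)
  w <- s$windows
  expect_equal(w$excluded[1], "min-beats")
  expect_equal(w$excluded[2], "artefacts")
  expect_true(is.na(w$excluded[3]))
  expect_equal(w$median_pp[3], 4)
  expect_equal(w$median_coi[3], 4)
  # medians are invariant to beat order within a window
  perm <- sample(nrow(pp))
  s2 <- summarize_segments(pp[perm, ], coi[perm, ], dummy)
  expect_equal(s2$windows$median_pp, w$median_pp)
})

test_that("timepoint extraction and normalisation follow the window rules", {
  fs <- 1000
  dummy <- signal_record(matrix(0, 400000, 1), numeric(400000),
                         numeric(400000), ablation_time = 60)
  times <- seq(0.5, 399, by = 1)
  pp <- data.frame(beat = seq_along(times), qrs_index = round(times * fs),
                   time_s = times,
                   pp_bipolar = ifelse(times < 60, 6, 3), valid = TRUE)
  coi <- data.frame(beat = seq_along(times), qrs_index = round(times * fs),
                    time_s = times,
                    coi = ifelse(times < 60, 0.2, 5), valid = TRUE)
  s <- summarize_segments(pp, coi, dummy)
  tp <- extract_timepoints(s)
  expect_equal(unname(tp$pp["pre"]), 6)
  expect_equal(unname(tp$pp["post_30s"]), 3)
  expect_equal(unname(tp$normalized["pp_post_over_pre"]), 0.5)
  # unipolar windows inside the 30-s saturation recovery are excluded
  blanked <- s$windows$t_center > 60 & s$windows$t_center < 88
  expect_true(all(!is.na(s$windows$coi_excluded[blanked])))
  expect_equal(unname(tp$coi["post_30s"]), 5)
  expect_equal(unname(tp$normalized["coi_3p5min_over_30s"]), 1)
  # truncated record: the 3.5-min window is reported absent
  dummy2 <- signal_record(matrix(0, 200000, 1), numeric(200000),
                          numeric(200000), ablation_time = 60)
  sel <- times < 200
  s2 <- summarize_segments(pp[sel, ], coi[sel, ], dummy2)
  tp2 <- extract_timepoints(s2)
  expect_true(is.na(tp2$pp["post_3p5min"]))
  expect_false(is.na(tp2$pp["post_30s"]))
})
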