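# Synthetic PPG/ABP generator: amplitudes, determinism, coupling, artifacts.

test_that("profile invariants are enforced", {
  expect_error(subject_profile(80, 90))                     # sbp <= dbp
  expect_error(subject_profile(110, -5))
  expect_error(subject_profile(110, 72, heart_rate = 250))
  expect_error(subject_profile(110, 72, wander_frequency = 0.05))
  expect_error(subject_profile(110, 72, noise_sd = -1))
})

test_that("noiseless ABP attains its systolic/diastolic targets exactly", {
  abp <- generate_abp(clean_profile(110, 72, 60), 1250, FS)
  pt <- detect_peaks_troughs(abp, FS)
  expect_lt(max(abs(abp[pt$peaks] - 110)), 0.5)
  expect_lt(max(abs(abp[pt$troughs] - 72)), 0.5)
  # across categories (amplitude fidelity invariant)
  for (bp in list(c(110, 72), c(125, 75), c(135, 85), c(160, 100))) {
    rec_bp <- segment_bp(generate_abp(clean_profile(bp[1], bp[2], 75), 1250, FS), FS)
    expect_lt(abs(rec_bp[["sbp"]] - bp[1]), 1)
    expect_lt(abs(rec_bp[["dbp"]] - bp[2]), 1)
  }
})

test_that("generation is bit-deterministic given the seed", {
  p <- subject_profile(130, 85, 80, seed = 17L)   # noisy defaults
  a1 <- generate_abp(p, 2000, FS); a2 <- generate_abp(p, 2000, FS)
  expect_identical(a1, a2)
  expect_identical(generate_ppg(a1, p, FS), generate_ppg(a2, p, FS))
  d1 <- generate_dataset(5, base_seed = 3, duration_s = 6)
  d2 <- generate_dataset(5, base_seed = 3, duration_s = 6)
  expect_identical(d1, d2)
  # different seeds differ
  p2 <- subject_profile(130, 85, 80, seed = 18L)
  expect_false(identical(generate_abp(p2, 2000, FS), a1))
})

test_that("beat count tracks the heart rate", {
  abp <- generate_abp(clean_profile(120, 80, 75), 60 * FS, FS)
  n_peaks <- length(detect_peaks_troughs(abp, FS)$peaks)
  expect_gte(n_peaks, 74); expect_lte(n_peaks, 76)
})

test_that("records shorter than one beat are rejected", {
  expect_error(generate_abp(clean_profile(110, 72, 60), 100, FS),
               "shorter than one beat")
})

test_that("noiseless PPG is beat-periodic", {
  rec <- clean_record(110, 72, 60, duration_s = 20)
  ac <- acf(rec$ppg, lag.max = 200, plot = FALSE)$acf[-1]
  period <- FS * 60 / 60
  peak_lag <- which.max(ac[50:200]) + 49
  expect_lt(abs(peak_lag - period), 5)
  expect_gt(max(ac[50:200]), 0.7)
})

test_that("baseline wander shows up at the wander frequency", {
  p <- subject_profile(110, 72, 72, wander_amplitude = 0.5,
                       wander_frequency = 0.3, noise_sd = 0, seed = 9)
  rec <- generate_record(p, 40, FS)
  n <- rec$n_samples
  sp <- Mod(fft(rec$ppg - mean(rec$ppg)))^2
  f <- (seq_len(n) - 1) * FS / n
  resp_bin <- which.min(abs(f - 0.3))
  # wander bin dominates its spectral neighbourhood below the pulse band
  low <- which(f > 0.05 & f < 0.8)
  expect_equal(low[which.max(sp[low])], resp_bin, tolerance = 1)
})

test_that("pulse morphology differs measurably between BP regimes", {
  rec_lo <- clean_record(110, 72, 70, seed = 5)
  rec_hi <- clean_record(150, 95, 70, seed = 5)
  expect_gt(mean(abs(rec_lo$ppg - rec_hi$ppg)), 0.01)
  # monotone coupling: width grows with sbp
  w <- sapply(c(110, 130, 150), function(s)
    diff(range(which(clean_record(s, 70, 60, seed = 2)$ppg[1:125] > 0.5))))
  expect_false(is.unsorted(w))
})

test_that("artifact injection touches exactly the requested span", {
  rec <- clean_record()
  n <- rec$n_samples
  expect_identical(inject_artifact(rec, "spike", 100, 0), rec)   # span 0
  fl <- inject_artifact(rec, "flatline", 1, n, channel = "abp")
  expect_equal(sd(fl$abp), 0)
  expect_identical(fl$ppg, rec$ppg)                              # other channel untouched
  dr <- inject_artifact(rec, "dropout", 51, 100, channel = "ppg")
  expect_true(all(dr$ppg[51:150] == 0))
  expect_identical(dr$ppg[-(51:150)], rec$ppg[-(51:150)])
  sp <- inject_artifact(rec, "spike", 201, 50, channel = "ppg")
  expect_true(which.max(abs(sp$ppg)) %in% 201:250)
  expect_error(inject_artifact(rec, "spike", n - 5, 20), "within the record")
})

test_that("generated cohorts honour the category mix and seeds", {
  recs <- generate_dataset(12, c(1, 0, 0, 0), base_seed = 9, duration_s = 10,
                           wander_amplitude = 0, noise_sd = 0)
  labs <- vapply(recs, function(r) {
    bp <- segment_bp(r$abp, FS)
    as.character(classify_acc_aha(bp[["sbp"]], bp[["dbp"]]))
  }, character(1))
  expect_true(all(labs == "NORMAL"))
  expect_identical(generate_dataset(0), list())
  expect_error(generate_dataset(5, c(0, 0, 0, 0)))
  expect_error(generate_dataset(5, c(1, 1)))
  # largest-remainder apportionment covers all categories for big enough n
  recs2 <- generate_dataset(8, c(1, 1, 1, 1), base_seed = 2, duration_s = 6,
                            wander_amplitude = 0, noise_sd = 0)
  expect_length(recs2, 8)
})

test_that("record CSV + JSON round trip preserves the waveforms and profile", {
  rec <- clean_record(125, 75, 80, duration_s = 4, seed = 21)
  path <- tempfile(fileext = ".csv")
  write_record(rec, path)
  back <- read_record(path)
  expect_equal(back$ppg, rec$ppg, tolerance = 1e-12)
  expect_equal(back$abp, rec$abp, tolerance = 1e-12)
  expect_identical(back$fs, rec$fs)
  expect_equal(unclass(back$profile), unclass(rec$profile))
  unlink(c(path, paste0(path, ".json")))
})
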