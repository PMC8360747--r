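# Smoothing, detrending, quality control, beat detection, BP labelling.

test_that("moving average is exact on simple closed-form cases", {
  expect_equal(moving_average(rep(3.5, 20), 7), rep(3.5, 20))
  imp <- c(rep(0, 10), 1, rep(0, 10))
  out <- moving_average(imp, 5)
  expect_equal(out[9:13], rep(1 / 5, 5))   # box response plateau
  expect_equal(sum(out), 1)                # mass preserved in the interior
  x <- rnorm(10)
  expect_equal(moving_average(x, 1), x)    # window 1 is the identity
  # shrinking edge windows: first output is mean of first (w+1)/2 samples
  expect_equal(moving_average(x, 5)[1], mean(x[1:3]))
})

test_that("even, non-positive, or oversized windows are rejected", {
  expect_error(moving_average(rnorm(10), 4), "odd")
  expect_error(moving_average(rnorm(10), 0), "odd|positive")
  expect_error(moving_average(rnorm(3), 5), "shorter")
})

test_that("repeated smoothing never increases variance", {
  set.seed(11)
  for (w in c(3, 5, 9)) {
    x <- rnorm(200)
    once <- moving_average(x, w)
    twice <- moving_average(once, w)
    expect_lte(var(twice), var(once))
    expect_lte(var(once), var(x))
  }
})

test_that("baseline removal attenuates the respiratory band, spares the pulse band", {
  t <- (0:1999) / FS
  band_power <- function(x, f) {
    sp <- Mod(fft(x))^2
    sp[round(f * length(x) / FS) + 1]
  }
  resp <- sin(2 * pi * 0.25 * t)
  out <- remove_baseline(resp, FS, 2)
  # moving-average remover: residual amplitude |1 - sinc(0.25 * 2s)| ~ 0.37,
  # i.e. ~87% of the 0.25 Hz power removed
  expect_lt(band_power(out, 0.25) / band_power(resp, 0.25), 0.15)
  pulse <- sin(2 * pi * 1.25 * t)
  out2 <- remove_baseline(pulse, FS, 2)
  amp_ratio <- sqrt(band_power(out2, 1.25) / band_power(pulse, 1.25))
  expect_gt(amp_ratio, 0.8)   # < 20% pulse-band amplitude loss
  expect_equal(remove_baseline(rep(2, 500), FS, 2), rep(0, 500))
  expect_error(remove_baseline(rnorm(100), FS, 2), "shorter")
})

test_that("peak detection recovers beats of known rate and phase", {
  # 1 Hz sinusoid over 5 s: 5 +- 1 maxima at the known phase
  t <- (0:624) / FS
  x <- sin(2 * pi * t)
  pt <- detect_peaks_troughs(x, FS)
  expect_gte(length(pt$peaks), 4); expect_lte(length(pt$peaks), 6)
  expect_true(all(abs((t[pt$peaks] %% 1) - 0.25) < 0.02))
  # constant series: no peaks
  expect_length(detect_peaks_troughs(rep(1, 250), FS)$peaks, 0)
  # 10 s noiseless beat train at 60 bpm: 10 +- 1 peaks, one trough between
  abp <- generate_abp(clean_profile(110, 72, 60), 1250, FS)
  pt2 <- detect_peaks_troughs(abp, FS)
  expect_gte(length(pt2$peaks), 9); expect_lte(length(pt2$peaks), 11)
  expect_length(pt2$troughs, length(pt2$peaks) - 1L)
  expect_true(all(diff(sort(c(pt2$peaks, pt2$troughs))) > 0))
})

test_that("segment BP is the arithmetic mean of peak and trough values", {
  # hand-built triangle train: detected peaks {120, 120, 122, 118} (mean
  # 120), between-peak minima {80, 78, 82} (mean 80)
  ramp <- function(a, b) seq(a, b, length.out = 26)[-1]
  x <- c(seq(85, 120, length.out = 26), ramp(120, 80), ramp(80, 120),
         ramp(120, 78), ramp(78, 122), ramp(122, 82), ramp(82, 118),
         ramp(118, 90))
  bp <- segment_bp(x, FS)
  expect_equal(unname(bp["sbp"]), 120)
  expect_equal(unname(bp["dbp"]), 80)
  # noiseless synthetic fixture recovers its targets within 1 mmHg
  abp <- generate_abp(clean_profile(110, 72, 60), 1250, FS)
  bp2 <- segment_bp(abp, FS)
  expect_lt(abs(bp2[["sbp"]] - 110), 1)
  expect_lt(abs(bp2[["dbp"]] - 72), 1)
  # single-beat segment: means equal that beat's extrema
  one <- generate_abp(clean_profile(110, 72, 60), 130, FS)
  bp3 <- segment_bp(one, FS)
  expect_equal(bp3[["sbp"]], max(one))
  expect_equal(bp3[["dbp"]], min(one))
  # labelled failure, distinct from QC: flat segment has no beats
  expect_error(segment_bp(rep(90, 250), FS), class = "scalobp_label_error")
})

test_that("ACC/AHA classification reproduces worked examples and boundaries", {
  expect_equal(as.character(classify_acc_aha(110, 72)), "NORMAL")
  expect_equal(as.character(classify_acc_aha(128, 78)), "ELEVATED")
  expect_equal(as.character(classify_acc_aha(125, 85)), "STAGE1")   # DBP rule
  expect_equal(as.character(classify_acc_aha(141, 70)), "STAGE2")
  expect_equal(as.character(classify_acc_aha(120, 79)), "ELEVATED")
  expect_equal(as.character(classify_acc_aha(130, 70)), "STAGE1")
  expect_equal(as.character(classify_acc_aha(139, 90)), "STAGE2")
  expect_error(classify_acc_aha(80, 90))   # sbp <= dbp
  expect_error(classify_acc_aha(80, 0))
})

test_that("classification partitions the grid and is monotone in both inputs", {
  grid <- expand.grid(sbp = 60:200, dbp = 40:130)
  grid <- grid[grid$sbp > grid$dbp, ]
  cats <- classify_acc_aha(grid$sbp, grid$dbp)
  expect_false(anyNA(cats))                       # total: every input labelled
  expect_setequal(levels(cats), c("NORMAL", "ELEVATED", "STAGE1", "STAGE2"))
  # monotone in sbp at fixed dbp, and in dbp at fixed sbp
  for (dbp in c(60, 75, 85)) {
    sbp <- (dbp + 1):200
    expect_false(is.unsorted(classify_acc_aha(sbp, rep(dbp, length(sbp)))))
  }
  for (sbp in c(118, 128, 150)) {
    dbp <- 40:(sbp - 1)
    expect_false(is.unsorted(classify_acc_aha(rep(sbp, length(dbp)), dbp)))
  }
})

test_that("binary label pools every non-normal category as abnormal", {
  expect_identical(binarize(c("NORMAL", "ELEVATED", "STAGE1", "STAGE2")),
                   c(0L, 1L, 1L, 1L))
  expect_identical(binarize(classify_acc_aha(110, 72)), 0L)
  expect_error(binarize("HIGH"))
})

test_that("pooled group means are consistent with elevated counted as abnormal", {
  # a mixture over the four categories in ICU-like proportions
  # (1641 : 1739 : 2692 : 334): the abnormal pool's mean SBP must sit far
  # above any normal reading, which only happens when ELEVATED is pooled
  # into abnormal rather than normal
  mids <- data.frame(sbp = c(110, 124, 135, 150), dbp = c(72, 76, 85, 95))
  n <- c(1641, 1739, 2692, 334)
  lab <- binarize(classify_acc_aha(mids$sbp, mids$dbp))
  expect_identical(lab, c(0L, 1L, 1L, 1L))
  abn_sbp <- weighted.mean(mids$sbp[lab == 1], n[lab == 1])
  expect_gt(abn_sbp, 120)
  expect_lt(weighted.mean(mids$sbp[lab == 0], n[lab == 0]), 120)
})

test_that("quality control flags dead, gappy, and spiky records", {
  rec <- clean_record()
  expect_true(quality_check(rec)$passed)
  flat <- inject_artifact(rec, "flatline", 1, rec$n_samples, channel = "ppg")
  qf <- quality_check(flat)
  expect_false(qf$passed)
  expect_true("no_signal" %in% qf$reasons)
  drop3 <- inject_artifact(rec, "dropout", 200, 3 * FS, channel = "both")
  qd <- quality_check(drop3)
  expect_false(qd$passed)
  expect_true("missing_peaks" %in% qd$reasons)
  spiky <- inject_artifact(rec, "spike", 300, 10, channel = "ppg")
  qs <- quality_check(spiky)
  expect_false(qs$passed)
  expect_true("artifact" %in% qs$reasons)
  # passed iff reasons empty
  expect_identical(quality_check(rec)$reasons, character(0))
})
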