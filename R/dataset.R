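# Slicing records into fixed-length labelled segments and emitting an
# image + manifest dataset with a deterministic randomised train/val split.

.segment_lengths <- c(100L, 150L, 200L, 250L, 300L, 350L, 400L, 450L, 500L)

#' Non-overlapping segment windows
#'
#' Consecutive half-open windows `[start, start + L)` from sample 0;
#' remainder samples are discarded.
#'
#' @param n_total Total samples available.
#' @param L Window length in samples (>= 1).
#' @return Data frame with 0-based `start` and `length` columns; zero rows
#'   when `L > n_total`.
#' @examples
#' segment_indices(1000, 300)   # starts 0, 300, 600
#' @export
segment_indices <- function(n_total, L) {
  if (L < 1) stop("L must be >= 1")
  k <- floor(n_total / L)
  data.frame(start = as.integer(seq_len(k) - 1L) * as.integer(L),
             length = rep(as.integer(L), k))
}

#' Deterministic randomised train/validation split
#'
#' Shuffles `1:n_items` with the given seed; the first
#' `floor(train_frac * n)` shuffled items form the training set, the
#' remainder the validation set. The two sets are disjoint and exhaustive.
#'
#' @param n_items Number of items (> 0).
#' @param train_frac Training fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `val`.
#' @examples
#' lengths(split_indices(3110, 0.9, seed = 1))   # 2799 / 311
#' @export
split_indices <- function(n_items, train_frac = 0.9, seed = 1L) {
  if (n_items <= 0) stop("n_items must be positive")
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie strictly between 0 and 1")
  perm <- with_seed(seed, sample.int(n_items))
  n_train <- floor(train_frac * n_items)
  list(train = perm[seq_len(n_train)],
       val = perm[setdiff(seq_len(n_items), seq_len(n_train))])
}

#' Build an image + manifest dataset from waveform records
#'
#' The full front end of the pipeline: records failing [quality_check()]
#' are excluded (one log line each); each surviving record's PPG is
#' smoothed (moving average, `smooth_window` samples) and detrended
#' ([remove_baseline()]) at record level, then sliced into non-overlapping
#' length-`L` windows; each window is labelled from its raw ABP samples
#' ([segment_bp()] + [classify_acc_aha()]); the PPG window is transformed
#' with the requested wavelet and rendered to a 224 x 224 x 3 PNG (or
#' rendered raw for the `"none"` baseline). Segments whose ABP window
#' yields no detectable beat are dropped and logged. Finally the surviving
#' segments are split train/validation at segment level with `seed`.
#'
#' @param records List of `waveform_record` objects.
#' @param wavelet A [wavelet_spec()], or `"none"` for the no-CWT baseline.
#' @param L Segment length in samples.
#' @param train_frac Training fraction.
#' @param seed Integer seed controlling the split.
#' @param out_dir Output directory; images land in
#'   `out_dir/<wavelet>/<L>/`.
#' @param smooth_window Moving-average window (samples) for the PPG.
#' @param trend_window Baseline-trend window (seconds).
#' @param qc Thresholds from [qc_config()].
#' @param write_images Set `FALSE` to skip PNG writing (manifest only,
#'   images returned in memory).
#' @return Data frame manifest (class `scalobp_manifest`): one row per
#'   surviving segment with columns `image`, `split`, `sbp`, `dbp`,
#'   `category`, `binary`, `wavelet`, `segment_length`, `seed`, plus
#'   attributes `dropped` (segments without a detectable beat),
#'   `excluded_records`, and `images` (list of `scalogram_image`, in row
#'   order). The manifest CSV and a JSON run-config snapshot are written
#'   next to the images.
#' @export
build_dataset <- function(records, wavelet, L, train_frac = 0.9, seed = 1L,
                          out_dir = tempfile("scalobp_ds_"),
                          smooth_window = 5L, trend_window = 2,
                          qc = qc_config(), write_images = TRUE) {
  if (!length(records)) stop("no input records")
  baseline <- identical(wavelet, "none")
  if (!baseline && !inherits(wavelet, "wavelet_spec"))
    stop("wavelet must be a wavelet_spec or \"none\"")
  wname <- if (baseline) "none" else wavelet$name
  fs <- records[[1]]$fs

  keep <- logical(length(records))
  excluded <- character(0)
  for (i in seq_along(records)) {
    rep_i <- quality_check(records[[i]], config = qc)
    keep[i] <- rep_i$passed
    if (!rep_i$passed) {
      msg <- sprintf("record %d excluded: %s", i,
                     paste(rep_i$reasons, collapse = ", "))
      excluded <- c(excluded, msg)
      message(msg)
    }
  }
  records <- records[keep]
  if (!length(records))
    stop("all records were excluded by quality control")

  scales <- if (!baseline) default_scales(L, fs, wavelet)
  img_dir <- file.path(out_dir, wname, L)
  if (write_images) dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list(); images <- list(); dropped <- 0L
  for (r in seq_along(records)) {
    rec <- records[[r]]
    ppg <- remove_baseline(moving_average(rec$ppg, smooth_window),
                           fs, trend_window)
    wins <- segment_indices(rec$n_samples, L)
    for (w in seq_len(nrow(wins))) {
      idx <- (wins$start[w] + 1L):(wins$start[w] + L)
      bp <- tryCatch(segment_bp(rec$abp[idx], fs),
                     scalobp_label_error = function(e) NULL)
      if (is.null(bp)) {
        dropped <- dropped + 1L
        message(sprintf("record %d, segment at %d: no ABP beats, dropped",
                        r, wins$start[w]))
        next
      }
      category <- classify_acc_aha(bp[["sbp"]], bp[["dbp"]])
      meta <- list(wavelet = wname, segment_length = L, record = r,
                   start = wins$start[w])
      img <- if (baseline) render_raw_segment(ppg[idx], meta = meta)
             else {
               res <- cwt(ppg[idx], scales, wavelet, fs)
               meta$scale_range <- range(scales)
               render(coeffs_to_matrix(res), meta = meta)
             }
      path <- file.path(img_dir, sprintf("seg_r%03d_s%06d.png", r,
                                         wins$start[w]))
      if (write_images) save_image(img, path)
      images[[length(images) + 1L]] <- img
      rows[[length(rows) + 1L]] <- data.frame(
        image = path, split = NA_character_, sbp = bp[["sbp"]],
        dbp = bp[["dbp"]], category = as.character(category),
        binary = binarize(category), wavelet = wname, segment_length = L,
        seed = as.integer(seed))
    }
  }
  if (!length(rows)) stop("zero surviving segments")
  manifest <- do.call(rbind, rows)
  sp <- split_indices(nrow(manifest), train_frac, seed)
  manifest$split[sp$train] <- "train"
  manifest$split[sp$val] <- "val"
  if (write_images) {
    utils::write.csv(manifest, file.path(img_dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(wavelet = wname, segment_length = L, train_frac = train_frac,
           seed = seed, fs = fs, smooth_window = smooth_window,
           trend_window = trend_window, qc = qc,
           scales = if (!baseline) scales,
           n_dropped = dropped, excluded_records = excluded),
      file.path(img_dir, "run_config.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(manifest, class = c("scalobp_manifest", "data.frame"),
            dropped = dropped, excluded_records = excluded, images = images)
}

#' @export
print.scalobp_manifest <- function(x, ...) {
  cat(sprintf("<scalobp_manifest> %d segments (%s, L = %d): %d train / %d val, %d dropped\n",
              nrow(x), x$wavelet[1], x$segment_length[1],
              sum(x$split == "train"), sum(x$split == "val"),
              attr(x, "dropped")))
  invisible(x)
}
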