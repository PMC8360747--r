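# Rendering CWT coefficient matrices as fixed-size colour images.
#
# Images are produced directly from the coefficient matrix — per-image
# min-max normalisation, separable bilinear resize to 224 x 224, then a
# perceptually ordered dark-blue-to-bright-yellow (viridis) colormap —
# rather than through a plotting canvas, which keeps the pixels
# bit-reproducible and margin-free.

.IMG_SIZE <- 224L

#' Reduce CWT coefficients to a real matrix
#'
#' @param result A `cwt_result` from [cwt()] or [cwt_oracle()].
#' @param mode `"magnitude"` (|W|, the default for complex wavelets) or
#'   `"real"` (Re W, the default for real wavelets).
#' @return Real matrix, same shape as the coefficient matrix.
#' @export
coeffs_to_matrix <- function(result,
                             mode = if (result$wavelet$is_complex)
                               "magnitude" else "real") {
  stopifnot(inherits(result, "cwt_result"))
  mode <- match.arg(mode, c("magnitude", "real"))
  if (!length(result$coeffs)) stop("empty CWT result")
  out <- if (mode == "magnitude") Mod(result$coeffs) else Re(result$coeffs)
  attr(out, "mode") <- mode
  out
}

# 256-entry RGB lookup table (0-255 per channel), dark blue -> bright yellow
scalogram_colormap <- function(name = "viridis") {
  cols <- grDevices::hcl.colors(256L, palette = name)
  t(grDevices::col2rgb(cols))
}

# linear-interpolation matrix mapping n_in samples to n_out, with the first
# and last points aligned
interp_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  if (n_in == 1L) { A[, 1L] <- 1; return(A) }
  pos <- seq(1, n_in, length.out = n_out)
  lo <- pmin(floor(pos), n_in - 1L)
  frac <- pos - lo
  A[cbind(seq_len(n_out), lo)] <- 1 - frac
  A[cbind(seq_len(n_out), lo + 1L)] <- A[cbind(seq_len(n_out), lo + 1L)] + frac
  A
}

# separable bilinear resize as two interpolation-matrix products
resize_bilinear <- function(M, out_h = .IMG_SIZE, out_w = .IMG_SIZE) {
  interp_matrix(nrow(M), out_h) %*% M %*% t(interp_matrix(ncol(M), out_w))
}

new_scalogram_image <- function(pixels, meta = list()) {
  structure(list(pixels = pixels, meta = meta), class = "scalogram_image")
}

#' @export
print.scalogram_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<scalogram_image> %d x %d x %d, 8-bit\n", d[1], d[2], d[3]))
  if (!is.null(x$meta$wavelet))
    cat(sprintf("  wavelet %s, segment length %s\n", x$meta$wavelet,
                x$meta$segment_length))
  invisible(x)
}

#' Render a coefficient matrix as a 224 x 224 x 3 image
#'
#' The matrix is min-max normalised to `[0, 1]` (a constant matrix maps to
#' 0.5, the colormap midpoint), bilinearly resized to 224 x 224, and passed
#' through a dark-blue-to-yellow colormap: low coefficients render dark
#' blue, large coefficients bright yellow. Row 1 of the matrix (smallest
#' scale, highest pseudo-frequency) becomes the top image row; time runs
#' left to right.
#'
#' @param matrix Real, finite coefficient matrix (scales x time).
#' @param colormap Palette name understood by [grDevices::hcl.colors()].
#' @param meta Optional metadata list stored with the image (and in the
#'   JSON sidecar on save).
#' @return A `scalogram_image`: integer pixel array of dim
#'   `c(224, 224, 3)` with values in 0..255, plus metadata including the
#'   normalisation bounds.
#' @export
render <- function(matrix, colormap = "viridis", meta = list()) {
  if (!is.matrix(matrix) || !length(matrix)) stop("matrix must be nonempty")
  bad <- which(!is.finite(matrix))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(matrix))
    stop(sprintf("non-finite coefficient at row %d, column %d", rc[1], rc[2]))
  }
  lo <- min(matrix); hi <- max(matrix)
  norm <- if (hi > lo) (matrix - lo) / (hi - lo)
          else matrix(0.5, nrow(matrix), ncol(matrix))
  resized <- resize_bilinear(norm)
  resized[resized < 0] <- 0; resized[resized > 1] <- 1
  lut <- scalogram_colormap(colormap)
  idx <- matrix(as.integer(round(resized * 255)) + 1L, nrow(resized))
  pixels <- array(0L, dim = c(.IMG_SIZE, .IMG_SIZE, 3L))
  for (ch in 1:3)
    pixels[, , ch] <- matrix(lut[idx, ch], nrow(idx))
  meta$colormap <- colormap
  meta$normalization <- c(min = lo, max = hi)
  meta$orientation <- "row 1 = smallest scale (top); time left to right"
  new_scalogram_image(pixels, meta)
}

#' Render a raw PPG segment as an image (no-CWT baseline)
#'
#' The comparison baseline that feeds the classifier the untransformed
#' signal: the segment is min-max normalised, linearly resampled to 224
#' points, and tiled down 224 rows as a grayscale image replicated over the
#' three colour channels.
#'
#' @param x Numeric PPG segment.
#' @param meta Optional metadata list.
#' @return A `scalogram_image`.
#' @export
render_raw_segment <- function(x, meta = list()) {
  if (!length(x) || any(!is.finite(x))) stop("x must be nonempty and finite")
  lo <- min(x); hi <- max(x)
  v <- if (hi > lo) (x - lo) / (hi - lo) else rep(0.5, length(x))
  row <- as.numeric(interp_matrix(length(v), .IMG_SIZE) %*% v)
  gray <- as.integer(round(pmin(pmax(row, 0), 1) * 255))
  pixels <- array(rep(matrix(gray, .IMG_SIZE, .IMG_SIZE, byrow = TRUE), 3L),
                  dim = c(.IMG_SIZE, .IMG_SIZE, 3L))
  meta$colormap <- "grayscale"
  meta$normalization <- c(min = lo, max = hi)
  new_scalogram_image(pixels, meta)
}

#' Save / load a scalogram image
#'
#' Lossless PNG round trip; metadata travels in a JSON sidecar
#' (`<path>.json`).
#'
#' @param img A `scalogram_image`.
#' @param path PNG file path.
#' @return `save_image` returns `path` invisibly; `load_image` the
#'   reconstructed `scalogram_image` (bit-identical pixels).
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "scalogram_image"))
  png::writePNG(img$pixels / 255, path)
  if (length(img$meta))
    jsonlite::write_json(img$meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname save_image
#' @export
load_image <- function(path) {
  px <- tryCatch(png::readPNG(path), error = function(e)
    stop(sprintf("failed to read PNG '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  pixels <- array(as.integer(round(px[, , 1:3] * 255)), dim = c(dim(px)[1:2], 3L))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  new_scalogram_image(pixels, meta)
}
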