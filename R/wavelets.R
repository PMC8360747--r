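# Six continuous-wavelet bases and the CWT engine.
#
# All six mother wavelets are implemented from their closed forms:
#   fbsp:  sqrt(Fb) * sinc(Fb*t/m)^m * exp(2i*pi*Fc*t)
#   shan:  sqrt(Fb) * sinc(Fb*t)     * exp(2i*pi*Fc*t)
#   cgau1: C1 * d/dt[ exp(-1i*t) * exp(-t^2) ],  C1 s.t. ||psi||_2 = 1
#   morl:  exp(-t^2/2) * cos(5*t)
#   mexh:  (2/(sqrt(3)*pi^(1/4))) * exp(-t^2/2) * (1 - t^2)
#   gaus1: C1 * d/dt[ exp(-t^2) ],               C1 s.t. ||psi||_2 = 1
# sinc(x) = sin(pi*x)/(pi*x).

.wavelet_names <- c("fbsp", "shan", "cgau1", "morl", "mexh", "gaus1")

#' Specify a mother wavelet
#'
#' Builds the parameterised description of one of the six supported
#' continuous-wavelet bases. Defaults are the standard published
#' parameterisations: `fbsp1-15-1` (order m = 1, bandwidth Fb = 15, centre
#' frequency Fc = 1), `shan15-1` (Fb = 15, Fc = 1), and first-derivative
#' (one vanishing moment) complex and real Gaussians.
#'
#' For the band-limited wavelets (`fbsp`, `shan`) a centre frequency at or
#' below half the bandwidth puts zero frequency inside the nominal support
#' band, which violates the usual admissibility sufficiency condition
#' `Fc > Fb/2`; the default `shan15-1`/`fbsp1-15-1` parameters do exactly
#' that, so a warning is emitted and the wavelet is used as parameterised.
#'
#' @param name One of `"fbsp"`, `"shan"`, `"cgau1"`, `"morl"`, `"mexh"`,
#'   `"gaus1"`.
#' @param F_b Bandwidth parameter (fbsp, shan).
#' @param F_c Centre-frequency parameter in cycles per unit time (fbsp, shan).
#' @param m Integer order (fbsp only, >= 1).
#' @param n Number of vanishing moments (cgau1, gaus1; fixed at 1 here).
#' @return An object of class `wavelet_spec` with fields `name`, `F_b`,
#'   `F_c`, `m`, `n`, `is_complex`.
#' @examples
#' wavelet_spec("morl")
#' wavelet_spec("cgau1")
#' @export
wavelet_spec <- function(name = .wavelet_names, F_b = NULL, F_c = NULL,
                         m = NULL, n = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    fbsp  = list(name = name, F_b = 15, F_c = 1, m = 1L, n = NA_integer_,
                 is_complex = TRUE),
    shan  = list(name = name, F_b = 15, F_c = 1, m = NA_integer_,
                 n = NA_integer_, is_complex = TRUE),
    cgau1 = list(name = name, F_b = NA_real_, F_c = NA_real_,
                 m = NA_integer_, n = 1L, is_complex = TRUE),
    morl  = list(name = name, F_b = NA_real_, F_c = NA_real_,
                 m = NA_integer_, n = NA_integer_, is_complex = FALSE),
    mexh  = list(name = name, F_b = NA_real_, F_c = NA_real_,
                 m = NA_integer_, n = NA_integer_, is_complex = FALSE),
    gaus1 = list(name = name, F_b = NA_real_, F_c = NA_real_,
                 m = NA_integer_, n = 1L, is_complex = FALSE))
  if (!is.null(F_b)) spec$F_b <- F_b
  if (!is.null(F_c)) spec$F_c <- F_c
  if (!is.null(m)) spec$m <- as.integer(m)
  if (!is.null(n)) {
    if (!identical(as.integer(n), 1L))
      stop("only n = 1 (first derivative) Gaussian wavelets are supported")
    spec$n <- 1L
  }
  if (name %in% c("fbsp", "shan")) {
    if (!is.finite(spec$F_b) || spec$F_b <= 0)
      stop("F_b must be a positive number")
    if (!is.finite(spec$F_c)) stop("F_c must be a number")
    if (name == "fbsp" && (!is.finite(spec$m) || spec$m < 1L))
      stop("fbsp order m must be an integer >= 1")
    if (spec$F_c <= spec$F_b / 2)
      warning(sprintf(
        "%s with F_b = %g, F_c = %g: F_c <= F_b/2, the admissibility ",
        name, spec$F_b, spec$F_c),
        "sufficiency condition F_c > F_b/2 is violated; ",
        "using the wavelet as parameterised", call. = FALSE)
  }
  structure(spec, class = "wavelet_spec")
}

#' @export
print.wavelet_spec <- function(x, ...) {
  pars <- c(F_b = x$F_b, F_c = x$F_c, m = x$m, n = x$n)
  pars <- pars[!is.na(pars)]
  cat(sprintf("<wavelet_spec> %s (%s)\n", x$name,
              if (x$is_complex) "complex" else "real"))
  if (length(pars))
    cat("  ", paste(names(pars), pars, sep = " = ", collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

# normalised sinc, sin(pi x)/(pi x)
sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# L2-normalisation constants of the derivative Gaussians, from the Gaussian
# moment integrals:
#   gaus1:  psi = C * (-2t) exp(-t^2),        ||.||^2 = C^2 sqrt(pi/2)
#   cgau1:  psi = C * (-i - 2t) exp(-it-t^2), ||.||^2 = C^2 sqrt(2*pi)
.gaus1_C <- (pi / 2)^(-1 / 4)
.cgau1_C <- (2 * pi)^(-1 / 4)

#' Evaluate a mother wavelet on a time grid
#'
#' @param spec A [wavelet_spec()].
#' @param t_grid Numeric vector of (finite) time points, conventionally
#'   symmetric about 0.
#' @return Complex values for complex wavelets (`fbsp`, `shan`, `cgau1`),
#'   numeric for real ones (`morl`, `mexh`, `gaus1`).
#' @examples
#' wavelet_function(wavelet_spec("morl"), 0)        # 1
#' wavelet_function(wavelet_spec("mexh"), 0)        # 2/(sqrt(3)*pi^0.25)
#' @export
wavelet_function <- function(spec, t_grid) {
  if (!inherits(spec, "wavelet_spec")) stop("spec must be a wavelet_spec")
  if (!all(is.finite(t_grid))) stop("t_grid must be finite")
  t <- t_grid
  switch(spec$name,
    fbsp  = sqrt(spec$F_b) * sinc(spec$F_b * t / spec$m)^spec$m *
            exp(2i * pi * spec$F_c * t),
    shan  = sqrt(spec$F_b) * sinc(spec$F_b * t) * exp(2i * pi * spec$F_c * t),
    cgau1 = .cgau1_C * (-1i - 2 * t) * exp(-1i * t - t^2),
    morl  = exp(-t^2 / 2) * cos(5 * t),
    mexh  = (2 / (sqrt(3) * pi^(1 / 4))) * exp(-t^2 / 2) * (1 - t^2),
    gaus1 = .gaus1_C * (-2 * t) * exp(-t^2))
}

# Effective half-support of the wavelet in its own time units: the point where
# the envelope falls below 1e-8 of its peak. The sinc-modulated wavelets decay
# only like 1/t, so their support is capped at 8 effective oscillation
# periods (8 / F_c).
wavelet_support <- function(spec) {
  switch(spec$name,
    fbsp  = 8 / abs(spec$F_c),
    shan  = 8 / abs(spec$F_c),
    # exp(-t^2) < 1e-8  =>  |t| > sqrt(log(1e8))
    cgau1 = sqrt(log(1e8)),
    gaus1 = sqrt(log(1e8)),
    # exp(-t^2/2) < 1e-8  =>  |t| > sqrt(2 log(1e8))
    morl  = sqrt(2 * log(1e8)),
    mexh  = sqrt(2 * log(1e8)))
}

# memoised numeric centre frequencies (cycles per unit t)
.cf_cache <- new.env(parent = emptyenv())

#' Nominal centre frequency of a wavelet
#'
#' The dominant frequency of the mother wavelet, in cycles per unit of the
#' wavelet's own time variable, located numerically as the peak of the
#' magnitude spectrum on a dense grid. Used to convert a scale `a` (in
#' samples) to a pseudo-frequency `f = F_c_eff * fs / a`.
#'
#' @param spec A [wavelet_spec()].
#' @return Positive scalar, cycles per unit time.
#' @export
wavelet_center_frequency <- function(spec) {
  # band-limited wavelets have a flat passband, so the numeric spectral peak
  # is ill-defined; their nominal centre frequency is the F_c parameter
  if (spec$name %in% c("fbsp", "shan")) return(abs(spec$F_c))
  key <- paste(spec$name, spec$F_b, spec$F_c, spec$m, sep = "_")
  if (!is.null(.cf_cache[[key]])) return(.cf_cache[[key]])
  half <- wavelet_support(spec)
  n <- 2^14
  dt <- 2 * half / n
  t <- (seq_len(n) - n / 2 - 1) * dt
  psi <- wavelet_function(spec, t)
  spec_mag <- Mod(stats::fft(as.complex(psi)))
  # signed frequency axis: cgau1's exp(-1i*t) factor puts its energy on the
  # negative half, so take the magnitude of the dominant signed frequency
  freq <- (seq_len(n) - 1) / (n * dt)
  freq[freq >= 1 / (2 * dt)] <- freq[freq >= 1 / (2 * dt)] - 1 / dt
  f <- abs(freq[which.max(spec_mag)])
  .cf_cache[[key]] <- f
  f
}

#' Default CWT scale grid
#'
#' 64 geometrically spaced scales covering pseudo-frequencies 0.5-20 Hz via
#' `f = F_c_eff * fs / a`, where `F_c_eff` is the wavelet's nominal centre
#' frequency. The grid depends only on the wavelet and sampling rate, never
#' on segment content.
#'
#' @param segment_len Segment length in samples (>= 16).
#' @param fs Sampling rate in Hz.
#' @param spec A [wavelet_spec()].
#' @param n_scales Number of scales.
#' @param f_min,f_max Pseudo-frequency band limits in Hz.
#' @return Strictly increasing numeric vector of scales, in samples.
#' @export
default_scales <- function(segment_len, fs, spec, n_scales = 64L,
                           f_min = 0.5, f_max = 20) {
  if (segment_len < 16) stop("segment_len must be >= 16 samples")
  fc <- wavelet_center_frequency(spec)
  freqs <- exp(seq(log(f_max), log(f_min), length.out = n_scales))
  fc * fs / freqs
}

# Sampled, conjugated kernel g[j] = Conj(psi(j/a)) for j = -K..K, shared by
# the fast path and the direct-summation oracle, plus the 1/sqrt(a) * dt
# normalisation factor.
cwt_kernel <- function(spec, a, fs) {
  K <- max(1L, as.integer(ceiling(wavelet_support(spec) * a)))
  j <- seq(-K, K)
  g <- Conj(as.complex(wavelet_function(spec, j / a)))
  list(g = g, K = K, norm = 1 / (sqrt(a) * fs))
}

new_cwt_result <- function(coeffs, scales, fs, spec) {
  structure(list(coeffs = coeffs, scales = scales, fs = fs, wavelet = spec),
            class = "cwt_result")
}

#' @export
print.cwt_result <- function(x, ...) {
  cat(sprintf("<cwt_result> %s: %d scales x %d samples (%s), fs = %g Hz\n",
              x$wavelet$name, nrow(x$coeffs), ncol(x$coeffs),
              if (is.complex(x$coeffs)) "complex" else "real", x$fs))
  cat(sprintf("  scales %.3g .. %.3g samples\n", min(x$scales), max(x$scales)))
  invisible(x)
}

check_cwt_args <- function(x, scales) {
  if (length(x) == 0) stop("x must be a nonempty numeric series")
  if (length(scales) == 0) stop("scales must be nonempty")
  if (any(!is.finite(scales)) || any(scales < 1))
    stop("scales must be finite and >= 1 sample")
  if (is.unsorted(scales, strictly = TRUE))
    stop("scales must be strictly increasing")
}

#' Continuous wavelet transform
#'
#' Computes `W(a, b) = a^(-1/2) * sum_t x[t] * Conj(psi((t - b)/a)) * dt`
#' for every scale `a` (in samples) and every translation `b` on the sample
#' grid of `x`, with `dt = 1/fs`. The signal is treated as zero outside its
#' own span (zero-padding by one wavelet support length each side); rows are
#' computed by frequency-domain convolution and returned for the original
#' time span only. [cwt_oracle()] evaluates the same sum by direct
#' summation.
#'
#' @param x Numeric series.
#' @param scales Strictly increasing scales in samples (>= 1).
#' @param spec A [wavelet_spec()].
#' @param fs Sampling rate in Hz.
#' @return A `cwt_result`: coefficient matrix (scales x time; complex for
#'   complex wavelets), the scale grid, and `fs`.
#' @examples
#' x <- sin(2 * pi * 2 * seq(0, 2, by = 1 / 125))
#' res <- cwt(x, default_scales(length(x), 125, wavelet_spec("morl")),
#'            wavelet_spec("morl"), 125)
#' @export
cwt <- function(x, scales, spec, fs = 125) {
  check_cwt_args(x, scales)
  n <- length(x)
  coeffs <- matrix(0i, nrow = length(scales), ncol = n)
  for (s in seq_along(scales)) {
    ker <- cwt_kernel(spec, scales[s], fs)
    K <- ker$K
    nfft <- stats::nextn(n + 2L * K, 2)
    xp <- complex(real = c(x, numeric(nfft - n)))
    # place h[j] = g[-j] so that linear convolution yields the correlation
    hp <- complex(length.out = nfft)
    hp[1] <- ker$g[K + 1]
    jj <- seq_len(K)
    hp[1 + jj] <- ker$g[K + 1 - jj]          # h[+j] = g[-j]
    hp[nfft + 1 - jj] <- ker$g[K + 1 + jj]   # h[-j] = g[+j]
    conv <- stats::fft(stats::fft(xp) * stats::fft(hp), inverse = TRUE) / nfft
    coeffs[s, ] <- ker$norm * conv[seq_len(n)]
  }
  if (!spec$is_complex) coeffs <- Re(coeffs)
  new_cwt_result(coeffs, scales, fs, spec)
}

#' Direct-summation CWT oracle
#'
#' Literal double-loop evaluation of the transform sum, with no transform
#' tricks; the independent reference against which [cwt()] is verified.
#' Intended for short inputs only (cost is quadratic-like in the support).
#'
#' @inheritParams cwt
#' @return A `cwt_result`, structured exactly as [cwt()]'s.
#' @export
cwt_oracle <- function(x, scales, spec, fs = 125) {
  check_cwt_args(x, scales)
  kers <- lapply(scales, function(a) cwt_kernel(spec, a, fs))
  coeffs <- .cwt_oracle_cpp(as.numeric(x),
                            lapply(kers, `[[`, "g"),
                            vapply(kers, `[[`, numeric(1), "norm"))
  if (!spec$is_complex) coeffs <- Re(coeffs)
  new_cwt_result(coeffs, scales, fs, spec)
}
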