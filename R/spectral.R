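#' Welch power spectral density
#'
#' Averaged modified periodogram of the z-scored trace: Hamming-tapered
#' subwindows of `window_ms` (default 500 ms) with `overlap` fraction
#' (default 0.5).  With `window_ms = NULL` the whole trace forms a single
#' window (the short-segment mode used for 200/300 ms windows).  Density
#' units: signal^2 / Hz, one-sided.
#'
#' @param lfp an `lfp_trace` (or numeric vector with `fs` supplied).
#' @param window_ms subwindow length (ms) or `NULL` for a single window.
#' @param overlap overlap fraction in `[0, 1)`.
#' @param fs sampling rate, only if `lfp` is a bare numeric vector.
#' @param zscore z-score the trace first (default TRUE, as all LFPs are
#'   z-scored before spectral analysis).
#' @return object of class `psd_result`: list with `freq` (Hz), `power`
#'   (linear density), `power_db` (10*log10), `window_ms`, `overlap`,
#'   `contrast`.
#' @export
#' @examples
#' x <- sin(2 * pi * 60 * seq(0, 2, by = 1e-3))
#' p <- welch_psd(lfp_trace(x, 1000))
#' p$freq[which.max(p$power)]  # 60
welch_psd <- function(lfp, window_ms = 500, overlap = 0.5, fs = NULL,
                      zscore = TRUE) {
  if (inherits(lfp, "lfp_trace")) {
    x <- lfp$values
    fs <- lfp$fs
    contrast <- lfp$contrast
  } else {
    if (is.null(fs)) stop("fs required for a bare numeric trace", call. = FALSE)
    x <- as.numeric(lfp)
    contrast <- NA_real_
  }
  if (zscore) {
    s <- sd(x)
    x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  }
  n <- length(x)
  nwin <- if (is.null(window_ms)) n else round(window_ms * fs / 1000)
  if (n < nwin)
    stop("trace shorter than one Welch window", call. = FALSE)
  step <- max(1L, as.integer(round(nwin * (1 - overlap))))
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- .hamming(nwin)
  u <- sum(w^2)  # window power normalization
  nf <- nwin %/% 2 + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nwin - 1L)] * w
    sp <- abs(fft(seg))^2 / (fs * u)
    half <- sp[seq_len(nf)]
    half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    if (nwin %% 2 == 1L) half[nf] <- 2 * half[nf]
    acc <- acc + half
  }
  power <- acc / length(starts)
  freq <- (seq_len(nf) - 1) * fs / nwin
  structure(list(freq = freq, power = power,
                 power_db = 10 * log10(pmax(power, .Machine$double.xmin)),
                 window_ms = nwin * 1000 / fs, overlap = overlap,
                 contrast = contrast, fs = fs),
            class = "psd_result")
}

.hamming <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Decibel conversion helpers
#'
#' `power_to_db` is `10*log10(p)`; `db_to_power` inverts it.
#' @param p linear power.
#' @param db power in dB.
#' @return converted values.
#' @export
power_to_db <- function(p) 10 * log10(p)

#' @rdname power_to_db
#' @export
db_to_power <- function(db) 10^(db / 10)

#' PSD modulation relative to a reference contrast
#'
#' Pointwise relative power change on the linear scale,
#' `(PSD_K' - PSD_ref) / PSD_ref`, where the reference is typically the
#' median PSD at the intermediate contrast K = 30.
#'
#' @param psd a `psd_result` (or numeric power vector).
#' @param reference the reference `psd_result` (or numeric power vector on
#'   the same frequency grid).
#' @return object of class `modulation_curve`: list with `freq`, `modulation`
#'   (dimensionless fraction), `contrast`, `reference_contrast`.
#' @export
#' @examples
#' m <- psd_modulation(c(2, 4), c(1, 2))
#' m$modulation  # 1, 1
psd_modulation <- function(psd, reference) {
  f1 <- if (inherits(psd, "psd_result")) psd$freq else NULL
  f2 <- if (inherits(reference, "psd_result")) reference$freq else NULL
  p1 <- if (inherits(psd, "psd_result")) psd$power else as.numeric(psd)
  p2 <- if (inherits(reference, "psd_result")) reference$power else as.numeric(reference)
  if (!is.null(f1) && !is.null(f2)) {
    if (length(f1) != length(f2) || max(abs(f1 - f2)) > 1e-9)
      stop("frequency grids do not match", call. = FALSE)
  }
  if (length(p1) != length(p2))
    stop("power vectors have different lengths", call. = FALSE)
  if (any(p2 <= 0))
    stop("degenerate reference: zero power at some frequency", call. = FALSE)
  structure(list(freq = if (!is.null(f1)) f1 else seq_along(p1) - 1,
                 modulation = (p1 - p2) / p2,
                 contrast = if (inherits(psd, "psd_result")) psd$contrast else NA,
                 reference_contrast = if (inherits(reference, "psd_result"))
                   reference$contrast else NA),
            class = "modulation_curve")
}

#' Band-average power from a PSD
#'
#' Mean linear power density over one or more frequency ranges (used for the
#' narrow-band, broad-band and whole-gamma summaries).
#'
#' @param psd a `psd_result`.
#' @param ranges two-column matrix of `[lo, hi]` ranges (Hz) or a length-2
#'   vector.
#' @param peak if TRUE return the maximum instead of the mean.
#' @return scalar power.
#' @export
band_power <- function(psd, ranges, peak = FALSE) {
  if (is.null(dim(ranges))) ranges <- matrix(ranges, ncol = 2, byrow = TRUE)
  sel <- rep(FALSE, length(psd$freq))
  for (i in seq_len(nrow(ranges)))
    sel <- sel | (psd$freq >= ranges[i, 1] & psd$freq <= ranges[i, 2])
  if (!any(sel)) stop("band outside the frequency grid", call. = FALSE)
  if (peak) max(psd$power[sel]) else mean(psd$power[sel])
}

#' Peak frequency within a band
#'
#' @param psd a `psd_result`.
#' @param range `[lo, hi]` (Hz), default the narrow band.
#' @return frequency (Hz) of the maximum power inside the range.
#' @export
peak_frequency <- function(psd, range = c(45, 65)) {
  sel <- psd$freq >= range[1] & psd$freq <= range[2]
  psd$freq[sel][which.max(psd$power[sel])]
}
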